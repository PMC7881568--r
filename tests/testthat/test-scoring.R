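# Reaction centers, protonation, proton affinities, site selection,
# reactivity classes and report assembly.

test_that("reaction centers collapse to one class per symmetry orbit", {
  benz <- find_reaction_centers(tautomer_of("c1ccccc1"))
  expect_equal(length(benz), 1)
  expect_equal(length(benz[[1]]$equivalent_atoms), 6)

  # fluorobenzene: ortho, meta, para (0-based indices frozen from the
  # canonical-ranking oracle on Fc1ccccc1)
  fb <- find_reaction_centers(tautomer_of("Fc1ccccc1"))
  expect_equal(length(fb), 3)
  classes <- lapply(fb, function(ct) sort(ct$atom_index0))
  members <- lapply(fb, function(ct) sort(ct$equivalent_atoms - 1L))
  expect_setequal(vapply(members, paste, "", collapse = ","),
                  c("2,6", "3,5", "4"))

  pyr <- find_reaction_centers(tautomer_of("c1ccncc1"))
  expect_equal(length(pyr), 3)

  tol <- find_reaction_centers(tautomer_of("Cc1ccccc1"))
  expect_equal(length(tol), 3)

  expect_warning(none <- find_reaction_centers(tautomer_of("CCO")),
                 "no EAS sites")
  expect_equal(length(none), 0)
})

test_that("symmetry classes agree with the brute-force automorphism oracle", {
  for (smi in c("c1ccccc1", "Fc1ccccc1", "Cc1ccccc1", "c1ccncc1",
                "c1cc[nH]c1", "COc1ccccc1", "O=c1cccc[nH]1",
                "c1ccc2[nH]ccc2c1", "c1ccc2[nH]ccc2n1")) {
    mg <- ns$mg_from_smiles(smi)
    got <- ns$mg_symmetry_classes(mg)
    want <- brute_force_orbits(mg)
    expect_true(same_partition(got, want), info = smi)
  }
})

test_that("protonation builds the arenium ion with consistent bookkeeping", {
  t <- tautomer_of("c1ccccc1")
  ct <- find_reaction_centers(t)[[1]]
  p <- protonate(t, ct)
  expect_equal(ns$mg_formula(p$graph), "C6H7")
  expect_equal(ns$mg_net_charge(p$graph), 1)

  # two equivalent atoms of one class give the identical canonical species
  fb <- tautomer_of("Fc1ccccc1")
  ortho <- find_reaction_centers(fb)[[1]]
  alt <- ortho
  alt$atom_index <- ortho$equivalent_atoms[2]
  expect_identical(protonate(fb, ortho)$smiles, protonate(fb, alt)$smiles)

  # para attack: 7 heavy atoms, +1, para carbon now carries two hydrogens
  para <- Filter(function(ct) length(ct$equivalent_atoms) == 1,
                 find_reaction_centers(fb))[[1]]
  pp <- protonate(fb, para)
  expect_equal(sum(pp$graph$elements != "H"), 7)
  expect_equal(ns$mg_net_charge(pp$graph), 1)
  expect_equal(ns$mg_nH(pp$graph)[para$atom_index], 2)
})

test_that("proton affinity is the neutral/protonated energy difference", {
  expect_equal(proton_affinity(-1000, -1085), 85)
  expect_equal(proton_affinity(energy_value(-50), energy_value(-50)), 0)
  expect_equal(proton_affinity(-1000 + 500, -1085 + 500), 85)
  expect_error(
    proton_affinity(energy_value(60000, TRUE), energy_value(-100)),
    "sentinel")
})

test_that("site selection labels by deficit with inclusive windows", {
  sites <- select_sites(c(a = 90.0, b = 89.5, c = 88.5, d = 86.0))
  labels <- vapply(sites, `[[`, character(1), "label")
  expect_equal(labels, c("green", "green", "red", "none"))
  expect_equal(vapply(sites, `[[`, numeric(1), "deficit"),
               c(0, 0.5, 1.5, 4))

  expect_equal(select_sites(c(x = 77))[[1]]$label, "green")
  expect_true(all(vapply(select_sites(c(a = 5, b = 5, c = 5)), `[[`,
                         character(1), "label") == "green"))

  # boundary: deficits of exactly 1 and 3 are inside their windows
  edge <- vapply(select_sites(c(90, 89, 87, 86.999)), `[[`,
                 character(1), "label")
  expect_equal(edge, c("green", "green", "red", "none"))
  expect_error(select_sites(numeric(0)))
})

test_that("site labels partition sites and the argmax is always green", {
  set.seed(11)
  for (rep in 1:25) {
    pas <- round(runif(sample(2:7, 1), 60, 95), 2)
    sites <- select_sites(pas)
    labels <- vapply(sites, `[[`, character(1), "label")
    expect_true(all(labels %in% c("green", "red", "none")))
    expect_equal(labels[which.max(pas)], "green")
    deficits <- vapply(sites, `[[`, numeric(1), "deficit")
    expect_true(all(deficits[labels != "none"] <= 3))
    expect_true(all(deficits[labels == "none"] > 3))
  }
})

test_that("reactivity classification uses the closed 70-100 band", {
  expect_equal(classify_reactivity(65), "low")
  expect_equal(classify_reactivity(85), "medium")
  expect_equal(classify_reactivity(105), "high")
  expect_equal(classify_reactivity(70), "medium")
  expect_equal(classify_reactivity(100), "medium")
  # monotone in pa_max
  cls <- vapply(c(10, 69.9, 70, 88, 100, 100.1, 140), classify_reactivity, "")
  ranks <- match(cls, c("low", "medium", "high"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("reports order tautomers and take reactivity from the most stable", {
  m <- parse_input("c1ccccc1", "benzene")
  mk_tr <- function(rel, reactivity, no_sites = FALSE) {
    t <- structure(list(smiles = "x", graph = NULL, rel_energy = rel,
                        is_input = rel == 0, stereo_stripped = FALSE),
                   class = "tautomer")
    list(tautomer = t, sites = list(), pa_max = if (no_sites) NA_real_ else 80,
         reactivity = if (no_sites) NA_character_ else reactivity,
         no_sites = no_sites, not_evaluated = list())
  }
  r <- build_report(m, list(mk_tr(4, "high"), mk_tr(0, "medium")))
  expect_equal(vapply(r$tautomer_results, function(tr) tr$tautomer$rel_energy,
                      numeric(1)), c(0, 4))
  expect_equal(r$reactivity_class, "medium")

  # a most-stable form without sites is skipped for the report-level call
  r2 <- build_report(m, list(mk_tr(0, NA, no_sites = TRUE), mk_tr(2, "low")))
  expect_equal(r2$reactivity_class, "low")
})
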