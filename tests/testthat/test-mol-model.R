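# Molecule records, XYZ I/O, distance-based bond perception and unit
# conversion.

test_that("parse_input validates, canonicalizes and counts rotatable bonds", {
  rec <- parse_input("c1ccccc1", "benzene")
  expect_s3_class(rec, "molecule_record")
  expect_equal(rec$n_rot, 0)
  expect_equal(rec$net_charge, 0)
  expect_match(rec$smiles, "c1ccccc1", fixed = TRUE)

  # frozen oracle values (strict rotatable-bond definition)
  oracle <- c("CCO" = 0, "CCCC" = 1, "CCCCC" = 2, "COc1ccccc1" = 1,
              "O=[N+]([O-])c1ccccc1" = 1, "CC(=O)NC" = 0, "CC#CC" = 0,
              "CC(C)(C)C" = 0, "CCOCC" = 2, "OCCc1ccccc1" = 2)
  for (smi in names(oracle)) {
    expect_equal(parse_input(smi, smi)$n_rot, unname(oracle[smi]), info = smi)
  }
})

test_that("parse_input rejects bad notation and charged molecules", {
  expect_error(parse_input("notasmiles((", "bad"), "unparseable")
  expect_error(parse_input("c1ccccc1[O-]", "phenolate"), "charge")
  expect_error(parse_input("", "empty"))
})

test_that("XYZ write/read round-trips and flags malformed input", {
  h <- structure3d("H", matrix(0, 1, 3))
  lines <- write_xyz(h)
  expect_equal(length(lines), 3)
  expect_equal(trimws(lines[1]), "1")

  s <- methane_structure()
  rt <- read_xyz(write_xyz(s, energy = -12.5))
  expect_identical(rt$elements, s$elements)
  expect_lt(max(abs(rt$coords - s$coords)), 1e-6)

  expect_error(read_xyz(c("3", "comment", "H 0 0 0")), "malformed")
  expect_error(read_xyz(c("x", "comment")), "atom count")
})

test_that("connectivity is perceived from covalent radii", {
  h2 <- structure3d(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  expect_equal(nrow(perceive_connectivity(h2)), 1)

  far <- structure3d(c("He", "He"), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(nrow(perceive_connectivity(far)), 0)

  # methane: distance-matrix oracle says exactly the 4 C-H pairs bond
  s <- methane_structure()
  bonds <- perceive_connectivity(s)
  d <- as.matrix(dist(s$coords))
  radii <- c(C = 0.76, H = 0.31)[s$elements]
  expected <- which(d <= 1.3 * outer(radii, radii, "+") & upper.tri(d),
                    arr.ind = TRUE)
  expect_equal(nrow(bonds), 4)
  expect_setequal(paste(bonds$i, bonds$j),
                  paste(expected[, 1], expected[, 2]))

  clash <- structure3d(c("C", "C"), rbind(c(0, 0, 0), c(0.1, 0, 0)))
  expect_error(perceive_connectivity(clash), "overlapping")
})

test_that("connectivity_changed detects rebonding and ignores rigid motion", {
  s <- methane_structure()
  expect_false(connectivity_changed(s, s))
  expect_false(connectivity_changed(s, rotate_z(s, 1.1)))

  # proton moved from O to N across a fixture pair
  oh <- structure3d(c("O", "N", "H"),
                    rbind(c(0, 0, 0), c(3, 0, 0), c(0.97, 0, 0)))
  nh <- structure3d(c("O", "N", "H"),
                    rbind(c(0, 0, 0), c(3, 0, 0), c(2.0, 0, 0)))
  expect_true(connectivity_changed(oh, nh))
  expect_identical(connectivity_changed(oh, nh), connectivity_changed(nh, oh))

  expect_error(
    connectivity_changed(s, structure3d("H", matrix(0, 1, 3))),
    "atom sequence")
})

test_that("hartree conversion uses the pinned factor and is linear", {
  expect_identical(hartree_to_kcal(0), 0)
  expect_equal(hartree_to_kcal(1), 627.509474)
  expect_equal(hartree_to_kcal(-0.5), -313.754737)
  for (pair in list(c(0.1, 0.2), c(-1.3, 2.7), c(1e-6, 5))) {
    expect_equal(hartree_to_kcal(sum(pair)),
                 sum(hartree_to_kcal(pair[1]), hartree_to_kcal(pair[2])),
                 tolerance = 1e-9)
  }
})

test_that("energy_value enforces the sentinel invariant", {
  expect_error(energy_value(123, is_sentinel = TRUE), "60000")
  ev <- energy_value(60000, is_sentinel = TRUE)
  expect_true(ev$is_sentinel)
  expect_equal(ev$value, 60000)
})
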