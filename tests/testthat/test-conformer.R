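# Conformer counting, embedding, force-field pre-screen, Butina clustering
# and refinement.

test_that("conformer count follows min(1 + 3 n_rot, 20)", {
  expect_equal(conformer_count(0), 1)
  expect_equal(conformer_count(6), 19)
  expect_equal(conformer_count(7), 20)
  expect_error(conformer_count(-1))
  counts <- conformer_count(0:20)
  expect_true(all(diff(counts) >= 0))
  expect_lte(max(counts), 20)
})

test_that("embedding is deterministic and preserves the atom contract", {
  g <- ns$mg_from_smiles("c1ccccc1")
  e1 <- embed_conformers(g, 1, seed = 90)
  expect_equal(length(e1$members), 1)
  expect_equal(length(e1$members[[1]]$structure$elements), 12)

  e2 <- embed_conformers(g, 1, seed = 90)
  expect_identical(e1$members[[1]]$structure$coords,
                   e2$members[[1]]$structure$coords)

  ge <- ns$mg_from_smiles("CCO")
  e4 <- embed_conformers(ge, 4, seed = 90)
  expect_equal(length(e4$members), 4)
  for (m in e4$members) {
    expect_identical(m$structure$elements, ge$elements)
  }
  e4b <- embed_conformers(ge, 4, seed = 90)
  for (k in seq_along(e4$members)) {
    expect_identical(e4$members[[k]]$structure$coords,
                     e4b$members[[k]]$structure$coords)
  }
})

test_that("pre-screen keeps members strictly within the energy window", {
  spec <- backend_spec("MOCK")
  # surrogate energies 320 + delta for bonded H2 at tuned distances
  e <- make_ensemble(lapply(c(0, 1, 3.5), h2_member), "[H][H]")
  out <- ff_prescreen(e, spec, window = 3)
  rel <- vapply(out$members, `[[`, numeric(1), "energy") - 320
  expect_equal(round(rel, 6), c(0, 1))

  # single conformer is always its own minimum
  single <- ff_prescreen(make_ensemble(list(h2_member(0))), spec)
  expect_equal(length(single$members), 1)

  # minimum member always retained regardless of window
  tiny <- ff_prescreen(make_ensemble(lapply(c(5, 0, 9), h2_member)), spec,
                       window = 0.001)
  expect_equal(min(vapply(tiny$members, `[[`, numeric(1), "energy")), 320)
})

test_that("pre-screen retention grows with the window", {
  spec <- backend_spec("MOCK")
  deltas <- c(0, 0.5, 2, 4, 8)
  sizes <- vapply(c(0.1, 1, 3, 5, 10), function(w) {
    length(ff_prescreen(make_ensemble(lapply(deltas, h2_member)),
                        spec, window = w)$members)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("failed force-field members fall back to the embedded structure", {
  failing <- backend_spec("MOCK", mock_fail = TRUE)
  e <- make_ensemble(lapply(c(0, 2), h2_member))
  out <- ff_prescreen(e, failing)
  expect_equal(length(out$members), 2)
  expect_true(all(vapply(out$members, `[[`, logical(1), "ff_failed")))
  expect_identical(out$members[[1]]$structure$coords,
                   e$members[[1]]$structure$coords)
})

test_that("Butina clustering collapses duplicates and separates distant members", {
  dup <- cluster_butina(make_ensemble(list(he_member(0), he_member(0))))
  expect_equal(length(dup$members), 1)

  far <- cluster_butina(make_ensemble(list(he_member(0), he_member(5))), 0.5)
  expect_equal(length(far$members), 2)
})

test_that("Butina centroids match the brute-force oracle on constructed sets", {
  cases <- list(c(0, 0.2, 0.4, 3, 3.3),
                c(0, 1, 2, 3, 4, 5),
                c(0, 0.1, 0.2, 0.3, 0.4, 0.45),
                c(0, 0.6, 1.2, 1.7, 5, 5.2))
  for (xs in cases) {
    e <- make_ensemble(lapply(xs, he_member))
    d <- abs(outer(xs, xs, "-"))
    want <- brute_force_butina(d, 0.5)
    got <- ns$butina_centroids(d, 0.5)
    expect_equal(got, want, info = paste(xs, collapse = ","))
    clustered <- cluster_butina(e, 0.5)
    expect_equal(length(clustered$members), length(want))
  }
})

test_that("refinement selects the minimum-energy member", {
  spec <- backend_spec("MOCK")
  e <- make_ensemble(lapply(c(5, 0, 2), h2_member))
  out <- refine(e, spec)
  expect_equal(out$best$energy$value, 320, tolerance = 1e-9)
  expect_false(out$best$energy$is_sentinel)
  expect_false(out$all_sentinel)
  expect_equal(out$ensemble$stage, "refined")
  expect_error(suppressWarnings(refine(e, backend_spec("MOCK",
                                                       mock_fail = TRUE))),
               "failed")
})
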