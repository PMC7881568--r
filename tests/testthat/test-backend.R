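# Energy backends: surrogate contract, engine adapter plumbing, sentinel.

test_that("surrogate energy is deterministic and motion-invariant", {
  s <- methane_structure()
  expect_identical(mock_energy(s), mock_energy(s))

  shifted <- s
  shifted$coords <- s$coords + 1
  expect_equal(mock_energy(shifted), mock_energy(s), tolerance = 1e-9)
  expect_equal(mock_energy(rotate_z(s, 0.7)), mock_energy(s),
               tolerance = 1e-9)
})

test_that("the charge term lowers protonated-species energies by 250", {
  s <- methane_structure()
  charged <- s
  charged$charge <- 1L
  expect_equal(mock_energy(s) - mock_energy(charged), 250, tolerance = 1e-9)
})

test_that("MOCK optimization is a no-op with the surrogate energy", {
  s <- h2_structure(2)
  res <- optimize_structure(s, backend_spec("MOCK"))
  expect_true(res$converged)
  expect_identical(res$structure$coords, s$coords)
  expect_equal(res$energy, 322, tolerance = 1e-9)

  res_fail <- optimize_structure(s, backend_spec("MOCK", mock_fail = TRUE))
  expect_false(res_fail$converged)
})

test_that("backend specs echo the methanol dielectric and validate charge", {
  spec <- backend_spec("TB1", "methanol")
  expect_equal(spec$dielectric, 33.6)
  expect_error(backend_spec("TB1", total_charge = 2L))
  expect_error(backend_spec("TB1", multiplicity = 3L))
  expect_equal(backend_spec("MOCK", "water")$dielectric, 78.4)
})

test_that("a missing engine binary raises an actionable error", {
  withr::local_envvar(EASREGIO_XTB = "definitely-not-a-real-engine")
  expect_error(
    optimize_structure(methane_structure(), backend_spec("TB1")),
    "definitely-not-a-real-engine")
})

test_that("engine output parsing finds the final total energy", {
  log <- c("some banner", "   | TOTAL ENERGY       -26.425939358406 Eh   |",
           "gradient stuff", "   | TOTAL ENERGY       -26.426001234567 Eh   |")
  expect_equal(ns$parse_xtb_energy(log),
               -26.426001234567 * 627.509474, tolerance = 1e-8)
  expect_true(is.na(ns$parse_xtb_energy(c("no energy here"))))
})

test_that("the connectivity sentinel replaces energies after rebonding", {
  oh <- structure3d(c("O", "N", "H"),
                    rbind(c(0, 0, 0), c(3, 0, 0), c(0.97, 0, 0)))
  nh <- structure3d(c("O", "N", "H"),
                    rbind(c(0, 0, 0), c(3, 0, 0), c(2.0, 0, 0)))
  ok <- structure(list(structure = oh, energy = -95.2, converged = TRUE,
                       backend_log_path = NULL), class = "optimization_result")
  expect_equal(apply_connectivity_sentinel(oh, ok)$value, -95.2)
  expect_false(apply_connectivity_sentinel(oh, ok)$is_sentinel)

  moved <- ok
  moved$structure <- nh
  ev <- apply_connectivity_sentinel(oh, moved)
  expect_true(ev$is_sentinel)
  expect_equal(ev$value, 60000)

  # sentinel can never win a lowest-energy comparison
  expect_lt(-95.2, ev$value)
})
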