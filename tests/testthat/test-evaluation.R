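# Correct / semi-correct / failed labels and dataset summaries.

test_that("single-prediction labels follow the set-inclusion definition", {
  expect_equal(label_single(c(2), c(2, 4), integer(0)), "Corr")
  expect_equal(label_single(c(2, 4), c(2), c(4)), "Semi")
  expect_equal(label_single(c(5), c(2), c(4)), "Fail")
  expect_error(label_single(integer(0), c(1)), "non-empty")
})

test_that("labels match the definition exhaustively on a 4-site universe", {
  sites <- 1:4
  states <- c("green", "red", "none")
  grids <- expand.grid(s1 = states, s2 = states, s3 = states, s4 = states,
                       stringsAsFactors = FALSE)
  observed_sets <- Filter(length, lapply(0:15, function(mask) {
    sites[bitwAnd(mask, 2^(sites - 1)) > 0]
  }))
  for (g in seq_len(nrow(grids))) {
    assign_state <- unlist(grids[g, ])
    green <- sites[assign_state == "green"]
    red <- sites[assign_state == "red"]
    for (obs in observed_sets) {
      # independent oracle: classify per observed site, then aggregate
      per_site <- vapply(obs, function(s) {
        if (s %in% green) "g" else if (s %in% red) "r" else "n"
      }, character(1))
      want <- if (all(per_site == "g")) "Corr"
              else if (!any(per_site == "n")) "Semi"
              else "Fail"
      expect_identical(label_single(obs, green, red), want)
    }
  }
})

test_that("tautomer-aware labels reduce to the single-form label", {
  set.seed(7)
  for (rep in 1:50) {
    universe <- 1:6
    green <- sample(universe, sample(0:4, 1))
    red <- sample(setdiff(universe, green), sample(0:2, 1))
    obs <- sample(universe, sample(1:3, 1))
    expect_identical(
      label_with_tautomers(obs, list(list(green = green, red = red))),
      label_single(obs, green, red))
  }
})

test_that("adding a tautomer never worsens the label", {
  rank <- function(l) match(l, c("Fail", "Semi", "Corr"))
  set.seed(13)
  for (rep in 1:50) {
    universe <- 1:6
    obs <- sample(universe, sample(1:3, 1))
    taus <- lapply(1:3, function(i) {
      g <- sample(universe, sample(0:4, 1))
      list(green = g, red = sample(setdiff(universe, g), sample(0:2, 1)))
    })
    prev <- "Fail"
    for (k in 1:3) {
      cur <- label_with_tautomers(obs, taus[1:k])
      expect_gte(rank(cur), rank(prev))
      prev <- cur
    }
  }
})

test_that("tautomer labels are existential over the forms", {
  obs <- c(1, 2)
  taus <- list(list(green = c(3), red = c(1, 2)),
               list(green = c(1, 2), red = integer(0)))
  expect_equal(label_with_tautomers(obs, taus), "Corr")
  taus_semi <- list(list(green = c(3), red = integer(0)),
                    list(green = c(1), red = c(2)))
  expect_equal(label_with_tautomers(obs, taus_semi), "Semi")
  expect_equal(label_with_tautomers(c(5), taus), "Fail")
})

test_that("summaries count and rate the labels", {
  s <- summarize_labels(c("Corr", "Corr", "Fail"))
  expect_equal(c(s$n_corr, s$n_semi, s$n_fail), c(2, 0, 1))
  expect_equal(s$success_rate, 66.7)

  expect_equal(summarize_labels(rep("Corr", 8))$success_rate, 100)

  # published-scale sanity: 485/29/21 gives a 90.7% success rate
  big <- summarize_labels(c(rep("Corr", 485), rep("Semi", 29),
                            rep("Fail", 21)))
  expect_equal(big$success_rate, 90.7)
  expect_equal(big$semi_rate, 5.4)
  expect_equal(big$fail_rate, 3.9)
  expect_equal(big$corr_rate + big$semi_rate + big$fail_rate, 100,
               tolerance = 0.1)
})

test_that("observed-site CSVs round-trip with 0-based indices", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(molecule_id = "pyrrole", smiles = "c1cc[nH]c1",
                       observed_sites = "2;4"),
            path, row.names = FALSE)
  recs <- read_observed_csv(path)
  expect_equal(recs[[1]]$observed_sites, c(3, 5))
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(molecule_id = "x", smiles = "C",
                       observed_sites = ""), bad, row.names = FALSE)
  expect_error(read_observed_csv(bad), "malformed|empty")
})
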