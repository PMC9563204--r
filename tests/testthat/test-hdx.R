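# HDX: centroids, uptake, kinetics fits, protection comparison.

test_that("window centroids are intensity-weighted means", {
  sym <- tibble::tibble(mz = seq(500, 502, by = 0.1))
  sym$intensity <- dnorm(sym$mz, 501, 0.4)
  expect_equal(centroid_mz(sym)$centroid_mz, 501, tolerance = 1e-9)

  two <- tibble::tibble(mz = c(500, 502), intensity = c(1, 1))
  expect_equal(centroid_mz(two)$centroid_mz, 501)

  skew <- withr::with_seed(4, tibble::tibble(
    mz = seq(600, 604, by = 0.05),
    intensity = runif(81)
  ))
  oracle <- sum(skew$mz * skew$intensity) / sum(skew$intensity)
  expect_equal(centroid_mz(skew)$centroid_mz, oracle, tolerance = 1e-9)

  # replicate spread
  reps <- dplyr::bind_rows(
    dplyr::mutate(two, replicate = 1),
    dplyr::mutate(tibble::tibble(mz = c(500, 502), intensity = c(1, 3)),
      replicate = 2
    )
  )
  res <- centroid_mz(reps)
  expect_equal(res$n_replicates, 2)
  expect_equal(res$centroid_mz, mean(c(501, 501.5)))

  expect_error(centroid_mz(tibble::tibble(mz = 1:3, intensity = 0)), "zero")
})

test_that("percent deuteration is linear and affine-invariant", {
  expect_equal(deuterium_uptake(500, 500, 505), 0)
  expect_equal(deuterium_uptake(505, 500, 505), 100)
  expect_equal(deuterium_uptake(502.5, 500, 505), 50)
  expect_equal(
    deuterium_uptake(502.5 + 7, 500 + 7, 505 + 7),
    deuterium_uptake(502.5, 500, 505)
  )
  expect_error(deuterium_uptake(502, 505, 505), "exceed")
  # optional D2O-fraction normalization
  expect_equal(
    deuterium_uptake(502.5, 500, 505, d2o_fraction = 0.925, normalize_d2o = TRUE),
    50 / 0.925
  )
})

test_that("exchangeable amide counting follows convention", {
  expect_equal(max_exchangeable_amides("KKVVVVVVVKK"), 9)
  expect_equal(max_exchangeable_amides("APPG"), 1)
  expect_equal(max_exchangeable_amides("AG"), 0)
})

test_that("one-phase kinetics are recovered with calibrated confidence intervals", {
  ok <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    cur <- sim_curve("one-phase", d1 = 80, k1 = 0.5, sd = 2, seed = r)
    f <- fit_uptake(cur, seed = r)
    p <- f$parameters
    good <- f$model == "one-phase" &&
      p$conf_low[p$term == "k"] <= 0.5 && 0.5 <= p$conf_high[p$term == "k"] &&
      p$conf_low[p$term == "dmax"] <= 80 && 80 <= p$conf_high[p$term == "dmax"]
    if (isTRUE(good)) ok <- ok + 1
  }
  expect_gte(ok, 0.8 * n_rep)
})

test_that("a fast+slow biphasic curve selects the two-phase model with k1 > k2", {
  ok <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    cur <- sim_curve("two-phase", d1 = 40, k1 = 5, d2 = 40, k2 = 0.05,
      sd = 2, seed = 200 + r
    )
    f <- fit_uptake(cur, seed = r)
    if (f$model == "two-phase") {
      ok <- ok + 1
      p <- f$parameters
      expect_gt(p$estimate[p$term == "k1"], p$estimate[p$term == "k2"])
    }
  }
  expect_gte(ok, 0.9 * n_rep)
})

test_that("saturated and flat curves trigger the documented overrides", {
  sat <- sim_curve("one-phase", d1 = 95, k1 = 6, sd = 1, seed = 5)
  f <- fit_uptake(sat, seed = 5)
  expect_equal(f$model, "one-phase")
  expect_match(f$selection, "first timepoint")

  flat <- tibble::tibble(
    timepoint_min = c(1, 5, 10, 30, 60),
    pct_d = c(0.1, -0.2, 0.15, 0.05, -0.1), sd = 0.2, n = 3
  )
  ff <- fit_uptake(flat, seed = 1)
  expect_true(ff$no_exchange)
  expect_equal(ff$parameters$estimate[ff$parameters$term == "dmax"], 0)
})

test_that("protection verdicts match construction and are antisymmetric", {
  free <- sim_curve("one-phase", d1 = 98, k1 = 6, sd = 2, seed = 11, id = "v")
  bound <- sim_curve("one-phase", d1 = 45, k1 = 0.5, sd = 2, seed = 12, id = "v")
  cmp <- protection_compare(free, bound)
  expect_equal(cmp$verdict, "protected")
  expect_lt(cmp$max_labeling_bound, 50)
  expect_gt(cmp$max_labeling_free, 90)
  # antisymmetry
  expect_equal(protection_compare(bound, free)$verdict, "deprotected")
  # identical curves
  same <- protection_compare(free, free)
  expect_equal(same$verdict, "no difference")
  expect_true(all(same$table$delta_d == 0))

  # null pairs rarely alarm
  nd <- 0
  for (r in 1:30) {
    a <- sim_curve("one-phase", d1 = 60, k1 = 0.5, sd = 2, seed = 1000 + r)
    b <- sim_curve("one-phase", d1 = 60, k1 = 0.5, sd = 2, seed = 5000 + r)
    if (protection_compare(a, b)$verdict == "no difference") nd <- nd + 1
  }
  expect_gte(nd, 28)

  short <- free[1:4, ]
  expect_error(protection_compare(short, bound), "timepoints")
})
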