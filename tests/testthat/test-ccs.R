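# Projection-approximation CCS: analytic cases, oracle agreement,
# invariances, convergence.

single_atom <- function(r = 2) {
  atomic_model(tibble::tibble(element = "BEAD", x = 0, y = 0, z = 0, radius = r))
}

test_that("a single sphere gives the analytic disc area for any orientation count", {
  m <- single_atom(2)
  for (n in c(2, 10, 100)) {
    est <- pa_ccs(m, probe = 1, n_orientations = n, seed = 1)
    expect_equal(est$value, pi * 3^2, tolerance = 1e-12)
    expect_equal(est$se, 0)
  }
  # Cauchy: mean projection of a convex body = surface / 4 = pi R^2
  expect_equal(pa_ccs_oracle(m, probe = 0.5)$value, pi * 2.5^2, tolerance = 1e-12)
})

test_that("two coincident atoms project like one", {
  m2 <- atomic_model(tibble::tibble(
    element = "BEAD", x = c(0, 0), y = 0, z = 0, radius = 2
  ))
  expect_equal(
    pa_ccs(m2, probe = 1, n_orientations = 10, seed = 1)$value,
    pi * 9, tolerance = 1e-12
  )
})

test_that("scaling is explicit, exact and invertible", {
  est <- pa_ccs(single_atom(2), probe = 1, n_orientations = 5, seed = 1)
  est$value <- 2000
  est$se <- 10
  sc <- scale_ccs(est, 1.14)
  expect_equal(sc$value, 2280)
  expect_equal(sc$se, 11.4)
  expect_equal(sc$scale_factor, 1.14)
  expect_equal(scale_ccs(est, 1)$value, 2000)
  back <- scale_ccs(sc, 1 / 1.14)
  expect_equal(back$value, 2000, tolerance = 1e-12)
  expect_error(scale_ccs(est, 0), "> 0")
  # raw value recoverable from the recorded factor
  expect_equal(sc$value / sc$scale_factor, 2000)
})

test_that("Monte-Carlo agrees with the deterministic oracle on dumbbell and chain", {
  db <- make_geometry("dumbbell", radius = 2, separation = 10)
  mc <- pa_ccs(db, probe = 1, n_orientations = 2000, seed = 3)
  or <- pa_ccs_oracle(db, probe = 1, n_orientations = 800)
  expect_lt(abs(mc$value - or$value), 3 * mc$se)
  expect_lt(abs(mc$value - or$value) / or$value, 0.01)

  ch <- make_geometry("bead_chain", n_beads = 20, radius = 2, seed = 7)
  mcc <- pa_ccs(ch, probe = 1, n_orientations = 600, seed = 4)
  occ <- pa_ccs_oracle(ch, probe = 1, n_orientations = 400)
  expect_lt(abs(mcc$value - occ$value), max(3 * mcc$se, 0.01 * occ$value))
})

test_that("the oracle is converged: doubling its angular grid moves it < 0.1%", {
  db <- make_geometry("dumbbell", radius = 2, separation = 10)
  a <- pa_ccs_oracle(db, probe = 1, n_orientations = 400)$value
  b <- pa_ccs_oracle(db, probe = 1, n_orientations = 800)$value
  expect_lt(abs(a - b) / b, 0.001)
  expect_error(pa_ccs_oracle(random_model(250, 1)), "too large")
})

test_that("CCS is invariant under rigid motion of the model", {
  ch <- make_geometry("bead_chain", n_beads = 10, radius = 2, seed = 9)
  base <- pa_ccs(ch, probe = 1, n_orientations = 400, seed = 5)
  moved <- transform_model(ch, random_rotation(31), c(5, -2, 8))
  after <- pa_ccs(moved, probe = 1, n_orientations = 400, seed = 6)
  expect_lt(abs(base$value - after$value), 3 * sqrt(base$se^2 + after$se^2))
})

test_that("CCS grows with probe radius and with added atoms", {
  ch <- make_geometry("bead_chain", n_beads = 8, radius = 2, seed = 13)
  v1 <- pa_ccs(ch, probe = 0.5, n_orientations = 200, seed = 7)$value
  v2 <- pa_ccs(ch, probe = 1.0, n_orientations = 200, seed = 7)$value
  v3 <- pa_ccs(ch, probe = 2.0, n_orientations = 200, seed = 7)$value
  expect_lt(v1, v2)
  expect_lt(v2, v3)
  bigger <- atomic_model(dplyr::bind_rows(
    ch, tibble::tibble(
      element = "BEAD", atom = "BEAD", x = 30, y = 0, z = 0, chain = "B",
      resno = 1L, resname = "UNK", confidence = NA_real_, radius = 2
    )
  ))
  v4 <- pa_ccs(bigger, probe = 1.0, n_orientations = 200, seed = 7)$value
  expect_gte(v4, v2)
})

test_that("dumbbell CCS is monotone in separation and approaches twice one sphere", {
  one <- pi * 3^2
  seps <- c(0, 2, 5, 10, 25, 100)
  vals <- vapply(seps, function(s) {
    pa_ccs_oracle(
      make_geometry("dumbbell", radius = 2, separation = s),
      probe = 1, n_orientations = 600
    )$value
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
  expect_true(all(vals <= 2 * one + 1e-9))
  # separation 50x radius
  expect_lt(abs(vals[length(vals)] - 2 * one) / (2 * one), 0.01)
})

test_that("Monte-Carlo standard error scales as 1/sqrt(n) over a decade", {
  db <- make_geometry("dumbbell", radius = 2, separation = 6)
  se_small <- mean(vapply(1:8, function(s) {
    pa_ccs(db, probe = 1, n_orientations = 100, seed = s)$se
  }, numeric(1)))
  se_big <- mean(vapply(1:8, function(s) {
    pa_ccs(db, probe = 1, n_orientations = 1000, seed = 100 + s)$se
  }, numeric(1)))
  ratio <- se_small / se_big
  expect_gt(ratio, sqrt(10) * 0.7)
  expect_lt(ratio, sqrt(10) * 1.4)
})

test_that("degenerate inputs are refused", {
  m <- single_atom(2)
  expect_error(pa_ccs(m, n_orientations = 1), "standard error")
  expect_silent(pa_ccs(m, n_orientations = 1, se = FALSE))
  expect_error(pa_ccs(m[0, ], n_orientations = 10), "empty")
})
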