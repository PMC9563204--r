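# Native MS: peak picking, charge-series deconvolution, stoichiometry,
# abundances, titrations.

test_that("peak picking finds noiseless Gaussian centers and ignores noise", {
  mz <- seq(1000, 1100, by = 0.05)
  centers <- c(1020.37, 1050.11, 1080.73)
  y <- rowSums(vapply(centers, function(c0) exp(-0.5 * ((mz - c0) / 0.8)^2),
    numeric(length(mz))
  ))
  pk <- pick_peaks(tibble::tibble(mz = mz, intensity = y))
  expect_equal(nrow(pk), 3)
  expect_true(all(abs(pk$mz - centers) < 0.01))

  # pure noise on a flat baseline yields no peaks at snr 5
  fails <- 0
  for (r in 1:20) {
    noise <- withr::with_seed(r, tibble::tibble(
      mz = seq(1000, 1100, by = 0.1),
      intensity = 10 + rnorm(1001, 0, 1)
    ))
    if (nrow(pick_peaks(noise, min_snr = 5)) > 0) fails <- fails + 1
  }
  expect_lte(fails, 1)

  flat <- tibble::tibble(mz = 1:100, intensity = rep(2, 100))
  expect_equal(nrow(pick_peaks(flat)), 0)
  empty <- tibble::tibble(mz = numeric(), intensity = numeric())
  expect_equal(nrow(pick_peaks(empty)), 0)
})

test_that("charge series give closed-form and ppm-exact masses", {
  pk <- tibble::tibble(mz = c(1001, 501), intensity = 1, width = 1)
  ser <- infer_mass(pk, adduct = 1.0)
  expect_equal(nrow(ser), 1)
  expect_equal(ser$mass_da, 1000)
  expect_equal(sort(ser$charges[[1]]), c(1, 2))

  pk2 <- series_peaks(36600, 12:14)
  ser2 <- infer_mass(pk2)
  expect_equal(nrow(ser2), 1)
  expect_lt(abs(ser2$mass_da - 36600) / 36600 * 1e6, 1)

  # interleaved series from two species are separated
  pk3 <- dplyr::bind_rows(series_peaks(18300, 9:12), series_peaks(36600, 13:15))
  pk3 <- dplyr::arrange(pk3, mz)
  ser3 <- infer_mass(pk3)
  expect_equal(nrow(ser3), 2)
  expect_lt(abs(ser3$mass_da[1] - 18300) / 18300 * 1e6, 1)
  expect_lt(abs(ser3$mass_da[2] - 36600) / 36600 * 1e6, 1)
})

test_that("stoichiometry enumeration matches brute force and flags ambiguity", {
  comp <- tibble::tibble(
    name = c("chaperone", "client"), mass_da = c(18300, 4300),
    max_count = c(3, 2)
  )
  hyp <- assign_stoichiometry(22600, comp, tolerance_ppm = 100)
  expect_equal(nrow(hyp), 1)
  expect_equal(hyp$chaperone, 1)
  expect_equal(hyp$client, 1)
  expect_false(hyp$ambiguous[1])

  # tetramer + one peptide, as in a 1:4 heterocomplex
  comp2 <- tibble::tibble(
    name = c("subunit", "peptide"), mass_da = c(13761, 1955),
    max_count = c(4, 2)
  )
  obs <- 4 * 13761 + 1955
  hyp2 <- assign_stoichiometry(obs, comp2, tolerance_ppm = 10)
  expect_equal(hyp2$subunit[1], 4)
  expect_equal(hyp2$peptide[1], 1)

  # zero tolerance with a noisy mass returns nothing
  expect_equal(nrow(assign_stoichiometry(obs + 0.5, comp2, tolerance_ppm = 0)), 0)
  expect_error(assign_stoichiometry(1000, comp2[0, ]), "empty")

  # randomized agreement with the exhaustive oracle
  for (r in 1:10) {
    withr::with_seed(r, {
      k <- sample(2:5, 1)
      masses <- runif(k, 1000, 20000)
      maxc <- sample(1:6, k, replace = TRUE)
      target_counts <- vapply(maxc, function(m) sample(0:m, 1), integer(1))
      if (sum(target_counts) == 0) target_counts[1] <- 1L
      obs_r <- sum(target_counts * masses) * (1 + rnorm(1, 0, 2e-5))
      comp_r <- tibble::tibble(
        name = paste0("c", 1:k), mass_da = masses, max_count = maxc
      )
      got <- assign_stoichiometry(obs_r, comp_r, tolerance_ppm = 100)
      oracle <- stoichiometry_oracle(obs_r, masses, maxc, 100)
      expect_equal(nrow(got), length(oracle))
      if (nrow(got) > 0) {
        got_sets <- apply(as.matrix(got[, paste0("c", 1:k)]), 1, paste,
          collapse = ","
        )
        orc_sets <- vapply(oracle, paste, character(1), collapse = ",")
        expect_setequal(got_sets, orc_sets)
      }
    })
  }
})

test_that("species abundances normalize to one and recover generator truth", {
  s <- tibble::tibble(species = c("monomer", "trimer"), intensity = c(2, 2))
  expect_equal(species_abundance(s)$fraction, c(0.5, 0.5))
  s2 <- tibble::tibble(species = c("a", "b"), intensity = c(3, 1))
  expect_equal(species_abundance(s2)$fraction, c(0.75, 0.25))
  expect_error(
    species_abundance(tibble::tibble(species = "a", intensity = 0)),
    "zero total"
  )

  sp <- simulate_spectrum(
    tibble::tibble(
      name = c("a", "b"), mass_da = c(18300, 41000), abundance = c(1, 3)
    ),
    peak_width = 1.5, seed = 8
  )
  ser <- infer_mass(pick_peaks(sp))
  ab <- species_abundance(ser)
  expect_equal(sum(ab$fraction), 1, tolerance = 1e-9)
  expect_equal(sort(ab$fraction), c(0.25, 0.75), tolerance = 0.02)
})

test_that("titration transitions are detected with the programmed midpoint", {
  ratios <- c(0.05, 0.1, 0.2, 0.33, 0.6, 1, 2)
  mk <- function(frac, sd = 0.02) {
    tibble::tibble(ratio = ratios, species = "trimer", fraction = frac, sd = sd)
  }
  flat <- titration_transition(mk(rep(0.5, 7)), "trimer")
  expect_equal(flat$verdict, "no transition")

  rising <- titration_transition(
    mk(0.1 + 0.8 / (1 + exp(-2 * (log(ratios) - log(0.3))))), "trimer"
  )
  expect_equal(rising$verdict, "no decline")

  mids <- vapply(1:25, function(r) {
    f <- 0.7 / (1 + exp(2.5 * (log(ratios) - log(0.33)))) + 0.1
    f <- f + withr::with_seed(r, rnorm(7, 0, 0.015))
    titration_transition(mk(f), "trimer")$midpoint_ratio
  }, numeric(1))
  expect_lt(abs(mean(mids, na.rm = TRUE) - 0.33) / 0.33, 0.2)
  expect_gt(mean(!is.na(mids)), 0.9)

  expect_error(
    titration_transition(mk(rep(0.5, 7))[c(1, 1, 2, 3), ], "trimer"),
    "distinct"
  )
})
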