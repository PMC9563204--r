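# Synthetic generators: determinism, recorded truths, end-to-end
# identifiability.

test_that("every generator is deterministic given its seed", {
  g1 <- make_geometry("bead_chain", n_beads = 15, seed = 42)
  g2 <- make_geometry("bead_chain", n_beads = 15, seed = 42)
  expect_identical(g1$x, g2$x)
  expect_false(identical(
    g1$x, make_geometry("bead_chain", n_beads = 15, seed = 43)$x
  ))

  s1 <- simulate_spectrum(
    tibble::tibble(name = "m", mass_da = 20000, abundance = 1),
    noise = 0.01, seed = 9
  )
  s2 <- simulate_spectrum(
    tibble::tibble(name = "m", mass_da = 20000, abundance = 1),
    noise = 0.01, seed = 9
  )
  expect_identical(s1$intensity, s2$intensity)

  cal <- fit_calibration(synth_calibrants())
  a1 <- simulate_atd(3000, cal, 12, 30000, noise = 0.02, seed = 5)
  a2 <- simulate_atd(3000, cal, 12, 30000, noise = 0.02, seed = 5)
  expect_identical(a1$intensity, a2$intensity)

  tr <- tibble::tibble(peptide_id = "p", model = "one-phase", d1 = 70, k1 = 1)
  h1 <- simulate_hdx(tr, seed = 3)
  h2 <- simulate_hdx(tr, seed = 3)
  expect_identical(h1$centroids$centroid_mz, h2$centroids$centroid_mz)
})

test_that("sphere truth matches the analytic projection area", {
  g <- make_geometry("sphere", radius = 3, probe = 1)
  truth <- attr(g, "ground_truth")
  expect_equal(truth$analytic_ccs, pi * 16)
  expect_equal(pa_ccs(g, probe = 1, n_orientations = 5, seed = 1)$value,
    truth$analytic_ccs,
    tolerance = 1e-12
  )
})

test_that("a buried ligand is more compact than a surface-bound one", {
  pocket <- make_geometry("pocket_complex", n_beads = 12, seed = 2)
  surface <- make_geometry("surface_complex", n_beads = 12, seed = 2)
  expect_equal(nrow(pocket), nrow(surface)) # identical composition
  cp <- pa_ccs_oracle(pocket, probe = 1, n_orientations = 200)
  cs <- pa_ccs_oracle(surface, probe = 1, n_orientations = 200)
  expect_lt(cp$value, cs$value)
  # ligand bigger than the host cavity is refused
  expect_error(
    make_geometry("pocket_complex", n_beads = 200, host_radius = 8, seed = 1),
    "pocket"
  )
})

test_that("noiseless spectra place apexes at the exact charge-state m/z", {
  sp <- simulate_spectrum(
    tibble::tibble(
      name = "m", mass_da = 25000, abundance = 1, mean_charge = 10,
      charge_sd = 1
    ),
    peak_width = 1, seed = 1
  )
  truth <- attr(sp, "ground_truth")
  pk <- pick_peaks(sp)
  main <- truth$peaks[truth$peaks$height > 0.05, ]
  for (i in seq_len(nrow(main))) {
    expect_true(any(abs(pk$mz - main$mz[i]) < 0.02))
  }
})

test_that("ATD simulation round-trips and warns outside the calibrated span", {
  cal <- fit_calibration(synth_calibrants())
  atd <- simulate_atd(2900, cal, 11, 28000, seed = 8)
  truth <- attr(atd, "ground_truth")
  expect_false(truth$extrapolated)
  got <- drift_to_ccs(cal, atd_peak(atd)$mode_ms, 11, 28000)
  expect_lt(abs(got - 2900) / 2900, 0.005)
  expect_warning(simulate_atd(9000, cal, 13, 33000, seed = 8), "span")

  # two species 7% apart in CCS resolve at 2% peak width
  a1 <- simulate_atd(3000, cal, 12, 30000, seed = 1)
  a2 <- simulate_atd(3210, cal, 12, 30000, seed = 1)
  m1 <- atd_peak(a1)$mode_ms
  m2 <- atd_peak(a2)$mode_ms
  w <- atd_peak(a1)$fwhm_ms
  expect_gt(abs(m2 - m1), w)
  expect_identical(
    simulate_atd(3000, cal, 12, 30000, seed = 1)$intensity, a1$intensity
  )
})

test_that("zero-noise HDX tables invert exactly through the uptake formula", {
  tr <- tibble::tibble(
    peptide_id = "p", model = "two-phase", d1 = 30, k1 = 4, d2 = 50, k2 = 0.1
  )
  sim <- simulate_hdx(tr, replicate_sd = 0, seed = 1)
  cur <- uptake_curve(
    sim$centroids,
    sim$controls$centroid_undeuterated,
    sim$controls$centroid_fully_deuterated
  )
  expect_equal(cur$pct_d, sim$truth$pct_d$pct_d_true, tolerance = 1e-9)
  expect_true(all(cur$sd < 1e-12))
  expect_error(simulate_hdx(tr, replicate_sd = -1), ">= 0")
})

test_that("generator-programmed titrations are recovered end-to-end", {
  ratios <- c(0.05, 0.12, 0.25, 0.4, 0.8, 1.6)
  trimer_frac <- 0.75 / (1 + exp(2.5 * (log(ratios) - log(0.33)))) + 0.1
  pts <- purrr::map_dfr(seq_along(ratios), function(i) {
    sp <- simulate_spectrum(
      tibble::tibble(
        name = c("monomer", "trimer"),
        mass_da = c(21000, 58000),
        abundance = c(1 - trimer_frac[i], trimer_frac[i])
      ),
      peak_width = 1.5, seed = 100 + i
    )
    ser <- infer_mass(pick_peaks(sp))
    ser$species <- ifelse(ser$mass_da > 40000, "trimer", "monomer")
    ab <- species_abundance(ser)
    tibble::tibble(
      ratio = ratios[i], species = ab$species, fraction = ab$fraction,
      sd = 0.02
    )
  })
  res <- titration_transition(pts, "trimer")
  expect_equal(res$verdict, "transition")
  expect_lt(abs(res$midpoint_ratio - 0.33) / 0.33, 0.35)
})
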