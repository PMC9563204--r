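# Synthetic data with recorded ground truth: toy geometries, native
# spectra, arrival-time distributions, calibrant sets and HDX centroid
# tables. Every generator is deterministic given (seed, parameters),
# and each output carries its truth so downstream stages can be tested
# end-to-end without instrument data.

.truth <- function(...) list(...)

#' Generate a toy geometry with known CCS properties
#'
#' Geometries: `"sphere"` (one atom), `"dumbbell"` (two atoms on the x
#' axis), `"bead_chain"` (seeded self-avoiding random walk),
#' `"pocket_complex"` (ligand chain inside a hollow spherical host
#' shell) and `"surface_complex"` (same composition, ligand on the
#' shell exterior). Spheres and well-separated dumbbells have analytic
#' projection-approximation CCS, recorded in the ground truth.
#'
#' @param kind geometry kind.
#' @param radius atom/bead radius, Angstrom (sphere, dumbbell,
#'   bead_chain).
#' @param separation center separation for `dumbbell`, Angstrom.
#' @param n_beads chain length for `bead_chain` and the ligand of the
#'   complexes.
#' @param bond_length chain step, Angstrom.
#' @param host_radius shell radius of the complex host, Angstrom.
#' @param n_host number of host shell beads.
#' @param host_bead_radius,ligand_bead_radius bead radii of host shell
#'   and ligand chain.
#' @param probe probe radius used for the recorded analytic CCS truth.
#' @param seed integer seed (stochastic kinds reproduce bitwise).
#' @return An `atomic_model` with attribute `ground_truth` (list with
#'   `kind`, `seed`, parameters, and `analytic_ccs` where available).
#' @export
make_geometry <- function(kind = c(
                            "sphere", "dumbbell", "bead_chain",
                            "pocket_complex", "surface_complex"
                          ),
                          radius = 2, separation = 10, n_beads = 20,
                          bond_length = NULL, host_radius = 12,
                          n_host = 60, host_bead_radius = 2,
                          ligand_bead_radius = 1.5, probe = 1, seed = 1L) {
  kind <- match.arg(kind)
  bond_length <- bond_length %||% (2.2 * radius)
  model <- switch(kind,
    sphere = atomic_model(
      tibble(element = "BEAD", x = 0, y = 0, z = 0, chain = "A", radius = radius),
      dialect = "synthetic"
    ),
    dumbbell = atomic_model(
      tibble(
        element = "BEAD", x = c(0, separation), y = 0, z = 0,
        chain = "A", radius = radius
      ),
      dialect = "synthetic"
    ),
    bead_chain = atomic_model(
      .self_avoiding_walk(n_beads, bond_length, 2 * radius, seed) |>
        dplyr::mutate(element = "BEAD", chain = "A", radius = radius),
      dialect = "synthetic"
    ),
    pocket_complex = .make_complex(
      inside = TRUE, n_beads, host_radius, n_host, host_bead_radius,
      ligand_bead_radius, seed
    ),
    surface_complex = .make_complex(
      inside = FALSE, n_beads, host_radius, n_host, host_bead_radius,
      ligand_bead_radius, seed
    )
  )
  analytic <- switch(kind,
    sphere = pi * (radius + probe)^2,
    dumbbell = if (separation >= 20 * (radius + probe)) {
      2 * pi * (radius + probe)^2 # well-separated limit
    } else NA_real_,
    NA_real_
  )
  attr(model, "ground_truth") <- .truth(
    kind = kind, seed = seed, probe = probe,
    radius = radius, separation = separation, n_beads = n_beads,
    analytic_ccs = analytic
  )
  model
}

.self_avoiding_walk <- function(n, step, min_sep, seed, confine = Inf) {
  withr::with_seed(seed, {
    pos <- matrix(0, n, 3)
    i <- 2
    tries <- 0
    restarts <- 0
    while (i <= n) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1, ] + step * u
      prior <- pos[seq_len(max(0, i - 2)), , drop = FALSE]
      ok <- sqrt(sum(cand^2)) <= confine &&
        (nrow(prior) == 0 ||
           all(sqrt(rowSums(sweep(prior, 2, cand)^2)) >= min_sep))
      if (ok) {
        pos[i, ] <- cand
        i <- i + 1
        tries <- 0
      } else {
        tries <- tries + 1
        if (tries > 200) { # walk trapped; restart
          i <- 2
          tries <- 0
          restarts <- restarts + 1
          if (restarts > 100) abort("self-avoiding walk cannot be placed")
        }
      }
    }
    tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3])
  })
}

.make_complex <- function(inside, n_beads, host_radius, n_host,
                          host_bead_radius, ligand_bead_radius, seed) {
  shell <- .fibonacci_sphere(n_host) * host_radius
  inner <- host_radius - host_bead_radius
  lig_step <- 2.2 * ligand_bead_radius
  # the ligand walk is confined to the cavity interior; refuse ligands
  # that cannot pack into it (random packing needs roughly
  # r * (n / 0.4)^(1/3) of radial room)
  confine <- 0.9 * (inner - ligand_bead_radius)
  needed <- ligand_bead_radius * (n_beads / 0.4)^(1 / 3)
  if (confine <= lig_step || needed > confine) {
    abort("ligand larger than pocket: shrink the ligand or grow the host")
  }
  lig <- .self_avoiding_walk(
    n_beads, lig_step, 2 * ligand_bead_radius, seed, confine = confine
  )
  lig_xyz <- as.matrix(lig)
  if (!inside) {
    dir <- withr::with_seed(seed + 1L, {
      v <- rnorm(3)
      v / sqrt(sum(v^2))
    })
    lig_xyz <- sweep(lig_xyz, 2, colMeans(lig_xyz))
    span <- max(sqrt(rowSums(lig_xyz^2))) + ligand_bead_radius
    lig_xyz <- sweep(lig_xyz, 2, -(host_radius + host_bead_radius + span) * dir)
  }
  atomic_model(
    dplyr::bind_rows(
      tibble(
        element = "BEAD", x = shell[, 1], y = shell[, 2], z = shell[, 3],
        chain = "H", radius = host_bead_radius
      ),
      tibble(
        element = "BEAD", x = lig_xyz[, 1], y = lig_xyz[, 2],
        z = lig_xyz[, 3], chain = "L", radius = ligand_bead_radius
      )
    ),
    dialect = "synthetic"
  )
}

#' Native-like mean charge for a neutral mass
#'
#' The native ESI charge heuristic `z = 0.0778 * sqrt(M)`.
#'
#' @param mass_da neutral mass, Da.
#' @return Mean charge (not rounded).
#' @export
native_charge <- function(mass_da) 0.0778 * sqrt(mass_da)

#' Simulate a native mass spectrum
#'
#' Each species contributes Gaussian peaks at `(M + z m_adduct)/z` for
#' integer charges weighted by a discretized Gaussian envelope around
#' its mean charge; peak apex heights are `abundance * envelope
#' weight`, so apex-summed species abundances are recoverable.
#' Additive Gaussian noise (clamped at zero) is seeded.
#'
#' @param species data frame with columns `name`, `mass_da`,
#'   `abundance` (> 0) and optionally `mean_charge` (default native
#'   heuristic) and `charge_sd` (default 1).
#' @param peak_width Gaussian sigma of each peak, Th (default 2).
#' @param noise additive noise SD as a fraction of the tallest peak
#'   (default 0).
#' @param seed integer seed.
#' @param mz_step grid spacing, Th (default `peak_width / 6`).
#' @param adduct adduct mass per charge (default proton).
#' @return Tibble `mz`, `intensity` with attribute `ground_truth`
#'   (species table expanded with per-charge peak centers and heights).
#' @export
simulate_spectrum <- function(species, peak_width = 2, noise = 0, seed = 1L,
                              mz_step = NULL, adduct = 1.007276) {
  sp <- as_tibble(species)
  if (nrow(sp) == 0) abort("no species to simulate")
  stopifnot(all(c("name", "mass_da", "abundance") %in% names(sp)))
  if (any(sp$abundance <= 0)) abort("abundances must be > 0")
  if (!"mean_charge" %in% names(sp)) sp$mean_charge <- native_charge(sp$mass_da)
  if (!"charge_sd" %in% names(sp)) sp$charge_sd <- 1
  if (any(sp$mean_charge < 1)) abort("mean charges must be >= 1")
  mz_step <- mz_step %||% (peak_width / 6)
  peaks <- purrr::pmap_dfr(sp, function(name, mass_da, abundance,
                                        mean_charge, charge_sd, ...) {
    z <- seq(
      max(1, floor(mean_charge - 4 * charge_sd)),
      ceiling(mean_charge + 4 * charge_sd)
    )
    wz <- exp(-0.5 * ((z - mean_charge) / charge_sd)^2)
    wz <- wz / sum(wz)
    tibble(
      name = name, mass_da = mass_da, charge = z,
      mz = (mass_da + z * adduct) / z,
      height = abundance * wz
    )
  })
  rng <- range(peaks$mz)
  mz <- seq(rng[1] - 12 * peak_width, rng[2] + 12 * peak_width, by = mz_step)
  intensity <- rep(0, length(mz))
  for (k in seq_len(nrow(peaks))) {
    intensity <- intensity +
      peaks$height[k] * exp(-0.5 * ((mz - peaks$mz[k]) / peak_width)^2)
  }
  if (noise > 0) {
    intensity <- intensity + withr::with_seed(
      seed, rnorm(length(mz), 0, noise * max(intensity))
    )
    intensity[intensity < 0] <- 0
  }
  out <- tibble(mz = mz, intensity = intensity)
  attr(out, "ground_truth") <- .truth(
    seed = seed, species = sp, peaks = peaks, peak_width = peak_width,
    noise = noise, adduct = adduct
  )
  out
}

#' Simulate an arrival-time distribution for a known CCS
#'
#' Inverts a fitted calibration to place a Gaussian arrival-time peak
#' where an ion of the given CCS, charge and mass would appear.
#'
#' @param ccs_A2 true CCS, Angstrom^2.
#' @param cal a `twims_calibration`.
#' @param charge ion charge.
#' @param mass_da neutral mass, Da.
#' @param width_ms Gaussian sigma of the ATD, ms (default 0.25).
#' @param noise additive noise SD as a fraction of the apex (default 0).
#' @param seed integer seed.
#' @param n_bins number of bins (default 201).
#' @return Tibble `arrival_ms`, `intensity` with attribute
#'   `ground_truth` (true CCS, true arrival time, and an
#'   `extrapolated` flag when the CCS lies outside the calibrated
#'   span, which also raises a warning).
#' @export
simulate_atd <- function(ccs_A2, cal, charge, mass_da, width_ms = 0.25,
                         noise = 0, seed = 1L, n_bins = 201) {
  if (ccs_A2 <= 0) abort("CCS must be > 0")
  mu <- .reduced_mass(mass_da, cal$gas_mass)
  ccs_corr <- ccs_A2 * sqrt(mu) / charge
  t_corr <- (ccs_corr / exp(cal$intercept))^(1 / cal$slope)
  mz <- (mass_da + charge * .m_proton) / charge
  t_true <- t_corr + cal$edc_coeff * sqrt(mz) / 1000
  span <- range(cal$calibrants$ccs_corr)
  extrapolated <- ccs_corr < span[1] || ccs_corr > span[2]
  if (extrapolated) {
    warn("true CCS lies outside the calibrated span; ATD is an extrapolation")
  }
  arrival <- seq(t_true - 6 * width_ms, t_true + 6 * width_ms,
    length.out = n_bins
  )
  intensity <- exp(-0.5 * ((arrival - t_true) / width_ms)^2)
  if (noise > 0) {
    intensity <- intensity +
      withr::with_seed(seed, rnorm(n_bins, 0, noise))
    intensity[intensity < 0] <- 0
  }
  out <- tibble(arrival_ms = arrival, intensity = intensity)
  attr(out, "ground_truth") <- .truth(
    seed = seed, ccs_A2 = ccs_A2, arrival_ms = t_true, charge = charge,
    mass_da = mass_da, width_ms = width_ms, noise = noise,
    extrapolated = extrapolated
  )
  out
}

#' Generate a noiseless synthetic calibrant table
#'
#' Calibrants constructed to lie exactly on a chosen power-law
#' calibration, for round-trip and recovery tests.
#'
#' @param slope,intercept the log-log calibration line.
#' @param masses,charges,ccs_ref_A2 calibrant properties (equal
#'   lengths).
#' @param gas_mass,edc_coeff instrument constants (defaults as in
#'   [fit_calibration()]).
#' @return Calibrant tibble suitable for [fit_calibration()], with
#'   attribute `ground_truth` recording the generating line.
#' @export
synth_calibrants <- function(slope = 0.55, intercept = 5.5,
                             masses = c(12000, 18000, 28000, 36000, 52000),
                             charges = c(7, 9, 11, 13, 15),
                             ccs_ref_A2 = c(1700, 2300, 2900, 3500, 4300),
                             gas_mass = 28.0134, edc_coeff = 1.41) {
  stopifnot(length(masses) == length(charges), length(masses) == length(ccs_ref_A2))
  mu <- .reduced_mass(masses, gas_mass)
  ccs_corr <- ccs_ref_A2 * sqrt(mu) / charges
  t_corr <- (ccs_corr / exp(intercept))^(1 / slope)
  mz <- (masses + charges * .m_proton) / charges
  out <- tibble(
    species = paste0("cal", seq_along(masses)),
    mass_da = masses, charge = charges, ccs_ref_A2 = ccs_ref_A2,
    arrival_ms = t_corr + edc_coeff * sqrt(mz) / 1000,
    basis = "N2"
  )
  attr(out, "ground_truth") <- .truth(
    slope = slope, intercept = intercept, gas_mass = gas_mass,
    edc_coeff = edc_coeff
  )
  out
}

.uptake_model <- function(t, model, d1, k1, d2 = NA, k2 = NA) {
  if (model == "one-phase") {
    d1 * (1 - exp(-k1 * t))
  } else {
    d1 * (1 - exp(-k1 * t)) + d2 * (1 - exp(-k2 * t))
  }
}

#' Simulate triplicate HDX centroid tables
#'
#' Generates per-replicate centroid m/z values for peptides whose true
#' deuterium uptake follows one- or two-phase association kinetics,
#' inverting the uptake formula so that [deuterium_uptake()] recovers
#' the programmed %D exactly at zero noise.
#'
#' @param truth data frame with columns `peptide_id`, `model`
#'   (`"one-phase"` or `"two-phase"`), `d1`, `k1` (amplitude %, rate
#'   min^-1) and for two-phase `d2`, `k2`; optionally `m0`
#'   (undeuterated centroid, default spaced from 500 Th) and
#'   `delta_full` (fully-deuterated mass shift, default 5 Th).
#' @param timepoints labelling times, min (default 1, 5, 10, 30, 60).
#' @param replicate_sd replicate noise on %D, percentage points
#'   (default 2).
#' @param n_replicates replicates per timepoint (default 3).
#' @param d2o_fraction labelling-buffer deuterium content (recorded).
#' @param seed integer seed.
#' @return List with `centroids` (peptide_id, timepoint_min, replicate,
#'   centroid_mz), `controls` (peptide_id, centroid_undeuterated,
#'   centroid_fully_deuterated), and `truth` (input truth plus seed and
#'   the per-timepoint true %D).
#' @export
simulate_hdx <- function(truth, timepoints = c(1, 5, 10, 30, 60),
                         replicate_sd = 2, n_replicates = 3,
                         d2o_fraction = 0.925, seed = 1L) {
  tr <- as_tibble(truth)
  stopifnot(all(c("peptide_id", "model", "d1", "k1") %in% names(tr)))
  if (replicate_sd < 0) abort("replicate SD must be >= 0")
  if (any(tr$k1 <= 0, na.rm = TRUE)) abort("rates must be > 0")
  if (!"d2" %in% names(tr)) tr$d2 <- NA_real_
  if (!"k2" %in% names(tr)) tr$k2 <- NA_real_
  if (any(tr$model == "two-phase" & (is.na(tr$k2) | tr$k2 <= 0))) {
    abort("two-phase truth needs positive k2")
  }
  if (!"m0" %in% names(tr)) tr$m0 <- 500 + 10 * seq_len(nrow(tr))
  if (!"delta_full" %in% names(tr)) tr$delta_full <- 5
  true_pd <- purrr::pmap_dfr(tr, function(peptide_id, model, d1, k1, d2, k2,
                                          m0, delta_full, ...) {
    tibble(
      peptide_id = peptide_id, timepoint_min = timepoints,
      pct_d_true = .uptake_model(timepoints, model, d1, k1, d2, k2)
    )
  })
  centroids <- withr::with_seed(seed, {
    purrr::pmap_dfr(tr, function(peptide_id, model, d1, k1, d2, k2,
                                 m0, delta_full, ...) {
      pd <- .uptake_model(timepoints, model, d1, k1, d2, k2)
      tidyr::expand_grid(
        timepoint_min = timepoints, replicate = seq_len(n_replicates)
      ) |>
        dplyr::mutate(
          peptide_id = peptide_id,
          pct_d_noisy = pd[match(.data$timepoint_min, timepoints)] +
            rnorm(dplyr::n(), 0, replicate_sd),
          centroid_mz = m0 + .data$pct_d_noisy / 100 * delta_full
        ) |>
        dplyr::select(
          "peptide_id", "timepoint_min", "replicate", "centroid_mz"
        )
    })
  })
  list(
    centroids = centroids,
    controls = tibble(
      peptide_id = tr$peptide_id,
      centroid_undeuterated = tr$m0,
      centroid_fully_deuterated = tr$m0 + tr$delta_full
    ),
    truth = c(
      .truth(seed = seed, replicate_sd = replicate_sd,
             d2o_fraction = d2o_fraction, timepoints = timepoints),
      list(parameters = tr, pct_d = true_pd)
    )
  )
}
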