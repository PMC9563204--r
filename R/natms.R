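# Native mass spectrometry: peak picking, charge-state deconvolution to
# neutral masses, stoichiometry assignment, species abundances and
# titration transitions.

#' Pick peaks from a mass spectrum
#'
#' Local maxima exceeding `min_snr` times the robust noise level
#' (median absolute deviation about the median intensity) are kept and
#' centroided by a three-point parabola. A flat or empty spectrum
#' yields an empty peak list, not an error.
#'
#' @param spectrum data frame with columns `mz` (strictly increasing)
#'   and `intensity` (>= 0).
#' @param min_snr signal-to-noise threshold (default 5).
#' @param min_width minimum estimated peak FWHM in Th (default 0,
#'   i.e. no width filter).
#' @return Tibble with columns `mz` (centroid), `intensity` (apex) and
#'   `width` (FWHM estimate, Th).
#' @export
pick_peaks <- function(spectrum, min_snr = 5, min_width = 0) {
  sp <- as_tibble(spectrum)
  stopifnot(all(c("mz", "intensity") %in% names(sp)))
  empty <- tibble(mz = numeric(), intensity = numeric(), width = numeric())
  if (nrow(sp) < 3) return(empty)
  x <- sp$mz
  y <- sp$intensity
  noise <- mad(y, center = median(y))
  floor_level <- median(y) + min_snr * noise
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max & y > floor_level)
  if (length(idx) == 0) return(empty)
  peaks <- purrr::map_dfr(idx, function(i) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (denom != 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    step <- (x[i + 1] - x[i - 1]) / 2
    apex <- y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta
    # sigma of the interpolating parabola treated as Gaussian apex
    sigma2 <- if (denom < 0) -apex / denom * step^2 else NA_real_
    width <- if (is.finite(sigma2)) 2 * sqrt(2 * log(2) * sigma2) else step
    tibble(mz = x[i] + delta * step, intensity = apex, width = width)
  })
  peaks <- peaks[is.na(peaks$width) | peaks$width >= min_width, , drop = FALSE]
  dplyr::arrange(peaks, .data$mz)
}

# neutral mass implied by a peak at m/z p carrying charge z
.implied_mass <- function(p, z, adduct) z * (p - adduct)

# predicted m/z of mass M at charge z
.predicted_mz <- function(M, z, adduct) M / z + adduct

#' Infer neutral masses from charge-state series
#'
#' Searches the peak list for series of consecutive charge states of a
#' common neutral mass. For a candidate peak pair (p1 > p2) the charge
#' of p1 is `round((p2 - adduct) / (p1 - p2))`; a series is extended
#' greedily across charges while the per-peak implied masses agree
#' within `tolerance_ppm`. Series are accepted largest-first and their
#' peaks removed, so interleaved series from several species are
#' resolved.
#'
#' @param peaks peak list as from [pick_peaks()] (columns `mz`,
#'   `intensity`; `width` optional).
#' @param adduct adduct mass per charge, Da (default proton, positive
#'   mode).
#' @param tolerance_ppm agreement tolerance between per-peak implied
#'   masses (default 50).
#' @param max_charge largest charge considered (default 100).
#' @return Tibble, one row per series: `species` (running id), `mass_da`,
#'   `mass_sd_da`, `n_charges`, `charges` (list), `peak_mz` (list),
#'   `intensity` (summed apex intensity).
#' @export
infer_mass <- function(peaks, adduct = 1.007276, tolerance_ppm = 50,
                       max_charge = 100) {
  pk <- dplyr::arrange(as_tibble(peaks), dplyr::desc(.data$mz))
  out <- list()
  while (nrow(pk) >= 2) {
    best <- NULL
    for (i in seq_len(nrow(pk) - 1)) {
      for (j in (i + 1):nrow(pk)) {
        dp <- pk$mz[i] - pk$mz[j]
        if (dp <= 0) next
        z_raw <- (pk$mz[j] - adduct) / dp
        z <- round(z_raw)
        if (z < 1 || z > max_charge) next
        M <- .implied_mass(pk$mz[i], z, adduct)
        if (M <= 0) next
        tol_da <- tolerance_ppm * M / 1e6
        if (abs(.implied_mass(pk$mz[j], z + 1, adduct) - M) > tol_da) next
        # collect all peaks matching this mass at any charge
        members <- integer()
        charges <- integer()
        for (zz in seq_len(max_charge)) {
          pred <- .predicted_mz(M, zz, adduct)
          k <- which(abs(pk$mz - pred) * zz <= tol_da)
          if (length(k) > 0) {
            k <- k[which.min(abs(pk$mz[k] - pred))]
            members <- c(members, k)
            charges <- c(charges, zz)
          }
        }
        if (length(members) < 2) next
        # a physical charge-state envelope is a consecutive run; keep the
        # run containing the seed charge (guards against harmonically
        # related masses claiming each other's peaks)
        run_id <- cumsum(c(1L, as.integer(diff(charges) != 1L)))
        seed_run <- run_id[match(z, charges)]
        if (is.na(seed_run)) {
          seed_run <- as.integer(names(which.max(table(run_id))))
        }
        keep_run <- run_id == seed_run
        members <- members[keep_run]
        charges <- charges[keep_run]
        if (length(members) < 2) next
        masses <- .implied_mass(pk$mz[members], charges, adduct)
        if (max(masses) - min(masses) > 2 * tol_da) next
        cand <- list(members = members, charges = charges, masses = masses)
        if (is.null(best) ||
            length(cand$members) > length(best$members) ||
            (length(cand$members) == length(best$members) &&
             sd(cand$masses) < sd(best$masses))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    out[[length(out) + 1]] <- tibble(
      mass_da = mean(best$masses),
      mass_sd_da = if (length(best$masses) > 1) sd(best$masses) else 0,
      n_charges = length(best$charges),
      charges = list(best$charges),
      peak_mz = list(pk$mz[best$members]),
      intensity = sum(pk$intensity[best$members])
    )
    pk <- pk[-best$members, , drop = FALSE]
  }
  if (length(out) == 0) {
    return(tibble(
      species = integer(), mass_da = numeric(), mass_sd_da = numeric(),
      n_charges = integer(), charges = list(), peak_mz = list(),
      intensity = numeric()
    ))
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$mass_da)
  dplyr::bind_cols(tibble(species = seq_len(nrow(res))), res)
}

#' Assign subunit stoichiometries to an observed mass
#'
#' Exhaustively enumerates component count combinations within the
#' given bounds and returns those whose total mass matches the observed
#' neutral mass within a ppm tolerance, sorted by absolute error
#' (ties broken by fewer total subunits). Ambiguity — more than one
#' hypothesis within tolerance — is flagged, never silently resolved.
#'
#' @param observed_mass_da observed neutral mass, Da.
#' @param components data frame with columns `name`, `mass_da` (> 0)
#'   and `max_count` (>= 0 integer bound per component).
#' @param tolerance_ppm acceptance tolerance (default 100).
#' @return Tibble with one count column per component plus
#'   `theoretical_mass_da`, `error_ppm`, `n_subunits`, `ambiguous`.
#' @export
assign_stoichiometry <- function(observed_mass_da, components,
                                 tolerance_ppm = 100) {
  comp <- as_tibble(components)
  if (nrow(comp) == 0) abort("component list is empty")
  stopifnot(all(c("name", "mass_da", "max_count") %in% names(comp)))
  if (any(comp$mass_da <= 0)) abort("component masses must be > 0")
  grid <- expand.grid(
    lapply(setNames(comp$max_count, comp$name), function(m) 0:m),
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  theo <- as.matrix(grid) %*% comp$mass_da
  err <- 1e6 * (theo - observed_mass_da) / observed_mass_da
  keep <- abs(err) <= tolerance_ppm
  res <- as_tibble(grid[keep, , drop = FALSE])
  res$theoretical_mass_da <- theo[keep]
  res$error_ppm <- err[keep]
  res$n_subunits <- rowSums(grid[keep, , drop = FALSE])
  res <- dplyr::arrange(res, abs(.data$error_ppm), .data$n_subunits)
  res$ambiguous <- nrow(res) >= 2
  res
}

#' Fractional species abundances from assigned charge series
#'
#' Abundance of a species is the sum of member-peak apex intensities
#' over all of its charge states, normalized to 1 across species.
#'
#' @param series data frame with columns `species` (label) and
#'   `intensity` (summed apex intensity per series), as from
#'   [infer_mass()] after labelling.
#' @return Tibble `species`, `intensity`, `fraction` (sums to 1).
#' @export
species_abundance <- function(series) {
  s <- as_tibble(series)
  stopifnot(all(c("species", "intensity") %in% names(s)))
  s <- dplyr::summarise(
    dplyr::group_by(s, .data$species),
    intensity = sum(.data$intensity), .groups = "drop"
  )
  total <- sum(s$intensity)
  if (total <= 0) abort("zero total intensity")
  s$fraction <- s$intensity / total
  s
}

#' Locate a titration transition for one species
#'
#' Fits a four-parameter logistic in log molar ratio to the fractional
#' abundance of the named species, weighted by replicate SD, and
#' compares it against a flat (no-transition) model. The verdict is
#' `"transition"` only when the sigmoid fits decisively better (small-
#' sample corrected information criterion) and describes a decline.
#'
#' @param points data frame with columns `ratio` (ligand:protein molar
#'   ratio, > 0, distinct), `species`, `fraction` (0-1) and optionally
#'   `sd` (replicate SD; zero/absent SDs fall back to equal weights).
#' @param species which species' fraction to model.
#' @return One-row tibble: `midpoint_ratio` (ratio at half-maximal
#'   decline; `NA` unless a transition is supported), `verdict`
#'   (`"transition"`, `"no transition"` or `"no decline"`),
#'   `fraction_high`, `fraction_low` (fitted asymptotes), `delta_aicc`
#'   (flat minus sigmoid; positive favours the sigmoid).
#' @export
titration_transition <- function(points, species) {
  pts <- dplyr::filter(as_tibble(points), .data$species == !!species)
  stopifnot(all(c("ratio", "fraction") %in% names(pts)))
  if (nrow(pts) < 4) abort("need >= 4 titration points")
  if (anyDuplicated(pts$ratio)) abort("titration ratios must be distinct")
  pts <- dplyr::arrange(pts, .data$ratio)
  if (!"sd" %in% names(pts) || !any(is.finite(pts$sd) & pts$sd > 0)) {
    pts$sd <- rep(0.02, nrow(pts))
  }
  pts$sd[!is.finite(pts$sd) | pts$sd <= 0] <- min(pts$sd[pts$sd > 0])
  w <- 1 / pts$sd^2
  lr <- log(pts$ratio)
  f <- pts$fraction

  # flat (null) model
  f0 <- weighted.mean(f, w)
  rss0 <- sum(w * (f - f0)^2)

  # 4PL decline: high asymptote at low ratio, low at high ratio
  start <- list(
    hi = max(f), lo = min(f),
    lmid = median(lr), slope = 2
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fraction ~ lo + (hi - lo) / (1 + exp(slope * (lr - lmid))),
      data = data.frame(fraction = f, lr = lr),
      start = start, weights = w,
      lower = c(hi = 0, lo = 0, lmid = min(lr) - 5, slope = 0.1),
      upper = c(hi = 1.5, lo = 1.5, lmid = max(lr) + 5, slope = 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )

  n <- length(f)
  aicc <- function(rss, k) {
    n * log(rss / n) + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  }
  out <- tibble(
    midpoint_ratio = NA_real_, verdict = "no transition",
    fraction_high = f0, fraction_low = f0, delta_aicc = NA_real_
  )
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  rss1 <- sum(w * residuals(fit)^2)
  d_aicc <- aicc(rss0, 1) - aicc(rss1, 4)
  out$delta_aicc <- d_aicc
  out$fraction_high <- unname(cf["hi"])
  out$fraction_low <- unname(cf["lo"])
  declining <- cf["hi"] > cf["lo"] + 1e-6
  if (!declining && d_aicc > 2) {
    out$verdict <- "no decline"
    return(out)
  }
  if (declining && d_aicc > 2) {
    out$verdict <- "transition"
    out$midpoint_ratio <- exp(unname(cf["lmid"]))
  }
  out
}
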