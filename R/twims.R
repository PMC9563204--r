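# Traveling-wave ion-mobility calibration.
#
# T-wave drift times have no first-principles CCS relation; the standard
# protocol calibrates them against species of known drift-tube CCS:
#   t'  = t - edc * sqrt(m/z) / 1000        (mass-dependent flight-time
#                                            correction; edc is the
#                                            instrument EDC delay
#                                            coefficient, us-scale units)
#   W'  = W_ref * sqrt(mu) / z              (charge / reduced-mass
#                                            corrected CCS; mu is the
#                                            ion-gas reduced mass)
#   ln W' = intercept + slope * ln t'       (power-law fit)
# Analyte CCS then follows by inverting the fit.

.edc_correct <- function(t, mz, edc) t - edc * sqrt(mz) / 1000

.reduced_mass <- function(mass, gas_mass) mass * gas_mass / (mass + gas_mass)

#' Fit a traveling-wave CCS calibration
#'
#' Fits the corrected power-law calibration (log-log linear) of reference
#' CCS against measured arrival time for a set of calibrant ions.
#'
#' @param calibrants data frame with columns `species`, `mass_da`
#'   (neutral mass, Da), `charge` (positive integer), `ccs_ref_A2`
#'   (reference drift-tube CCS, Angstrom^2), `arrival_ms` (measured
#'   arrival time, ms), and optionally `basis` (`"N2"` or `"He"`; must
#'   be uniform — mixing CCS bases within one fit is refused).
#' @param gas_mass drift-gas molecular mass, Da (default nitrogen,
#'   28.0134).
#' @param edc_coeff EDC delay coefficient (default 1.41); the arrival
#'   -time correction subtracted is `edc_coeff * sqrt(m/z) / 1000` ms.
#' @return A `twims_calibration`: list with `slope`, `intercept` (of
#'   ln CCS' on ln t'), `gas_mass`, `edc_coeff`, `basis`, `r_squared`,
#'   and `calibrants` (input plus corrected quantities, fitted values
#'   and residuals).
#' @export
fit_calibration <- function(calibrants, gas_mass = 28.0134, edc_coeff = 1.41) {
  cal <- as_tibble(calibrants)
  need <- c("species", "mass_da", "charge", "ccs_ref_A2", "arrival_ms")
  missing_cols <- setdiff(need, names(cal))
  if (length(missing_cols) > 0) {
    abort(paste0("calibrant table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cal) < 3) {
    abort(paste0("need >= 3 calibrant points, got ", nrow(cal)))
  }
  if (!"basis" %in% names(cal)) cal$basis <- "N2"
  if (length(unique(cal$basis)) > 1) {
    abort("calibrants mix CCS reference bases; fit He and N2 sets separately")
  }
  mz <- (cal$mass_da + cal$charge * .m_proton) / cal$charge
  cal$t_corr_ms <- .edc_correct(cal$arrival_ms, mz, edc_coeff)
  bad <- which(cal$t_corr_ms <= 0)
  if (length(bad) > 0) {
    abort(paste0(
      "non-positive corrected arrival time for calibrant(s): ",
      paste(cal$species[bad], collapse = ", ")
    ))
  }
  mu <- .reduced_mass(cal$mass_da, gas_mass)
  cal$ccs_corr <- cal$ccs_ref_A2 * sqrt(mu) / cal$charge
  fit <- lm(log(ccs_corr) ~ log(t_corr_ms), data = cal)
  cal$fitted_ccs_corr <- exp(fitted(fit))
  cal$residual_ln <- residuals(fit)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      gas_mass = gas_mass,
      edc_coeff = edc_coeff,
      basis = cal$basis[1],
      r_squared = suppressWarnings(summary(fit)$r.squared),
      calibrants = cal,
      fit = fit
    ),
    class = "twims_calibration"
  )
}

#' @export
print.twims_calibration <- function(x, ...) {
  cat(sprintf(
    "T-wave calibration: ln(CCS') = %.4f + %.4f ln(t'), r^2 = %.5f (%d calibrants, %s basis)\n",
    x$intercept, x$slope, x$r_squared, nrow(x$calibrants), x$basis
  ))
  invisible(x)
}

#' @method tidy twims_calibration
#' @export
tidy.twims_calibration <- function(x, ...) {
  dplyr::select(
    x$calibrants,
    dplyr::any_of(c(
      "species", "mass_da", "charge", "ccs_ref_A2", "arrival_ms",
      "t_corr_ms", "ccs_corr", "fitted_ccs_corr", "residual_ln"
    ))
  )
}

#' @method glance twims_calibration
#' @export
glance.twims_calibration <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    n_calibrants = nrow(x$calibrants), gas_mass = x$gas_mass,
    edc_coeff = x$edc_coeff, basis = x$basis
  )
}

#' Convert an arrival time to CCS via a fitted calibration
#'
#' Inverts the power-law calibration:
#' `CCS = exp(intercept) * t'^slope * z / sqrt(mu)`.
#'
#' @param cal a `twims_calibration`.
#' @param arrival_ms measured arrival time(s), ms.
#' @param charge ion charge.
#' @param mass_da neutral mass, Da.
#' @return CCS in Angstrom^2 (vectorized over `arrival_ms`).
#' @export
drift_to_ccs <- function(cal, arrival_ms, charge, mass_da) {
  mz <- (mass_da + charge * .m_proton) / charge
  t_corr <- .edc_correct(arrival_ms, mz, cal$edc_coeff)
  if (any(t_corr <= 0)) abort("corrected arrival time is not positive")
  mu <- .reduced_mass(mass_da, cal$gas_mass)
  exp(cal$intercept) * t_corr^cal$slope * charge / sqrt(mu)
}

#' Apex and width of an arrival-time distribution
#'
#' The apex is located by a three-point parabola through the maximum
#' bin and its neighbours; the full width at half maximum by linear
#' interpolation of the half-height crossings on either side.
#'
#' @param atd data frame with columns `arrival_ms` (strictly
#'   increasing bin centers) and `intensity` (>= 0); at least 5 bins.
#' @return One-row tibble: `mode_ms`, `fwhm_ms`, `apex_intensity`.
#' @export
atd_peak <- function(atd) {
  atd <- as_tibble(atd)
  stopifnot(all(c("arrival_ms", "intensity") %in% names(atd)))
  if (nrow(atd) < 5) abort("need at least 5 ATD bins")
  if (any(diff(atd$arrival_ms) <= 0)) abort("ATD bins must be strictly increasing")
  if (all(atd$intensity == 0)) abort("all-zero ATD")
  t <- atd$arrival_ms
  y <- atd$intensity
  i <- which.max(y)
  if (i > 1 && i < length(y)) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (denom != 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    step <- (t[i + 1] - t[i - 1]) / 2
    mode <- t[i] + delta * step
    apex <- y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta
  } else {
    mode <- t[i]
    apex <- y[i]
  }
  half <- apex / 2
  left <- NA_real_
  for (k in seq_len(i - 1)) {
    if (y[k] <= half && y[k + 1] > half) {
      left <- t[k] + (half - y[k]) / (y[k + 1] - y[k]) * (t[k + 1] - t[k])
    }
  }
  right <- NA_real_
  if (i < length(y)) {
    for (k in seq(i, length(y) - 1)) {
      if (y[k] > half && y[k + 1] <= half) {
        right <- t[k] + (y[k] - half) / (y[k] - y[k + 1]) * (t[k + 1] - t[k])
        break
      }
    }
  }
  tibble(
    mode_ms = mode,
    fwhm_ms = if (is.na(left) || is.na(right)) NA_real_ else right - left,
    apex_intensity = apex
  )
}
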