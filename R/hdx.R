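# Hydrogen-deuterium exchange: centroid masses, percent-deuteration,
# association-kinetics fitting and protection comparison.

#' Intensity-weighted centroid of a spectrum window
#'
#' Computes the intensity-weighted mean m/z of an isotope-envelope
#' window per replicate, and summarises mean and SD across replicates.
#'
#' @param window data frame with columns `mz`, `intensity` and
#'   optionally `replicate`; total intensity per replicate must be
#'   positive.
#' @return One-row tibble: `centroid_mz`, `centroid_sd`, `n_replicates`.
#' @export
centroid_mz <- function(window) {
  w <- as_tibble(window)
  stopifnot(all(c("mz", "intensity") %in% names(w)))
  if (!"replicate" %in% names(w)) w$replicate <- 1L
  per <- dplyr::summarise(
    dplyr::group_by(w, .data$replicate),
    total = sum(.data$intensity),
    centroid = if (sum(.data$intensity) > 0) {
      sum(.data$mz * .data$intensity) / sum(.data$intensity)
    } else NA_real_,
    .groups = "drop"
  )
  if (any(per$total <= 0)) abort("window has zero total intensity")
  tibble(
    centroid_mz = mean(per$centroid),
    centroid_sd = if (nrow(per) > 1) sd(per$centroid) else 0,
    n_replicates = nrow(per)
  )
}

#' Percent deuteration from centroid masses
#'
#' `%D = 100 * (m_t - m_0) / (m_full - m_0)`, where the fully
#' deuterated control centroid `m_full` absorbs back-exchange losses.
#' By default the D2O fraction of the labelling buffer is recorded but
#' not used for further normalization; set `normalize_d2o = TRUE` to
#' additionally divide by the D2O fraction.
#'
#' @param centroid_t centroid at the labelling time.
#' @param centroid_undeuterated undeuterated-control centroid `m_0`.
#' @param centroid_fully_deuterated fully-deuterated-control centroid
#'   `m_full` (must exceed `m_0`).
#' @param d2o_fraction deuterium content of the labelling buffer
#'   (default 0.925).
#' @param normalize_d2o divide %D by `d2o_fraction` (default `FALSE`).
#' @return Percent deuteration (vectorized over `centroid_t`).
#' @export
deuterium_uptake <- function(centroid_t, centroid_undeuterated,
                             centroid_fully_deuterated,
                             d2o_fraction = 0.925, normalize_d2o = FALSE) {
  if (centroid_fully_deuterated <= centroid_undeuterated) {
    abort("fully deuterated centroid must exceed undeuterated centroid")
  }
  pd <- 100 * (centroid_t - centroid_undeuterated) /
    (centroid_fully_deuterated - centroid_undeuterated)
  if (normalize_d2o) pd <- pd / d2o_fraction
  pd
}

#' Build an uptake curve from a replicate centroid table
#'
#' Convenience wrapper converting a long table of per-replicate
#' centroids (plus undeuterated and fully deuterated controls) into a
#' per-timepoint %D summary.
#'
#' @param centroids data frame with columns `peptide_id`,
#'   `timepoint_min`, `replicate`, `centroid_mz`.
#' @param centroid_undeuterated,centroid_fully_deuterated control
#'   centroids for this peptide.
#' @param max_amides number of exchangeable backbone amides (prolines
#'   and the two N-terminal residues excluded), recorded on the curve.
#' @param d2o_fraction labelling-buffer deuterium content.
#' @return An uptake curve: tibble with `timepoint_min`, `pct_d`
#'   (mean), `sd` (replicate SD), `n`, and attributes `peptide_id`,
#'   `max_amides`, `d2o_fraction`.
#' @export
uptake_curve <- function(centroids, centroid_undeuterated,
                         centroid_fully_deuterated, max_amides = NA_integer_,
                         d2o_fraction = 0.925) {
  ct <- as_tibble(centroids)
  stopifnot(all(c("timepoint_min", "replicate", "centroid_mz") %in% names(ct)))
  ct$pct_d <- deuterium_uptake(
    ct$centroid_mz, centroid_undeuterated, centroid_fully_deuterated,
    d2o_fraction
  )
  cur <- dplyr::summarise(
    dplyr::group_by(ct, .data$timepoint_min),
    sd = if (dplyr::n() > 1) sd(.data$pct_d) else 0,
    n = dplyr::n(),
    pct_d = mean(.data$pct_d),
    .groups = "drop"
  )
  cur <- cur[, c("timepoint_min", "pct_d", "sd", "n")]
  cur <- dplyr::arrange(cur, .data$timepoint_min)
  attr(cur, "peptide_id") <- ct$peptide_id[1] %||% NA_character_
  attr(cur, "max_amides") <- max_amides
  attr(cur, "d2o_fraction") <- d2o_fraction
  cur
}

# number of exchangeable backbone amides by HDX convention:
# prolines and the two N-terminal residues do not report.
#' @rdname uptake_curve
#' @param sequence peptide one-letter sequence.
#' @export
max_exchangeable_amides <- function(sequence) {
  s <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  if (length(s) <= 2) return(0L)
  body <- s[-(1:2)]
  sum(body != "P")
}

# AICc from weighted residuals of per-timepoint means; the likelihood
# is that of the replicate summary statistics, so the effective sample
# size is the total replicate count (sum of per-timepoint n).
.wls_aicc <- function(resid, se_mean, n_eff, k) {
  chi2 <- sum((resid / se_mean)^2)
  ll <- -0.5 * (chi2 + sum(log(2 * pi * se_mean^2)))
  aic <- -2 * ll + 2 * k
  if (n_eff - k - 1 > 0) aic + 2 * k * (k + 1) / (n_eff - k - 1) else Inf
}

# rates are capped at 5 / t_min: beyond that, exchange is complete
# before the first timepoint, the data carry only a lower bound on the
# rate, and an unbounded fit runs to a zero-gradient ridge
.k_cap <- function(t) 5 / min(t)

.fit_one_phase <- function(t, y, w, starts) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ dmax * (1 - exp(-k * t)),
        data = data.frame(t = t, y = y),
        start = list(dmax = s$dmax, k = min(s$k, 0.9 * .k_cap(t))),
        weights = w,
        lower = c(dmax = 0, k = 1e-6),
        upper = c(dmax = 200, k = .k_cap(t)),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(w * residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  best
}

.fit_two_phase <- function(t, y, w, starts) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ d1 * (1 - exp(-k1 * t)) + d2 * (1 - exp(-k2 * t)),
        data = data.frame(t = t, y = y),
        start = list(
          d1 = s$d1, k1 = min(s$k1, 0.9 * .k_cap(t)),
          d2 = s$d2, k2 = min(s$k2, 0.5 * .k_cap(t))
        ),
        weights = w,
        lower = c(d1 = 0, k1 = 1e-6, d2 = 0, k2 = 1e-6),
        upper = c(d1 = 200, k1 = .k_cap(t), d2 = 200, k2 = .k_cap(t)),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(w * residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  best
}

#' Fit association kinetics to an uptake curve
#'
#' Fits one-phase `D(t) = D_max (1 - e^(-k t))` and two-phase
#' `D(t) = D1 (1 - e^(-k1 t)) + D2 (1 - e^(-k2 t))` association models
#' by weighted least squares (inverse variance of the replicate mean,
#' with the replicate SD pooled across timepoints) with seeded
#' multistart, and selects between
#' them by small-sample corrected AIC computed from the replicate
#' summary likelihood. Two overrides apply: if the first timepoint
#' already reaches >= 95% of the fitted plateau the one-phase model is
#' selected, and a flat near-zero curve is flagged `"no exchange"`.
#' Two-phase parameters are reported with `k1 > k2`.
#'
#' @param curve uptake curve (tibble with `timepoint_min`, `pct_d`,
#'   `sd`, `n`), >= 4 timepoints.
#' @param n_starts number of multistart draws per model (default 10).
#' @param seed seed for the multistart draws.
#' @return A `kinetics_fit`: list with `model` (`"one-phase"` or
#'   `"two-phase"`), `parameters` (tibble: term, estimate, std_error,
#'   conf_low, conf_high at 95%), `aicc_one`, `aicc_two`, `rss`,
#'   `selection` (rationale string), `no_exchange` flag, and the
#'   underlying `fit` object.
#' @export
fit_uptake <- function(curve, n_starts = 10, seed = 1L) {
  cur <- as_tibble(curve)
  stopifnot(all(c("timepoint_min", "pct_d", "sd") %in% names(cur)))
  if (nrow(cur) < 4) abort("need >= 4 timepoints")
  if (any(diff(cur$timepoint_min) <= 0)) abort("timepoints must be strictly increasing")
  if (!"n" %in% names(cur)) cur$n <- 3L
  t <- cur$timepoint_min
  y <- cur$pct_d
  # replicate noise is pooled across timepoints: per-timepoint SDs from
  # triplicates are too unstable to weight with individually
  sdv <- cur$sd
  ok <- is.finite(sdv) & sdv > 0
  sd_pool <- if (any(ok)) sqrt(mean(sdv[ok]^2)) else 1e-3
  se_mean <- sd_pool / sqrt(cur$n)
  w <- 1 / se_mean^2
  n_eff <- sum(cur$n)

  # flat, essentially unexchanged curve
  if (max(abs(y)) < 1) {
    return(structure(
      list(
        model = "one-phase",
        parameters = tibble(
          term = c("dmax", "k"), estimate = c(0, NA_real_),
          std_error = NA_real_, conf_low = NA_real_, conf_high = NA_real_
        ),
        aicc_one = NA_real_, aicc_two = NA_real_, rss = sum(w * y^2),
        selection = "no exchange (flat curve)", no_exchange = TRUE,
        fit = NULL, curve = cur
      ),
      class = "kinetics_fit"
    ))
  }

  ymax <- max(y)
  starts1 <- withr::with_seed(seed, lapply(seq_len(n_starts), function(i) {
    list(
      dmax = ymax * runif(1, 0.8, 1.2),
      k = exp(runif(1, log(0.5 / max(t)), log(5 / min(t))))
    )
  }))
  # fast-phase starts capped so exp(-k1 t) stays resolvable at the first
  # timepoint (larger k1 gives a numerically zero gradient column)
  starts2 <- withr::with_seed(seed + 1L, lapply(seq_len(n_starts), function(i) {
    list(
      d1 = ymax * runif(1, 0.3, 0.7),
      k1 = exp(runif(1, log(0.5 / min(t)), log(4 / min(t)))),
      d2 = ymax * runif(1, 0.3, 0.7),
      k2 = exp(runif(1, log(0.2 / max(t)), log(0.5 / min(t))))
    )
  }))
  b1 <- .fit_one_phase(t, y, w, starts1)
  b2 <- .fit_two_phase(t, y, w, starts2)
  if (is.null(b1) && is.null(b2)) {
    abort("uptake fit failed to converge from all multistarts")
  }

  a1 <- if (!is.null(b1)) {
    .wls_aicc(residuals(b1$fit), se_mean, n_eff, k = 2)
  } else Inf
  a2 <- if (!is.null(b2)) {
    .wls_aicc(residuals(b2$fit), se_mean, n_eff, k = 4)
  } else Inf

  # first-timepoint plateau rule: near-maximum deuteration at the first
  # timepoint means the exchange is unresolved -> one-phase
  plateau1 <- if (!is.null(b1)) unname(coef(b1$fit)["dmax"]) else NA_real_
  first_at_plateau <- !is.null(b1) && is.finite(plateau1) && plateau1 > 0 &&
    y[1] >= 0.95 * plateau1

  use_one <- if (first_at_plateau) TRUE else a1 <= a2
  selection <- if (first_at_plateau) {
    "one-phase (first timepoint at >= 95% of plateau)"
  } else if (use_one) {
    "one-phase (lower AICc)"
  } else {
    "two-phase (lower AICc)"
  }
  chosen <- if (use_one) b1 else b2
  if (is.null(chosen)) {
    chosen <- if (use_one) b2 else b1
    use_one <- !use_one
    selection <- paste0(selection, "; fallback to converged model")
  }
  fit <- chosen$fit
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) {
    matrix(NA_real_, length(cf), length(cf))
  })
  # the weights carry a known error scale (pooled replicate variance),
  # so undo nls's rescaling by the few-df residual variance; the pooled
  # variance estimate enters the weights as 1/s^2, whose expectation
  # overstates precision by df/(df-2), hence the unbiasing factor
  sigma2_hat <- chosen$rss / max(1, nrow(cur) - length(cf))
  dof <- max(1, sum(cur$n - 1))
  if (is.finite(sigma2_hat) && sigma2_hat > 0) {
    vc <- vc / sigma2_hat * if (dof > 2) dof / (dof - 2) else 1
  }
  se <- sqrt(pmax(0, diag(vc)))
  tq <- qt(0.975, dof)
  params <- tibble(
    term = names(cf), estimate = unname(cf), std_error = unname(se),
    conf_low = unname(cf - tq * se), conf_high = unname(cf + tq * se)
  )
  if (!use_one) {
    # order phases so k1 > k2
    if (cf["k1"] < cf["k2"]) {
      swap <- c(d1 = "d2", k1 = "k2", d2 = "d1", k2 = "k1")
      params$term <- unname(swap[params$term])
      params <- dplyr::arrange(
        params, match(.data$term, c("d1", "k1", "d2", "k2"))
      )
    }
  }
  structure(
    list(
      model = if (use_one) "one-phase" else "two-phase",
      parameters = params,
      aicc_one = a1, aicc_two = a2, rss = chosen$rss,
      selection = selection, no_exchange = FALSE,
      fit = fit, curve = cur
    ),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Uptake kinetics: %s association (%s)\n", x$model, x$selection))
  print(x$parameters)
  invisible(x)
}

#' @method tidy kinetics_fit
#' @export
tidy.kinetics_fit <- function(x, ...) x$parameters

#' @method glance kinetics_fit
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble(
    model = x$model, aicc_one = x$aicc_one, aicc_two = x$aicc_two,
    rss = x$rss, no_exchange = x$no_exchange, selection = x$selection
  )
}

#' Compare deuterium uptake between two conditions
#'
#' Per-timepoint uptake difference (`free` minus `bound`) with the
#' propagated replicate SD `sqrt(sd_free^2 + sd_bound^2)`, each
#' condition's SD pooled across timepoints. The verdict
#' is `"protected"` when the bound state takes up significantly less
#' deuterium (difference exceeding `k_sd` propagated SDs) at one or
#' more timepoints with no significant difference of the opposite
#' sign, `"deprotected"` for the mirror case, `"no difference"`
#' otherwise.
#'
#' @param free,bound uptake curves on identical timepoints.
#' @param k_sd significance multiplier on the propagated SD (default 2).
#' @return A `protection_comparison`: list with `table` (per-timepoint
#'   `timepoint_min`, `delta_d`, `pooled_sd`, `significant`), `verdict`,
#'   `max_labeling_free`, `max_labeling_bound`, `k_sd`.
#' @export
protection_compare <- function(free, bound, k_sd = 2) {
  f <- as_tibble(free)
  b <- as_tibble(bound)
  if (nrow(f) != nrow(b) ||
      any(abs(f$timepoint_min - b$timepoint_min) > 1e-9)) {
    abort("timepoints of the two conditions do not match")
  }
  delta <- f$pct_d - b$pct_d
  # replicate SDs pooled across timepoints within each condition, then
  # propagated to the difference; per-timepoint triplicate SDs are too
  # noisy to threshold against individually
  pool2 <- function(s) {
    ok <- is.finite(s) & s > 0
    if (any(ok)) mean(s[ok]^2) else 1e-12
  }
  pooled <- rep(sqrt(pool2(f$sd) + pool2(b$sd)), length(delta))
  signif_pos <- delta > k_sd * pooled
  signif_neg <- delta < -k_sd * pooled
  verdict <- if (any(signif_pos) && !any(signif_neg)) {
    "protected"
  } else if (any(signif_neg) && !any(signif_pos)) {
    "deprotected"
  } else {
    "no difference"
  }
  structure(
    list(
      table = tibble(
        timepoint_min = f$timepoint_min, delta_d = delta,
        pooled_sd = pooled, significant = signif_pos | signif_neg
      ),
      verdict = verdict,
      max_labeling_free = max(f$pct_d),
      max_labeling_bound = max(b$pct_d),
      k_sd = k_sd
    ),
    class = "protection_comparison"
  )
}

#' @export
print.protection_comparison <- function(x, ...) {
  cat(sprintf(
    "Protection verdict: %s (max labeling free %.1f%%, bound %.1f%%, k_sd = %g)\n",
    x$verdict, x$max_labeling_free, x$max_labeling_bound, x$k_sd
  ))
  invisible(x)
}

#' @method tidy protection_comparison
#' @export
tidy.protection_comparison <- function(x, ...) x$table
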