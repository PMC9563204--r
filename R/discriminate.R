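# CCS-based discrimination between candidate complex architectures.

#' Rank candidate models against an experimental CCS
#'
#' Computes each candidate's relative deviation
#' `100 * (ccs_model - ccs_exp) / ccs_exp`, selects the candidate with
#' the smallest absolute deviation, and accepts every candidate within
#' the threshold. When the accepted candidates are mutually
#' unresolvable (pairwise CCS differences below the threshold) a
#' warning notes that gas-phase compaction of flexible regions can make
#' distinct architectures indistinguishable by CCS alone.
#'
#' @param exp_ccs experimental CCS, Angstrom^2 (> 0).
#' @param candidates data frame with columns `id`, `ccs_A2` (scaled
#'   theoretical CCS) and optionally `description`.
#' @param threshold acceptance threshold on the absolute relative
#'   deviation, percent (default 5).
#' @return A `discrimination_result`: list with `table` (per-candidate
#'   `id`, `ccs_A2`, `deviation_pct`, `accepted`), `best` (id),
#'   `accepted` (ids), `threshold`, `tie` flag.
#' @export
rank_models <- function(exp_ccs, candidates, threshold = 5) {
  cand <- as_tibble(candidates)
  if (nrow(cand) == 0) abort("candidate list is empty")
  stopifnot(all(c("id", "ccs_A2") %in% names(cand)))
  if (!is.finite(exp_ccs) || exp_ccs <= 0) abort("experimental CCS must be > 0")
  cand$deviation_pct <- 100 * (cand$ccs_A2 - exp_ccs) / exp_ccs
  cand$accepted <- abs(cand$deviation_pct) <= threshold
  best_i <- which.min(abs(cand$deviation_pct))
  tie <- sum(abs(abs(cand$deviation_pct) - abs(cand$deviation_pct[best_i])) < 1e-12) > 1
  accepted_ids <- cand$id[cand$accepted]
  if (length(accepted_ids) > 1) {
    grp <- resolvability(cand[cand$accepted, , drop = FALSE], threshold)
    if (!grp$resolvable) {
      warn(paste0(
        "accepted candidates are unresolvable at ", threshold,
        "% — gas-phase compaction of flexible regions can equalize the CCS",
        " of distinct architectures"
      ))
    }
  }
  structure(
    list(
      table = cand, best = cand$id[best_i], accepted = accepted_ids,
      threshold = threshold, tie = tie
    ),
    class = "discrimination_result"
  )
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "Best candidate: %s (threshold %.1f%%; accepted: %s)\n",
    x$best, x$threshold,
    if (length(x$accepted)) paste(x$accepted, collapse = ", ") else "none"
  ))
  print(x$table)
  invisible(x)
}

#' @method tidy discrimination_result
#' @export
tidy.discrimination_result <- function(x, ...) x$table

#' @method glance discrimination_result
#' @export
glance.discrimination_result <- function(x, ...) {
  tibble(
    best = x$best, n_accepted = length(x$accepted),
    threshold = x$threshold, tie = x$tie
  )
}

#' Group candidates that CCS cannot tell apart
#'
#' Single-linkage grouping of candidates whose pairwise relative CCS
#' differences fall below the stated resolution; flags whether the
#' candidate set is resolvable (every group a singleton).
#'
#' @param candidates data frame with columns `id`, `ccs_A2`.
#' @param resolution relative resolution, percent (default 2).
#' @return List with `resolvable` (logical), `groups` (list of id
#'   vectors) and `table` (candidates plus `group`).
#' @export
resolvability <- function(candidates, resolution = 2) {
  cand <- dplyr::arrange(as_tibble(candidates), .data$ccs_A2)
  if (nrow(cand) == 0) abort("candidate list is empty")
  if (nrow(cand) == 1) {
    cand$group <- 1L
    return(list(resolvable = TRUE, groups = list(cand$id), table = cand))
  }
  rel_gap <- diff(cand$ccs_A2) / utils::head(cand$ccs_A2, -1) * 100
  grp <- cumsum(c(1L, as.integer(rel_gap >= resolution)))
  cand$group <- grp
  groups <- split(cand$id, grp)
  names(groups) <- NULL
  list(
    resolvable = all(lengths(groups) == 1L),
    groups = groups,
    table = cand
  )
}
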