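# Workflow driver: wires the stages into the two end-to-end analyses
# (CCS-based model discrimination on synthetic geometries; HDX
# protection analysis), from a single self-documenting config.

.default_config <- function(workflow) {
  common <- list(workflow = workflow)
  if (workflow == "discrimination") {
    c(common, list(
      probe = 1.0, n_orientations = 300L, scale_factor = 1.14,
      threshold = 5, gas_mass = 28.0134, edc_coeff = 1.41,
      charge = 14L, mass_da = 36600,
      atd_width_ms = 0.25, atd_noise = 0,
      n_ligand_beads = 12L, host_radius = 12, n_host = 60,
      seeds = list(geometry = NULL, ccs = NULL, atd = NULL)
    ))
  } else {
    c(common, list(
      k_sd = 2, timepoints = c(1, 5, 10, 30, 60), replicate_sd = 2,
      n_replicates = 3L, d2o_fraction = 0.925,
      free_d1 = 98, free_k1 = 6, bound_d1 = 45, bound_k1 = 0.5,
      seeds = list(hdx = NULL)
    ))
  }
}

#' Validate and materialize a workflow config
#'
#' Fills in all defaults so a saved config is self-documenting, and
#' refuses configs whose stochastic stages lack an explicit seed.
#'
#' @param config named list (or path to a YAML file) with at least
#'   `workflow` (`"discrimination"` or `"hdx_protection"`) and a
#'   `seeds` list giving an integer seed for every stochastic stage
#'   (`geometry`, `ccs`, `atd` for discrimination; `hdx` for HDX).
#' @return The materialized config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$workflow) ||
      !config$workflow %in% c("discrimination", "hdx_protection")) {
    abort("config$workflow must be 'discrimination' or 'hdx_protection'")
  }
  full <- modifyList(.default_config(config$workflow), config)
  need <- names(.default_config(config$workflow)$seeds)
  for (s in need) {
    val <- full$seeds[[s]]
    if (is.null(val) || !is.numeric(val) || length(val) != 1 ||
        !is.finite(val)) {
      abort(paste0("config$seeds$", s, " must be a single integer seed"))
    }
    full$seeds[[s]] <- as.integer(val)
  }
  full
}

#' @rdname validate_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run an end-to-end workflow
#'
#' Executes the configured stages in order and returns a report in
#' which every numeric output is traceable to a stage, its parameters
#' and its seed. Identical configs reproduce the report bitwise.
#'
#' The `discrimination` workflow builds pocket and surface complexes of
#' identical composition, computes their scaled projection CCS, fits a
#' synthetic traveling-wave calibration, simulates the arrival-time
#' distribution of the pocket-bound (true) architecture, converts it
#' back to an experimental CCS, and ranks the two candidates. The
#' `hdx_protection` workflow simulates triplicate free/bound uptake
#' tables, fits kinetics to both and issues a protection verdict.
#'
#' @param config config list or YAML path (see [validate_config()]).
#' @return A `structms_report` list: `workflow`, `config`, `stages`
#'   (per-stage numeric results), `verdict`.
#' @export
run_workflow <- function(config) {
  cfg <- validate_config(config)
  report <- if (cfg$workflow == "discrimination") {
    .run_discrimination(cfg)
  } else {
    .run_hdx(cfg)
  }
  structure(report, class = "structms_report")
}

.run_discrimination <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  geoms <- stage("geometry", list(
    pocket = make_geometry(
      "pocket_complex",
      n_beads = cfg$n_ligand_beads, host_radius = cfg$host_radius,
      n_host = cfg$n_host, seed = cfg$seeds$geometry
    ),
    surface = make_geometry(
      "surface_complex",
      n_beads = cfg$n_ligand_beads, host_radius = cfg$host_radius,
      n_host = cfg$n_host, seed = cfg$seeds$geometry
    )
  ))
  ccs <- stage("ccs", purrr::imap(geoms, function(g, nm) {
    scale_ccs(
      pa_ccs(g,
        probe = cfg$probe, n_orientations = cfg$n_orientations,
        seed = cfg$seeds$ccs
      ),
      cfg$scale_factor
    )
  }))
  cal <- stage("calibration", fit_calibration(
    synth_calibrants(gas_mass = cfg$gas_mass, edc_coeff = cfg$edc_coeff),
    gas_mass = cfg$gas_mass, edc_coeff = cfg$edc_coeff
  ))
  atd <- stage("atd", suppressWarnings(simulate_atd(
    ccs$pocket$value, cal, cfg$charge, cfg$mass_da,
    width_ms = cfg$atd_width_ms, noise = cfg$atd_noise,
    seed = cfg$seeds$atd
  )))
  peak <- stage("atd_peak", atd_peak(atd))
  exp_ccs <- stage("drift_to_ccs", drift_to_ccs(
    cal, peak$mode_ms, cfg$charge, cfg$mass_da
  ))
  candidates <- tibble(
    id = c("pocket", "surface"),
    ccs_A2 = c(ccs$pocket$value, ccs$surface$value)
  )
  disc <- stage(
    "discriminate",
    suppressWarnings(rank_models(exp_ccs, candidates, cfg$threshold))
  )
  list(
    workflow = cfg$workflow,
    config = cfg,
    stages = list(
      ccs = list(
        pocket_ccs_A2 = ccs$pocket$value, pocket_se_A2 = ccs$pocket$se,
        surface_ccs_A2 = ccs$surface$value, surface_se_A2 = ccs$surface$se,
        scale_factor = cfg$scale_factor
      ),
      calibration = list(
        slope = cal$slope, intercept = cal$intercept, r_squared = cal$r_squared
      ),
      atd = list(mode_ms = peak$mode_ms, fwhm_ms = peak$fwhm_ms),
      experimental = list(exp_ccs_A2 = exp_ccs),
      discrimination = list(
        best = disc$best, accepted = disc$accepted,
        deviation_pct = setNames(
          as.list(disc$table$deviation_pct), disc$table$id
        )
      )
    ),
    verdict = list(selected_model = disc$best)
  )
}

.run_hdx <- function(cfg) {
  truth <- tibble(
    peptide_id = c("client_free", "client_bound"),
    model = "one-phase",
    d1 = c(cfg$free_d1, cfg$bound_d1),
    k1 = c(cfg$free_k1, cfg$bound_k1)
  )
  sim <- simulate_hdx(
    truth,
    timepoints = cfg$timepoints, replicate_sd = cfg$replicate_sd,
    n_replicates = cfg$n_replicates, d2o_fraction = cfg$d2o_fraction,
    seed = cfg$seeds$hdx
  )
  curves <- purrr::map(setNames(truth$peptide_id, truth$peptide_id), function(p) {
    ctl <- sim$controls[sim$controls$peptide_id == p, ]
    uptake_curve(
      sim$centroids[sim$centroids$peptide_id == p, ],
      ctl$centroid_undeuterated, ctl$centroid_fully_deuterated,
      d2o_fraction = cfg$d2o_fraction
    )
  })
  fits <- purrr::map(curves, fit_uptake, seed = cfg$seeds$hdx)
  cmp <- protection_compare(
    curves$client_free, curves$client_bound, cfg$k_sd
  )
  list(
    workflow = cfg$workflow,
    config = cfg,
    stages = list(
      fits = purrr::map(fits, function(f) {
        list(
          model = f$model,
          parameters = setNames(
            as.list(f$parameters$estimate), f$parameters$term
          )
        )
      }),
      protection = list(
        delta_d = cmp$table$delta_d,
        pooled_sd = cmp$table$pooled_sd,
        max_labeling_free = cmp$max_labeling_free,
        max_labeling_bound = cmp$max_labeling_bound
      )
    ),
    verdict = list(protection = cmp$verdict)
  )
}

#' Serialize a workflow report to JSON
#'
#' Deterministic serialization (no timestamps, full precision), so
#' repeated runs of an identical config produce byte-identical files.
#'
#' @param report a `structms_report`.
#' @param path output path; `NULL` returns the JSON string.
#' @return The path, or the JSON string when `path` is `NULL`.
#' @export
write_report <- function(report, path = NULL) {
  json <- jsonlite::toJSON(
    unclass(report),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  if (is.null(path)) {
    return(as.character(json))
  }
  writeLines(as.character(json), path)
  invisible(path)
}

#' @export
print.structms_report <- function(x, ...) {
  cat(sprintf("Workflow '%s'\n", x$workflow))
  v <- x$verdict
  for (nm in names(v)) cat(sprintf("  %s: %s\n", nm, v[[nm]]))
  invisible(x)
}
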