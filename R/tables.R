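# Reference tables: van-der-Waals radii and hydropathy scales.

# Bondi (1964) vdW radii for elements common in protein models, plus a
# united-atom variant with slightly inflated heavy-atom radii to absorb
# the hydrogens that crystal structures typically omit.
.radius_tables <- list(
  bondi = c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.00, MN = 2.00, CU = 1.40, `NA` = 2.27, K = 2.75
  ),
  united = c(
    H = 1.20, C = 1.90, N = 1.70, O = 1.60, S = 1.90, P = 1.90,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 2.00,
    FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.00, MN = 2.00, CU = 1.40, `NA` = 2.27, K = 2.75
  )
)

#' Van-der-Waals radius table
#'
#' Named atomic radii (Angstrom) used to dress atomic models for
#' clash counting and projection-approximation CCS.
#'
#' @param name `"bondi"` (default; Bondi 1964 values) or `"united"`
#'   (heavy atoms inflated to absorb implicit hydrogens).
#' @return Named numeric vector, element symbol (upper case) to radius in
#'   Angstrom.
#' @export
radius_table <- function(name = "bondi") {
  if (is.numeric(name) && !is.null(names(name))) {
    return(setNames(as.numeric(name), toupper(names(name))))
  }
  name <- match.arg(name, names(.radius_tables))
  .radius_tables[[name]]
}

.kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Hydropathy scale
#'
#' @param name scale name; only `"kyte-doolittle"` is built in. A named
#'   numeric vector (one value per one-letter residue code) is accepted
#'   as a custom scale.
#' @return Named numeric vector of per-residue hydropathy values.
#' @export
hydropathy_scale <- function(name = "kyte-doolittle") {
  if (is.numeric(name) && !is.null(names(name))) {
    return(setNames(as.numeric(name), toupper(names(name))))
  }
  name <- match.arg(name, "kyte-doolittle")
  .kyte_doolittle
}

# proton mass (Da), positive-mode ESI adduct default
.m_proton <- 1.007276

# nitrogen drift gas (Da)
.m_nitrogen <- 28.0134
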