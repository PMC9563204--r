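# Structure input and geometric comparison: reading PDB/mmCIF coordinates,
# rigid-body superposition, inter-chain clash counting, sequence hydropathy.

#' Construct an atomic model
#'
#' An atomic model is a tibble of atoms (one row per atom) with columns
#' `element`, `atom` (atom name, e.g. `"CA"`), `x`, `y`, `z` (Angstrom),
#' `chain`, `resno`, `resname`, `confidence` (per-atom score, `NA` if
#' absent) and `radius` (Angstrom, assigned from a radius table or given
#' directly), carrying the source dialect as an attribute.
#'
#' @param atoms data frame with at least `element`, `x`, `y`, `z`; missing
#'   label columns are filled with defaults (chain `"A"`, sequential
#'   residue numbers).
#' @param dialect provenance tag: `"pdb"`, `"mmcif"` or `"synthetic"`.
#' @param radius_table table name or named vector passed to
#'   [radius_table()]; ignored for rows that already carry a finite
#'   `radius`.
#' @return An `atomic_model` tibble.
#' @export
atomic_model <- function(atoms, dialect = "synthetic", radius_table = "bondi") {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0L) abort("atomic model is empty")
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"atom" %in% names(atoms)) atoms$atom <- atoms$element
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"resno" %in% names(atoms)) atoms$resno <- seq_len(nrow(atoms))
  if (!"resname" %in% names(atoms)) atoms$resname <- "UNK"
  if (!"confidence" %in% names(atoms)) atoms$confidence <- NA_real_
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atomic model has non-finite coordinates")
  }
  if (!"radius" %in% names(atoms)) atoms$radius <- NA_real_
  need <- !is.finite(atoms$radius)
  if (any(need)) {
    tab <- radius_table(radius_table)
    key <- toupper(atoms$element[need])
    unknown <- setdiff(unique(key), names(tab))
    if (length(unknown) > 0) {
      abort(paste0(
        "element(s) not in radius table: ",
        paste(unknown, collapse = ", ")
      ))
    }
    atoms$radius[need] <- unname(tab[key])
  }
  atoms <- atoms[, c(
    "element", "atom", "x", "y", "z", "chain", "resno", "resname",
    "confidence", "radius"
  )]
  attr(atoms, "dialect") <- dialect
  class(atoms) <- c("atomic_model", class(atoms))
  atoms
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses coordinates, chain and residue labels (preserved as in the
#' source file) and assigns per-atom van-der-Waals radii from a named
#' table. Hydrogens absent from the file are not added.
#'
#' @param path path to a coordinate file.
#' @param dialect `"pdb"` or `"mmcif"`.
#' @param radius_table radius table name or named vector (see
#'   [radius_table()]).
#' @return An `atomic_model` tibble.
#' @export
read_structure <- function(path, dialect = c("pdb", "mmcif"),
                           radius_table = "bondi") {
  dialect <- match.arg(dialect)
  parsed <- switch(dialect,
    pdb = bio3d::read.pdb(path),
    mmcif = suppressWarnings(bio3d::read.cif(path))
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) abort(paste0("no atoms in ", path))
  atomic_model(
    tibble(
      element = at$elesy,
      atom = at$elety,
      x = at$x, y = at$y, z = at$z,
      chain = ifelse(is.na(at$chain), "A", at$chain),
      resno = at$resno,
      resname = at$resid,
      confidence = at$b
    ),
    dialect = dialect, radius_table = radius_table
  )
}

# parse "chain:start-end" selection strings into a tibble
parse_selection <- function(selection) {
  purrr::map_dfr(selection, function(s) {
    m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
    if (length(m) != 4) abort(paste0("cannot parse selection '", s, "'"))
    tibble(
      chain = m[2],
      start = as.integer(m[3]),
      end = as.integer(m[4])
    )
  })
}

select_atoms <- function(model, selection = NULL, atoms = c("calpha", "all")) {
  atoms <- match.arg(atoms)
  keep <- rep(TRUE, nrow(model))
  if (!is.null(selection)) {
    sel <- parse_selection(selection)
    keep <- purrr::reduce(
      purrr::pmap(sel, function(chain, start, end) {
        model$chain == chain & model$resno >= start & model$resno <= end
      }),
      `|`
    )
  }
  if (atoms == "calpha" && any(model$atom == "CA")) {
    keep <- keep & model$atom == "CA"
  }
  model[keep, , drop = FALSE]
}

#' Least-squares rigid-body superposition
#'
#' Optimal rotation/translation of `mobile` onto `reference` over a
#' matched atom selection, via the closed-form covariance/SVD (Kabsch)
#' construction, with the reflection branch removed so the rotation is
#' always proper. Selections are closed residue intervals per chain
#' (`"A:5-100"`), `"calpha"` atoms by default.
#'
#' @param mobile,reference atomic models; the selected atoms must match
#'   one-to-one, in order.
#' @param selection character vector of `"chain:start-end"` strings, or
#'   `NULL` for all atoms.
#' @param atoms `"calpha"` (default; falls back to all atoms if no CA
#'   present) or `"all"`.
#' @return A `superposition` object: list with `rotation` (3x3,
#'   determinant +1), `translation` (length 3, Angstrom), `rmsd`
#'   (Angstrom) and `n_atoms_used`.
#' @export
superpose <- function(mobile, reference, selection = NULL,
                      atoms = c("calpha", "all")) {
  atoms <- match.arg(atoms)
  pm <- select_atoms(mobile, selection, atoms)
  pr <- select_atoms(reference, selection, atoms)
  if (nrow(pm) != nrow(pr)) {
    abort(paste0(
      "selection lengths differ: ", nrow(pm), " (mobile) vs ",
      nrow(pr), " (reference)"
    ))
  }
  if (nrow(pm) < 3) abort("need at least 3 matched atoms")
  P <- as.matrix(pm[, c("x", "y", "z")])
  Q <- as.matrix(pr[, c("x", "y", "z")])
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tv <- as.numeric(cq - R %*% cp)
  moved <- sweep(P %*% t(R), 2, -tv)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(
    list(
      rotation = R, translation = tv, rmsd = rmsd,
      n_atoms_used = nrow(pm)
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "Rigid-body superposition: rmsd %.4f A over %d atoms\n",
    x$rmsd, x$n_atoms_used
  ))
  invisible(x)
}

#' @method tidy superposition
#' @export
tidy.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms_used = x$n_atoms_used)
}

#' Apply a superposition (or any rigid motion) to a model
#'
#' @param model atomic model.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric, Angstrom.
#' @return The transformed model.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, -translation)
  model$x <- xyz[, 1]
  model$y <- xyz[, 2]
  model$z <- xyz[, 3]
  model
}

#' Count steric clashes between two models
#'
#' A pair of atoms (one from each model) clashes when their distance is
#' below the sum of their van-der-Waals radii minus a tolerance. Used to
#' test whether a bound-state model is compatible with an oligomeric
#' arrangement.
#'
#' @param a,b atomic models.
#' @param tolerance allowed overlap in Angstrom (>= 0); default 0.4.
#' @return A `clash_report`: list with `n_clashes`, `pairs` (tibble of
#'   atom indices and distances) and `tolerance`.
#' @export
count_clashes <- function(a, b, tolerance = 0.4) {
  if (tolerance < 0) abort("tolerance must be >= 0")
  if (nrow(a) == 0L || nrow(b) == 0L) abort("models must be non-empty")
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  lim <- outer(a$radius, b$radius, `+`) - tolerance
  hit <- which(sqrt(d2) < lim, arr.ind = TRUE)
  pairs <- tibble(
    atom_a = as.integer(hit[, 1]),
    atom_b = as.integer(hit[, 2]),
    distance = sqrt(d2[hit])
  )
  structure(
    list(n_clashes = nrow(pairs), pairs = pairs, tolerance = tolerance),
    class = "clash_report"
  )
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf(
    "%d clashing atom pair(s) at overlap tolerance %.2f A\n",
    x$n_clashes, x$tolerance
  ))
  invisible(x)
}

#' Mean hydropathy of a peptide sequence
#'
#' Arithmetic mean of per-residue hydropathy values (Kyte-Doolittle by
#' default). Whitespace in the sequence is stripped before scoring, so
#' sequences copied from line-wrapped sources score correctly.
#'
#' @param sequence one-letter amino-acid string.
#' @param scale scale name or named vector (see [hydropathy_scale()]).
#' @return Mean hydropathy (dimensionless).
#' @export
mean_hydropathy <- function(sequence, scale = "kyte-doolittle") {
  sc <- hydropathy_scale(scale)
  letters1 <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  if (length(letters1) == 0) abort("sequence is empty")
  unknown <- setdiff(unique(letters1), names(sc))
  if (length(unknown) > 0) {
    abort(paste0(
      "residue(s) not in hydropathy scale: ", paste(unknown, collapse = ", ")
    ))
  }
  mean(sc[letters1])
}
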