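# Independent oracles and small fixture builders used across the suite.

# --- structure fixtures ------------------------------------------------

toy_pdb_text <- function(elements = c("N", "C", "O"),
                         xyz = rbind(c(0, 0, 0), c(1.458, 0, 0), c(2, 1.4, 0))) {
  lines <- vapply(seq_along(elements), function(i) {
    sprintf(
      "ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  1.00 90.00          %2s",
      i, elements[i], 1L, xyz[i, 1], xyz[i, 2], xyz[i, 3], elements[i]
    )
  }, character(1))
  c(lines, "END")
}

toy_cif_text <- function(elements = c("N", "C", "O"),
                         xyz = rbind(c(0, 0, 0), c(1.458, 0, 0), c(2, 1.4, 0))) {
  hdr <- c(
    "data_toy", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- vapply(seq_along(elements), function(i) {
    sprintf(
      "ATOM %d %s %s . ALA A 1 1 ? %.3f %.3f %.3f 1.00 90.00 ? 1 ALA A %s 1",
      i, elements[i], elements[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
      elements[i]
    )
  }, character(1))
  c(hdr, rows)
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

random_model <- function(n, seed, spread = 10, radius_range = c(1.2, 2)) {
  withr::with_seed(seed, {
    atomic_model(
      tibble::tibble(
        element = "BEAD",
        x = runif(n, 0, spread), y = runif(n, 0, spread),
        z = runif(n, 0, spread),
        chain = "A",
        radius = runif(n, radius_range[1], radius_range[2])
      ),
      dialect = "synthetic"
    )
  })
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
    matrix(c(
      a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
      2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
      2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
    ), 3, 3, byrow = TRUE)
  })
}

# --- structure oracles -------------------------------------------------

euler_rotation <- function(a, b, c) {
  Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

# best rigid-fit rmsd by dense search over Euler angles plus Nelder-Mead
# refinement; independent of the SVD construction under test
rmsd_grid_oracle <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rmsd_of <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  grid <- expand.grid(
    a = seq(0, 2 * pi, length.out = 13)[-13],
    b = seq(0, pi, length.out = 7),
    c = seq(0, 2 * pi, length.out = 13)[-13]
  )
  vals <- apply(grid, 1, rmsd_of)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, rmsd_of, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

clash_count_oracle <- function(a, b, tolerance) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d < a$radius[i] + b$radius[j] - tolerance) n <- n + 1L
    }
  }
  n
}

# --- native MS oracle --------------------------------------------------

stoichiometry_oracle <- function(observed, masses, max_counts, tol_ppm) {
  counts <- vector("list", length(masses))
  for (i in seq_along(masses)) counts[[i]] <- 0:max_counts[i]
  grid <- as.matrix(expand.grid(counts))
  hits <- list()
  for (r in seq_len(nrow(grid))) {
    cts <- grid[r, ]
    if (sum(cts) == 0) next
    theo <- sum(cts * masses)
    if (abs(1e6 * (theo - observed) / observed) <= tol_ppm) {
      hits[[length(hits) + 1]] <- cts
    }
  }
  hits
}

# exact peak list for a charge series of mass M
series_peaks <- function(mass, charges, adduct = 1.007276, intensity = 1) {
  tibble::tibble(
    mz = (mass + charges * adduct) / charges,
    intensity = intensity, width = 1
  )
}

# --- HDX helper --------------------------------------------------------

sim_curve <- function(model, d1, k1, d2 = NA, k2 = NA, sd = 2, seed = 1,
                      id = "pep") {
  tr <- tibble::tibble(
    peptide_id = id, model = model, d1 = d1, k1 = k1, d2 = d2, k2 = k2
  )
  sim <- simulate_hdx(tr, replicate_sd = sd, seed = seed)
  ctl <- sim$controls
  uptake_curve(
    sim$centroids, ctl$centroid_undeuterated, ctl$centroid_fully_deuterated
  )
}
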