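# Densities, spin densities, their atom-condensation, and cube export.

#' Electron density and spin density on a point set
#'
#' `rho = rho_alpha + rho_beta`, `rho_z = rho_alpha - rho_beta`, with
#' `rho_sigma(r) = sum over occupied psi_i_sigma(r)^2`.
#'
#' @param mos a [spin_orbitals]
#' @param ao_values M x N_AO matrix from [eval_basis]
#' @return list with numeric vectors `rho`, `rhoz`, `rho_alpha`, `rho_beta`
#' @export
density_on_grid <- function(mos, ao_values) {
  if (ncol(ao_values) != nrow(mos$coeff$alpha)) {
    stop("AO value / coefficient dimension mismatch")
  }
  ra <- rowSums((ao_values %*% occupied_coeff(mos, "alpha"))^2)
  rb <- if (mos$restricted) ra else {
    rowSums((ao_values %*% occupied_coeff(mos, "beta"))^2)
  }
  list(rho = ra + rb, rhoz = ra - rb, rho_alpha = ra, rho_beta = rb)
}

#' Condense a field onto atoms over Wigner-Seitz cells
#'
#' @param values numeric field values on `grid$points`
#' @param grid a `molecular_grid`
#' @return named per-atom vector of cell integrals; sums to the whole-space
#'   grid integral by construction (hard disjoint cells)
#' @export
condensed_density <- function(values, grid) {
  nat <- n_atoms(grid$geometry)
  out <- vapply(seq_len(nat), function(a) integrate_cell(values, grid, a),
                numeric(1))
  names(out) <- atom_labels(grid$geometry)
  out
}

#' On-top alpha-beta pair density at coincident points
#'
#' `rho2_ab(r; r) = (rho(r)^2 - rho_z(r)^2) / 2`, identically equal to
#' `2 rho_alpha rho_beta` and hence non-negative.
#'
#' @param rho total density values
#' @param rhoz spin density values on the same points
#' @return numeric vector of on-top pair density values
#' @export
ontop_pair_density <- function(rho, rhoz) {
  0.5 * (rho^2 - rhoz^2)
}

#' Two-site closed-form spin density
#'
#' For the two-electron two-site model the spin density reduces to
#' `sqrt(1 - b^2) * (chi1^2 - chi2^2)` with `b` the effective bond order and
#' `chi` the orthogonalized site functions. Used as the analytic reference
#' against [density_on_grid] on toy systems.
#'
#' @param b effective bond order in `[0, 1]`
#' @param chi1_sq,chi2_sq site density values on a common point set
#' @return numeric vector of spin density values
#' @export
two_site_spin_density <- function(b, chi1_sq, chi2_sq) {
  if (b < 0 || b > 1) stop("bond order b must lie in [0, 1]")
  sqrt(1 - b^2) * (chi1_sq - chi2_sq)
}

#' Regular cube lattice enclosing a geometry
#'
#' @param geom a [geometry]
#' @param n points per axis (default 80)
#' @param pad box padding beyond the nuclei (bohr, default 4)
#' @return list with `origin`, `step` (3-vector), `n`, and the M x 3 `points`
#'   (x outer, z fastest, cube file ordering)
#' @export
cube_lattice <- function(geom, n = 80, pad = 4) {
  lo <- apply(geom$xyz, 2, min) - pad
  hi <- apply(geom$xyz, 2, max) + pad
  step <- (hi - lo) / (n - 1)
  ax <- lapply(1:3, function(k) lo[k] + step[k] * (seq_len(n) - 1))
  g <- expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]])
  list(origin = lo, step = step, n = rep(n, 3),
       points = cbind(g$x, g$y, g$z))
}

#' Write a Gaussian cube file
#'
#' @param path output path
#' @param geom a [geometry]
#' @param lattice a [cube_lattice]
#' @param values field values on `lattice$points`
#' @param comment two comment lines (character vector, recycled/padded);
#'   isosurface thresholds and sign conventions belong here
#' @export
write_cube <- function(path, geom, lattice, values,
                       comment = c("spinlrf field",
                                   "isosurface thresholds +-0.1 +-0.01 +-0.001; + blue, - red")) {
  comment <- rep_len(comment, 2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  nat <- n_atoms(geom)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nat,
                     lattice$origin[1], lattice$origin[2], lattice$origin[3]), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", lattice$n[1], lattice$step[1], 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", lattice$n[2], 0, lattice$step[2], 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", lattice$n[3], 0, 0, lattice$step[3]), con)
  for (i in seq_len(nat)) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", geom$z[i], geom$z[i],
                       geom$xyz[i, 1], geom$xyz[i, 2], geom$xyz[i, 3]), con)
  }
  # values arrive z-fastest within each (x, y) column; 6 per line
  nz <- lattice$n[3]
  m <- matrix(values, nrow = nz)
  for (col in seq_len(ncol(m))) {
    v <- m[, col]
    for (s in seq(1, nz, by = 6)) {
      writeLines(paste(sprintf("%13.5e", v[s:min(s + 5, nz)]), collapse = " "), con)
    }
  }
  invisible(path)
}
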