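# Broken-symmetry wavefunction diagnostics.

#' Corresponding-orbital overlaps between alpha and beta occupied spaces
#'
#' The singular values of `C_alpha_occ' S C_beta_occ`, sorted ascending so
#' the magnetic pair (smallest overlap) comes first. 1 for a closed shell,
#' 0 for a fully localized singlet diradical pair.
#'
#' @param mos a [spin_orbitals]
#' @param overlap AO overlap matrix (analytic or from [numerical_overlap])
#' @return numeric vector of overlaps `T_i`, length
#'   `min(N_occ(alpha), N_occ(beta))`
#' @export
corresponding_overlaps <- function(mos, overlap) {
  ca <- occupied_coeff(mos, "alpha")
  cb <- occupied_coeff(mos, "beta")
  if (ncol(ca) == 0 || ncol(cb) == 0) return(numeric(0))
  overlap <- as.matrix(overlap)
  if (nrow(overlap) != nrow(ca)) stop("overlap dimension mismatch")
  s <- svd(crossprod(ca, overlap %*% cb))$d
  if (any(s > 1 + 1e-8)) {
    stop(sprintf("overlap-matrix inconsistency: corresponding overlap %.6g exceeds 1",
                 max(s)))
  }
  s <- pmin(pmax(s, 0), 1)
  sort(s)
}

#' Bond-order and diradical indices from corresponding overlaps
#'
#' Effective bond order `b = sum T_i`; spin-projected bond order
#' `B = sum 2 T_i / (1 + T_i^2)`; per-pair diradical characters
#' `y_i = 1 - 2 T_i / (1 + T_i^2)`; natural occupations `1 + T_i` (bonding)
#' and `1 - T_i` (antibonding). The aggregate `y` reported is that of the
#' magnetic pair (smallest `T`); the per-pair vector carries the rest.
#'
#' @param T numeric vector of corresponding overlaps in `[0, 1]`
#' @return list with `b`, `B`, `y` (aggregate), `y_pair`, `n_bond`, `n_anti`
#' @export
bond_order_indices <- function(T) {
  if (any(T < 0 | T > 1)) stop("corresponding overlaps must lie in [0, 1]")
  T <- sort(T)
  bpair <- 2 * T / (1 + T^2)
  list(b = sum(T), B = sum(bpair),
       y = if (length(T)) 1 - bpair[1] else 0,
       y_pair = 1 - bpair,
       n_bond = 1 + T, n_anti = 1 - T)
}

#' Broken-symmetry diagnostics report
#'
#' Combines the corresponding-orbital spectrum, bond orders, diradical
#' character, the excess of unpaired spin orbitals, and (when a grid and AO
#' values are supplied) per-atom spin populations condensed over
#' Wigner-Seitz cells.
#'
#' @param mos a [spin_orbitals]
#' @param overlap AO overlap matrix
#' @param grid optional `molecular_grid` for spin populations
#' @param ao_values optional AO values on `grid$points`
#' @return an object of class `bs_diagnostics`
#' @export
bs_diagnostics <- function(mos, overlap, grid = NULL, ao_values = NULL) {
  T <- corresponding_overlaps(mos, overlap)
  idx <- bond_order_indices(T)
  spin_pop <- NULL
  if (!is.null(grid) && !is.null(ao_values)) {
    spin_pop <- condensed_density(density_on_grid(mos, ao_values)$rhoz, grid)
  }
  structure(
    list(T = T, b = idx$b, B = idx$B, y = idx$y, y_pair = idx$y_pair,
         n_bond = idx$n_bond, n_anti = idx$n_anti,
         n_unpaired_excess = abs(n_occ(mos, "alpha") - n_occ(mos, "beta")),
         spin_populations = spin_pop),
    class = "bs_diagnostics")
}

#' @export
print.bs_diagnostics <- function(x, ...) {
  cat("broken-symmetry diagnostics\n")
  if (length(x$T)) {
    tab <- data.frame(pair = seq_along(x$T), T = x$T, y = x$y_pair,
                      n_bond = x$n_bond, n_anti = x$n_anti)
    print(tab, row.names = FALSE, digits = 6)
  }
  cat(sprintf("  b = %.6f   B = %.6f   y (magnetic pair) = %.6f\n",
              x$b, x$B, x$y))
  if (x$n_unpaired_excess > 0) {
    cat(sprintf("  unpaired excess spin orbitals: %d (excluded from b/B/y)\n",
                x$n_unpaired_excess))
  }
  if (!is.null(x$spin_populations)) {
    cat("  spin populations:\n")
    print(round(x$spin_populations, 6))
  }
  invisible(x)
}

#' Pair table of a diagnostics report
#' @param x a `bs_diagnostics`
#' @return data.frame with one row per corresponding-orbital pair
#' @export
bs_pair_table <- function(x) {
  data.frame(pair = seq_along(x$T), T = x$T, y = x$y_pair,
             n_bond = x$n_bond, n_anti = x$n_anti)
}

#' Write a diagnostics report as JSON
#' @param x a `bs_diagnostics`
#' @param path output path
#' @export
write_bs_json <- function(x, path) {
  jsonlite::write_json(
    list(T = x$T, b = x$b, B = x$B, y = x$y, y_pair = x$y_pair,
         n_bond = x$n_bond, n_anti = x$n_anti,
         n_unpaired_excess = x$n_unpaired_excess,
         spin_populations = as.list(x$spin_populations)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
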