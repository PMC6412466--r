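# Sum-over-states linear response function of density and spin density,
# condensed onto Wigner-Seitz cells.
#
# The bare orbital response is evaluated in factorized form: the
# cell-integrated occupied x virtual orbital products (transition moments)
# are computed once per atom, then contracted over atom pairs. The full
# two-point kernel chi(r, r') is never formed.

#' Cell-integrated occupied-virtual orbital products
#'
#' For each spin channel, `M[i, a, A] = integral over cell A of
#' psi_i(r) psi_a(r) dr`, with the energy denominators
#' `eps_i - eps_a` (occupied minus virtual, strictly negative) cached.
#'
#' @param mos a validated [spin_orbitals]
#' @param grid a `molecular_grid` built for the same geometry
#' @param ao_values AO values on `grid$points` from [eval_basis]
#' @param gap_tol occupied-virtual gaps below this (hartree) abort with a
#'   near-degeneracy error, since the response formula diverges (default
#'   `1e-6`)
#' @param virtual_cutoff optional energy cutoff (hartree): virtuals above it
#'   are dropped from the sums; the default (`NULL`) keeps all virtuals, and
#'   any cutoff used is recorded in the provenance metadata
#' @return an object of class `transition_moments`
#' @export
transition_moments <- function(mos, grid, ao_values, gap_tol = 1e-6,
                               virtual_cutoff = NULL) {
  stopifnot(inherits(mos, "spin_orbitals"), inherits(grid, "molecular_grid"))
  nat <- n_atoms(grid$geometry)
  chan <- function(spin) {
    co <- occupied_coeff(mos, spin)
    cv <- virtual_coeff(mos, spin)
    eo <- mos$energy[[spin]][mos$occ[[spin]] == 1]
    ev <- mos$energy[[spin]][mos$occ[[spin]] == 0]
    if (!is.null(virtual_cutoff)) {
      keep <- ev <= virtual_cutoff
      cv <- cv[, keep, drop = FALSE]
      ev <- ev[keep]
    }
    if (ncol(co) == 0 || ncol(cv) == 0) {
      return(list(moments = array(0, c(ncol(co), ncol(cv), nat)),
                  denom = matrix(0, ncol(co), ncol(cv)),
                  occ_energy = eo, vir_energy = ev))
    }
    denom <- outer(eo, ev, "-")
    bad <- which(abs(denom) < gap_tol, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "near-degeneracy: %s occupied orbital %d and virtual orbital %d are separated by %.2e hartree (< %.0e); the response formula diverges",
        spin, bad[1, 1], bad[1, 2], abs(denom[bad[1, 1], bad[1, 2]]), gap_tol))
    }
    vo <- ao_values %*% co
    vv <- ao_values %*% cv
    m <- array(0, c(ncol(co), ncol(cv), nat))
    for (a in seq_len(nat)) {
      idx <- grid$owner_atom == a & grid$weights > 0
      m[, , a] <- crossprod(vo[idx, , drop = FALSE] * grid$weights[idx],
                            vv[idx, , drop = FALSE])
    }
    list(moments = m, denom = denom, occ_energy = eo, vir_energy = ev)
  }
  a <- chan("alpha")
  b <- if (mos$restricted) a else chan("beta")
  structure(
    list(alpha = a, beta = b, restricted = mos$restricted,
         labels = atom_labels(grid$geometry), n_atoms = nat,
         provenance = list(n_radial = grid$n_radial,
                           n_angular = grid$n_angular,
                           virtual_cutoff = virtual_cutoff)),
    class = "transition_moments")
}

#' @export
print.transition_moments <- function(x, ...) {
  cat(sprintf("transition_moments: %d x %d (alpha), %d x %d (beta) pairs over %d atoms\n",
              nrow(x$alpha$denom), ncol(x$alpha$denom),
              nrow(x$beta$denom), ncol(x$beta$denom), x$n_atoms))
  invisible(x)
}

# One spin channel's condensed response matrix; exactly symmetric and
# negative semidefinite by construction (-W'W with real W).
.channel_condensed <- function(ch, nat) {
  np <- length(ch$denom)
  if (np == 0) return(matrix(0, nat, nat))
  m <- matrix(ch$moments, nrow = np, ncol = nat)
  w <- m * sqrt(-1 / as.vector(ch$denom))
  -crossprod(w)
}

.new_condensed_lrf <- function(k, kind, labels, provenance) {
  dimnames(k) <- list(labels, labels)
  structure(list(matrix = k, kind = kind, labels = labels,
                 provenance = provenance),
            class = "condensed_lrf")
}

#' Atom-condensed linear response function of the electron density
#'
#' `K[I, J] = sum over spins, occupied i, virtual a of
#' M[i, a, I] * M[i, a, J] / (eps_i - eps_a)`. The denominator is occupied
#' minus virtual, so the matrix is negative semidefinite: a negative
#' `K[I, J]` means the density at atom I increases under an attractive
#' perturbation at atom J.
#'
#' @param tm a [transition_moments]
#' @return a `condensed_lrf` of kind `"density"`
#' @export
condensed_lrf_density <- function(tm) {
  stopifnot(inherits(tm, "transition_moments"))
  k <- .channel_condensed(tm$alpha, tm$n_atoms) +
    .channel_condensed(tm$beta, tm$n_atoms)
  .new_condensed_lrf(k, "density", tm$labels, tm$provenance)
}

#' Atom-condensed linear response function of the spin density
#'
#' Response of `rho_z = rho_alpha - rho_beta` to a virtual magnetic-field
#' perturbation: the alpha-channel sum minus the beta-channel sum. For
#' exactly closed-shell (duplicated-channel) input the result is an explicit
#' zero matrix.
#'
#' @param tm a [transition_moments]
#' @return a `condensed_lrf` of kind `"spin"`
#' @export
condensed_lrf_spin <- function(tm) {
  stopifnot(inherits(tm, "transition_moments"))
  k <- if (tm$restricted) {
    matrix(0, tm$n_atoms, tm$n_atoms)
  } else {
    .channel_condensed(tm$alpha, tm$n_atoms) -
      .channel_condensed(tm$beta, tm$n_atoms)
  }
  .new_condensed_lrf(k, "spin", tm$labels, tm$provenance)
}

#' @export
print.condensed_lrf <- function(x, ...) {
  cat(sprintf("condensed_lrf (%s): %d x %d atoms; max |K| = %.4g\n",
              x$kind, nrow(x$matrix), ncol(x$matrix), max(abs(x$matrix))))
  invisible(x)
}

#' Pointwise response field for one perturbing atom
#'
#' `delta rho(r) / delta v(J) = sum over spins, i, a of
#' psi_i(r) psi_a(r) M[i, a, J] / (eps_i - eps_a)` evaluated on arbitrary
#' points (for the spin kind, the channel difference).
#'
#' @param mos the [spin_orbitals] used to build `tm`
#' @param shells,geom basis and geometry for AO evaluation
#' @param tm a [transition_moments]
#' @param j_atom perturbing atom index
#' @param points M x 3 evaluation points (bohr)
#' @param kind `"density"` or `"spin"`
#' @return numeric vector of field values on `points`
#' @export
lrf_field <- function(mos, shells, geom, tm, j_atom, points, kind = "density") {
  kind <- match.arg(kind, c("density", "spin"))
  if (!(j_atom %in% seq_len(tm$n_atoms))) stop("perturbing atom out of range")
  ao <- eval_basis(shells, geom, points)
  chan_field <- function(ch, spin) {
    if (length(ch$denom) == 0) return(numeric(nrow(points)))
    b <- ch$moments[, , j_atom, drop = FALSE]
    dim(b) <- dim(ch$denom)
    b <- b / ch$denom
    vo <- ao %*% occupied_coeff(mos, spin)
    cv <- virtual_coeff(mos, spin)
    if (!is.null(tm$provenance$virtual_cutoff)) {
      cv <- cv[, mos$energy[[spin]][mos$occ[[spin]] == 0] <= tm$provenance$virtual_cutoff,
               drop = FALSE]
    }
    vv <- ao %*% cv
    rowSums((vo %*% b) * vv)
  }
  fa <- chan_field(tm$alpha, "alpha")
  if (kind == "spin" && tm$restricted) return(numeric(nrow(points)))
  fb <- if (tm$restricted) fa else chan_field(tm$beta, "beta")
  if (kind == "density") fa + fb else fa - fb
}

#' Write a response field for one perturbing atom as a cube file
#'
#' @inheritParams lrf_field
#' @param path output cube path
#' @param n,pad lattice resolution and padding, see [cube_lattice]
#' @export
write_lrf_cube <- function(path, mos, shells, geom, tm, j_atom,
                           kind = "density", n = 80, pad = 4) {
  lat <- cube_lattice(geom, n = n, pad = pad)
  f <- lrf_field(mos, shells, geom, tm, j_atom, lat$points, kind = kind)
  write_cube(path, geom, lat, f,
             comment = c(sprintf("%s response to a perturbation at atom %d (%s)",
                                 kind, j_atom, tm$labels[j_atom]),
                         "thresholds +-0.1 +-0.01 +-0.001; + blue, - red"))
  invisible(path)
}

#' Finite-difference oracle for the condensed density response
#'
#' Builds the one-electron perturbation `V_J = lambda * 1_cell_J(r)` in the
#' MO basis by quadrature, applies non-self-consistent first-order orbital
#' mixing, recomputes the condensed density, and returns
#' `(rho_perturbed - rho) / (2 lambda)` per atom. The factor 2 converts the
#' doubled first-order density change of the squared perturbed orbitals
#' (`2 psi_i delta psi_i` plus higher order) to the response kernel's
#' normalization, in which each occupied-virtual pair contributes once.
#' Converges to column J of [condensed_lrf_density] as `lambda -> 0`; kept
#' algorithmically independent of the factorized contraction as a
#' cross-check.
#'
#' @param mos a [spin_orbitals]
#' @param grid a `molecular_grid`
#' @param ao_values AO values on the grid
#' @param j_atom perturbed atom index
#' @param lambda perturbation strength (hartree; default `1e-4`)
#' @return per-atom vector `delta rho / lambda`
#' @export
finite_difference_oracle <- function(mos, grid, ao_values, j_atom,
                                     lambda = 1e-4) {
  nat <- n_atoms(grid$geometry)
  if (!(j_atom %in% seq_len(nat))) stop("perturbed atom out of range")
  if (lambda == 0) {
    out <- numeric(nat)
    names(out) <- atom_labels(grid$geometry)
    return(out)
  }
  idx <- grid$owner_atom == j_atom & grid$weights > 0
  base <- condensed_density(density_on_grid(mos, ao_values)$rho, grid)
  pert <- lapply(c(alpha = "alpha", beta = "beta"), function(spin) {
    cs <- mos$coeff[[spin]]
    mo_vals <- ao_values %*% cs
    v <- lambda * crossprod(mo_vals[idx, , drop = FALSE] * grid$weights[idx],
                            mo_vals[idx, , drop = FALSE])
    occ <- mos$occ[[spin]] == 1
    en <- mos$energy[[spin]]
    # first-order sanity: the perturbation must not reorder occupied/virtual
    e1 <- en + diag(v)
    if (any(occ) && any(!occ) && max(e1[occ]) >= min(e1[!occ])) {
      stop("oracle invalid: lambda is large enough to reorder orbitals")
    }
    x <- v[!occ, occ, drop = FALSE] /
      outer(en[!occ], en[occ], function(a, i) -(a - i))   # (eps_i - eps_a)
    cs[, occ, drop = FALSE] + cs[, !occ, drop = FALSE] %*% x
  })
  rho_p <- rowSums((ao_values %*% pert$alpha)^2) +
    rowSums((ao_values %*% pert$beta)^2)
  (condensed_density(rho_p, grid) - base) / (2 * lambda)
}

#' Export a condensed response matrix as atom-labeled CSV
#' @param lrf a `condensed_lrf`
#' @param path output path
#' @export
write_lrf_csv <- function(lrf, path) {
  # 17 significant digits so a read-back reproduces the matrix exactly
  df <- as.data.frame(apply(lrf$matrix, 2, function(x) sprintf("%.17g", x)),
                      optional = TRUE)
  names(df) <- lrf$labels
  utils::write.csv(cbind(atom = lrf$labels, df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export a condensed response matrix as JSON with a provenance block
#' @param lrf a `condensed_lrf`
#' @param path output path
#' @param source optional description of the orbital source (path or tag)
#' @export
write_lrf_json <- function(lrf, path, source = NULL) {
  prov <- lrf$provenance
  if (!is.null(source)) {
    prov$source <- source
    if (is.character(source) && length(source) == 1 && file.exists(source)) {
      prov$source_md5 <- unname(tools::md5sum(source))
    }
  }
  jsonlite::write_json(
    list(kind = lrf$kind, labels = lrf$labels,
         matrix = unname(lrf$matrix), provenance = prov),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
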