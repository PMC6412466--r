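# Analytic toy systems with prescribed broken-symmetry structure.
#
# Site functions are normalized s-Gaussians, symmetrically (Lowdin)
# orthogonalized before forming bonding/antibonding combinations, so the
# two-site identities (T = cos 2 theta, b = sum T, the two-site spin-density
# closed form) hold exactly in the orthogonalized site basis.
#
# Defaults emulate a stretched two-site bond in the regime where
# broken-symmetry solutions exist: site separation 3.2 bohr, compact site
# exponent 2.5 bohr^-2 (inter-site overlap ~ 3e-6, consistent with the
# two-site model's neglect of inter-site overlap), orbital gap 0.5 hartree.

# Analytic overlap of normalized s-Gaussians.
.ss_overlap <- function(a, b, r) {
  (2 * sqrt(a * b) / (a + b))^1.5 * exp(-a * b / (a + b) * r^2)
}

# Inverse square root of a symmetric positive-definite matrix.
.inv_sqrt <- function(s) {
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) <= 0) stop("overlap matrix not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Build a two-electron two-site broken-symmetry toy system
#'
#' The alpha occupied orbital is `cos(theta) phi_bond + sin(theta) phi_anti`
#' and the beta occupied orbital is `cos(theta) phi_bond - sin(theta)
#' phi_anti`; the virtuals are the orthogonal complements. `phi_bond` /
#' `phi_anti` are the (+)/(-) combinations of Lowdin-orthogonalized s-Gaussian
#' site functions on the two centers.
#'
#' @param theta mixing angle in radians (0 = closed shell, pi/4 = fully
#'   localized singlet diradical)
#' @param eps_bond energy of the occupied orbital (hartree)
#' @param eps_anti energy of the virtual orbital (hartree); must exceed
#'   `eps_bond`
#' @param separation inter-site distance (bohr)
#' @param exponent s-Gaussian site exponent (1/bohr^2)
#' @return an object of class `toy_system` (also a valid
#'   geometry/shells/mos triple) with the analytic AO `overlap`, the Lowdin
#'   `site_coeff` matrix, and the stored `theta`
#' @export
build_two_site_toy <- function(theta, eps_bond = -0.25, eps_anti = 0.25,
                               separation = 3.2, exponent = 2.5) {
  if (eps_bond >= eps_anti) {
    stop("degenerate gap: eps_bond must be strictly below eps_anti")
  }
  if (separation <= 0) stop("separation must be positive")
  geom <- geometry(c("H", "H"),
                   rbind(c(0, 0, -separation / 2), c(0, 0, separation / 2)))
  shells <- list(gaussian_shell(1, 0, exponent, 1),
                 gaussian_shell(2, 0, exponent, 1))
  s12 <- .ss_overlap(exponent, exponent, separation)
  s_ao <- rbind(c(1, s12), c(s12, 1))
  site <- .inv_sqrt(s_ao)                       # AO x orthonormal-site
  bond <- (site[, 1] + site[, 2]) / sqrt(2)
  anti <- (site[, 1] - site[, 2]) / sqrt(2)
  ca <- cbind(occ = cos(theta) * bond + sin(theta) * anti,
              vir = -sin(theta) * bond + cos(theta) * anti)
  cb <- cbind(occ = cos(theta) * bond - sin(theta) * anti,
              vir = sin(theta) * bond + cos(theta) * anti)
  mos <- spin_orbitals(
    coeff = list(alpha = ca, beta = cb),
    energy = list(alpha = c(eps_bond, eps_anti), beta = c(eps_bond, eps_anti)),
    occ = list(alpha = c(1, 0), beta = c(1, 0)),
    restricted = FALSE)
  structure(
    list(geometry = geom, shells = shells, mos = mos, overlap = s_ao,
         site_coeff = site, theta = theta,
         eps_bond = eps_bond, eps_anti = eps_anti,
         separation = separation, exponent = exponent),
    class = "toy_system")
}

#' Build a stack of independent broken-symmetry pairs
#'
#' One two-site unit per mixing angle, displaced far apart along x so the
#' units do not overlap; the corresponding-orbital spectrum of the combined
#' system is `cos(2 theta_i)`.
#'
#' @param thetas vector of mixing angles (radians)
#' @param pair_spacing displacement between consecutive units (bohr)
#' @inheritParams build_two_site_toy
#' @return a `toy_system` with `2 * length(thetas)` atoms
#' @export
build_pair_stack_toy <- function(thetas, eps_bond = -0.25, eps_anti = 0.25,
                                 separation = 3.2, exponent = 2.5,
                                 pair_spacing = 12) {
  if (eps_bond >= eps_anti) {
    stop("degenerate gap: eps_bond must be strictly below eps_anti")
  }
  k <- length(thetas)
  xyz <- do.call(rbind, lapply(seq_len(k), function(i) {
    rbind(c((i - 1) * pair_spacing, 0, -separation / 2),
          c((i - 1) * pair_spacing, 0, separation / 2))
  }))
  geom <- geometry(rep("H", 2 * k), xyz)
  shells <- lapply(seq_len(2 * k), function(a) gaussian_shell(a, 0, exponent, 1))
  nao <- 2 * k
  s_ao <- diag(nao)
  for (i in seq_len(nao - 1)) {
    for (j in (i + 1):nao) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      s_ao[i, j] <- s_ao[j, i] <- .ss_overlap(exponent, exponent, r)
    }
  }
  site <- .inv_sqrt(s_ao)
  ca <- matrix(0, nao, nao)
  cb <- matrix(0, nao, nao)
  for (i in seq_len(k)) {
    s1 <- site[, 2 * i - 1]
    s2 <- site[, 2 * i]
    bond <- (s1 + s2) / sqrt(2)
    anti <- (s1 - s2) / sqrt(2)
    th <- thetas[i]
    ca[, i] <- cos(th) * bond + sin(th) * anti
    ca[, k + i] <- -sin(th) * bond + cos(th) * anti
    cb[, i] <- cos(th) * bond - sin(th) * anti
    cb[, k + i] <- sin(th) * bond + cos(th) * anti
  }
  # tiny energy stagger keeps the canonical sort stable across pairs
  en <- c(eps_bond + 1e-3 * (seq_len(k) - 1), eps_anti + 1e-3 * (seq_len(k) - 1))
  occ <- c(rep(1, k), rep(0, k))
  mos <- spin_orbitals(coeff = list(alpha = ca, beta = cb),
                       energy = list(alpha = en, beta = en),
                       occ = list(alpha = occ, beta = occ))
  structure(
    list(geometry = geom, shells = shells, mos = mos, overlap = s_ao,
         site_coeff = site, theta = thetas,
         eps_bond = eps_bond, eps_anti = eps_anti,
         separation = separation, exponent = exponent),
    class = "toy_system")
}

#' Build a closed-shell linear-chain (or ring) toy system
#'
#' s-Gaussian sites on a line, Lowdin orthogonalized; model orbitals are the
#' eigenvectors of a nearest-neighbor tight-binding Hamiltonian in the
#' orthonormal site basis, with the eigenvalues as orbital energies. The
#' lowest `floor(n_sites / 2)` orbitals are doubly occupied (closed shell).
#'
#' @param n_sites number of sites (>= 3)
#' @param coupling nearest-neighbor coupling(s) in hartree; scalar or a
#'   vector of length `n_sites - 1` (the gap profile)
#' @param site_energy on-site energies (hartree); scalar or one per site.
#'   A monotone site-energy ramp breaks the alternant end-to-end pairing of
#'   uniform chains and yields near-sighted (distance-decaying) responses.
#' @param separation nearest-neighbor distance (bohr)
#' @param exponent s-Gaussian site exponent (1/bohr^2)
#' @param ring close the chain into a ring
#' @param n_occ number of doubly occupied orbitals; default
#'   `floor(n_sites / 2)` (half filling). Set explicitly for rings, where
#'   half filling can split a degenerate shell.
#' @return a `toy_system`; `$hamiltonian` holds the model Hamiltonian and
#'   `$mos` the derived orbitals
#' @export
make_chain_toy <- function(n_sites, coupling = -0.25, site_energy = 0,
                           separation = 3.2, exponent = 2.5, ring = FALSE,
                           n_occ = NULL) {
  if (n_sites < 3) stop("chain toy needs at least 3 sites")
  if (length(coupling) == 1) coupling <- rep(coupling, n_sites - 1)
  if (length(coupling) != n_sites - 1) {
    stop("coupling must be scalar or length n_sites - 1")
  }
  xyz <- cbind(0, 0, separation * (seq_len(n_sites) - 1))
  if (ring) {
    # regular polygon in the yz plane so all neighbor distances are equal
    rad <- separation / (2 * sin(pi / n_sites))
    ang <- 2 * pi * (seq_len(n_sites) - 1) / n_sites
    xyz <- cbind(0, rad * cos(ang), rad * sin(ang))
  }
  geom <- geometry(rep("H", n_sites), xyz)
  shells <- lapply(seq_len(n_sites), function(a) gaussian_shell(a, 0, exponent, 1))
  s_ao <- diag(n_sites)
  for (i in seq_len(n_sites - 1)) {
    for (j in (i + 1):n_sites) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      s_ao[i, j] <- s_ao[j, i] <- .ss_overlap(exponent, exponent, r)
    }
  }
  site <- .inv_sqrt(s_ao)
  if (length(site_energy) == 1) site_energy <- rep(site_energy, n_sites)
  if (length(site_energy) != n_sites) {
    stop("site_energy must be scalar or length n_sites")
  }
  h <- diag(site_energy)
  for (i in seq_len(n_sites - 1)) {
    h[i, i + 1] <- h[i + 1, i] <- coupling[i]
  }
  if (ring) h[1, n_sites] <- h[n_sites, 1] <- coupling[1]
  e <- eigen(h, symmetric = TRUE)
  ord <- order(e$values)
  cmo <- site %*% e$vectors[, ord]
  en <- e$values[ord]
  nocc <- if (is.null(n_occ)) floor(n_sites / 2) else n_occ
  if (nocc < 1 || nocc >= n_sites) stop("n_occ must be in [1, n_sites - 1]")
  occ <- c(rep(1, nocc), rep(0, n_sites - nocc))
  mos <- spin_orbitals(coeff = list(alpha = cmo, beta = cmo),
                       energy = list(alpha = en, beta = en),
                       occ = list(alpha = occ, beta = occ),
                       restricted = TRUE)
  structure(
    list(geometry = geom, shells = shells, mos = mos, overlap = s_ao,
         site_coeff = site, hamiltonian = h, separation = separation,
         exponent = exponent, ring = ring),
    class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy_system: %d atoms, %d AOs%s\n", n_atoms(x$geometry),
              nrow(x$mos$coeff$alpha),
              if (!is.null(x$theta)) {
                paste0(", theta = ", paste(signif(x$theta, 6), collapse = ", "))
              } else ""))
  invisible(x)
}

#' Broken-symmetry scan with attached closed-form expectations
#'
#' An evenly spaced grid of mixing angles over `theta_range`; every entry
#' carries its own expected diagnostics computed from the closed forms
#' `T = cos(2 theta)`, `b = T`, `B = 2T / (1 + T^2)`, `y = 1 - B`, which are
#' independent of the diagnostic code under test.
#'
#' @param n_points number of scan points
#' @param theta_range range of mixing angles within `[0, pi/4]`
#' @param ... forwarded to [build_two_site_toy]
#' @return list of records with elements `toy` and `expected`
#' @export
make_bs_scan <- function(n_points = 11, theta_range = c(0, pi / 4), ...) {
  if (theta_range[1] < 0 || theta_range[2] > pi / 4) {
    stop("theta_range must lie within [0, pi/4]")
  }
  thetas <- seq(theta_range[1], theta_range[2], length.out = n_points)
  lapply(thetas, function(th) {
    t1 <- cos(2 * th)
    bb <- 2 * t1 / (1 + t1^2)
    list(toy = build_two_site_toy(th, ...),
         expected = list(theta = th, T = t1, b = t1, B = bb, y = 1 - bb,
                         n_bond = 1 + t1, n_anti = 1 - t1))
  })
}

#' Generate a small-molecule Molden fixture with an external SCF engine
#'
#' `engine` is a hook: a function taking `(spec, path)` that runs an
#' unrestricted SCF and writes a Molden file. When no engine is supplied
#' (the default) the operation returns a skip marker instead of failing, so
#' test suites remain self-sufficient.
#'
#' @param molecule_spec arbitrary specification forwarded to the engine
#' @param path output Molden path
#' @param engine optional engine hook function
#' @return list with `skipped`/`path` fields
#' @export
make_molden_fixture <- function(molecule_spec, path, engine = NULL) {
  if (is.null(engine)) {
    return(list(skipped = TRUE, reason = "external SCF engine absent"))
  }
  engine(molecule_spec, path)
  list(skipped = FALSE, path = path)
}

#' Write a synthetic broken-symmetry Molden file from the toy generator
#'
#' Not an SCF result: a two-site toy at the given angle exported through the
#' package's Molden writer, for parser and pipeline tests.
#'
#' @param path output path
#' @param theta mixing angle (radians)
#' @param ... forwarded to [build_two_site_toy]
#' @return the toy system, invisibly
#' @export
write_synthetic_bs_molden <- function(path, theta = pi / 8, ...) {
  toy <- build_two_site_toy(theta, ...)
  write_molden(toy$geometry, toy$shells, toy$mos, path)
  invisible(toy)
}
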