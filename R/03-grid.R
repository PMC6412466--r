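# Atom-centered quadrature with hard Wigner-Seitz (nearest-atom Voronoi)
# cell ownership. Radial: Euler-Maclaurin in the Murray-Handy-Laming m = 2
# mapping scaled by the element's Bragg-Slater radius. Angular: Lebedev.

#' Euler-Maclaurin radial quadrature
#'
#' Murray-Handy-Laming m = 2 points `r_k = R a * q^2 / (1-q)^2`, `q = k/n`,
#' `k = 1..n-1`, with weights `2 Ra^3 q^5 / (1-q)^7 / n` that already absorb
#' the `r^2` Jacobian: `sum(w * f(r))` approximates `integral f(r) r^2 dr`
#' over `[0, Inf)`.
#'
#' @param n number of radial divisions (the rule has `n - 1` interior points);
#'   default 50
#' @param atom_element element symbol fixing the radius scale `Ra`
#' @param fallback_radius optional radius in bohr for elements missing from
#'   the Bragg-Slater table
#' @return list with `radii` and `weights`, each length `n - 1`
#' @export
build_radial_grid <- function(n = 50, atom_element = "H", fallback_radius = NULL) {
  if (n < 2) stop("radial grid needs n >= 2")
  ra <- bragg_slater_radius(atom_element, fallback = fallback_radius)
  q <- seq_len(n - 1) / n
  list(radii = ra * q^2 / (1 - q)^2,
       weights = 2 * ra^3 * q^5 / (1 - q)^7 / n)
}

#' Lebedev angular quadrature on the unit sphere
#'
#' Octahedrally symmetric point sets of Lebedev and Laikov, regenerated from
#' their published orbit parameters. Weights are normalized to sum to 1, so
#' `sum(w * f(x))` approximates the spherical mean `(1/4pi) integral f dOmega`.
#'
#' @param n number of angular points; supported: 6, 26, 50, 110, 302
#' @return list with `unit_points` (n x 3) and `weights` (length n, sum 1)
#' @export
build_lebedev <- function(n = 302) {
  key <- as.character(n)
  if (!key %in% names(.lebedev_orbits)) {
    stop("unsupported Lebedev order ", n, "; supported: ",
         paste(names(.lebedev_orbits), collapse = ", "))
  }
  orb <- .lebedev_orbits[[key]]
  pts <- vector("list", nrow(orb))
  wts <- vector("list", nrow(orb))
  for (i in seq_len(nrow(orb))) {
    p <- .lebedev_orbit_points(orb[i, 1], orb[i, 2], orb[i, 3])
    pts[[i]] <- p
    wts[[i]] <- rep(orb[i, 4], nrow(p))
  }
  list(unit_points = do.call(rbind, pts), weights = unlist(wts))
}

# Expand one symmetry orbit of the octahedral group.
.lebedev_orbit_points <- function(type, a, b) {
  sgn <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1)))
  if (type == 1) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (type == 2) {
    v <- 1 / sqrt(2)
    do.call(rbind, lapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ax) {
      m <- matrix(0, 4, 3)
      s <- as.matrix(expand.grid(c(v, -v), c(v, -v)))
      m[, ax] <- s
      m
    }))
  } else if (type == 3) {
    v <- 1 / sqrt(3)
    sgn * v
  } else if (type == 4) {
    # (a, a, b) with 2 a^2 + b^2 = 1: 24 points
    do.call(rbind, lapply(1:3, function(bpos) {
      s <- sgn
      m <- matrix(a, 8, 3)
      m[, bpos] <- b
      unique(m * s)
    }))
  } else if (type == 5) {
    # (a, b, 0) with a^2 + b^2 = 1: 24 points
    b <- sqrt(max(0, 1 - a^2))
    pat <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
    do.call(rbind, lapply(seq_len(nrow(pat)), function(i) {
      m <- matrix(0, 4, 3)
      s <- as.matrix(expand.grid(c(1, -1), c(1, -1)))
      m[, pat[i, 1]] <- a * s[, 1]
      m[, pat[i, 2]] <- b * s[, 2]
      m
    }))
  } else if (type == 6) {
    # (a, b, c): 48 points
    cc <- sqrt(max(0, 1 - a^2 - b^2))
    perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    v <- c(a, b, cc)
    do.call(rbind, lapply(seq_len(nrow(perms)), function(i) {
      sweep(sgn, 2, v[perms[i, ]], "*")
    }))
  } else stop("unknown orbit type ", type)
}

#' Assemble the molecular Wigner-Seitz quadrature grid
#'
#' A product (radial x angular) grid is placed on every atom; each point is
#' assigned to the Wigner-Seitz cell of its nearest atom (ties broken by
#' lowest atom index). The scheme is a hard partition: a point contributes to
#' integrals if and only if it lies inside its parent atom's own cell
#' (`owner == parent`); points falling in another atom's cell are retained in
#' the structure with their base weights but carry zero effective weight, so
#' that every region of space is integrated by exactly one atomic quadrature.
#'
#' @param geom a [geometry]
#' @param n_radial radial divisions per atom (default 50)
#' @param n_angular Lebedev order (default 302)
#' @param fallback_radius optional radius in bohr for unknown elements
#' @param weight_cutoff optional base-weight screening threshold (default
#'   `0`, i.e. no pruning, matching the fixed product grid)
#' @return an object of class `molecular_grid` with fields `points`
#'   (M x 3, bohr), `base_weights`, `weights` (effective), `parent_atom`,
#'   `owner_atom`, `n_radial`, `n_angular`
#' @export
assemble_ws_grid <- function(geom, n_radial = 50, n_angular = 302,
                             fallback_radius = NULL, weight_cutoff = 0) {
  stopifnot(inherits(geom, "geometry"))
  leb <- build_lebedev(n_angular)
  nat <- n_atoms(geom)
  pts <- vector("list", nat)
  wts <- vector("list", nat)
  parent <- vector("list", nat)
  for (a in seq_len(nat)) {
    rad <- build_radial_grid(n_radial, geom$element[a], fallback_radius)
    nr <- length(rad$radii)
    nl <- nrow(leb$unit_points)
    # outer product: radius-major blocks of Lebedev shells
    p <- leb$unit_points[rep(seq_len(nl), times = nr), , drop = FALSE] *
      rad$radii[rep(seq_len(nr), each = nl)]
    p <- sweep(p, 2, geom$xyz[a, ], "+")
    w <- 4 * pi * rad$weights[rep(seq_len(nr), each = nl)] *
      leb$weights[rep(seq_len(nl), times = nr)]
    keep <- w > weight_cutoff | weight_cutoff == 0
    pts[[a]] <- p[keep, , drop = FALSE]
    wts[[a]] <- w[keep]
    parent[[a]] <- rep.int(a, sum(keep))
  }
  points <- do.call(rbind, pts)
  base_weights <- unlist(wts)
  parent_atom <- unlist(parent)
  owner_atom <- .nearest_atom(points, geom$xyz)
  weights <- base_weights * (owner_atom == parent_atom)
  structure(
    list(points = points, base_weights = base_weights, weights = weights,
         parent_atom = parent_atom, owner_atom = owner_atom,
         n_radial = n_radial, n_angular = n_angular, geometry = geom),
    class = "molecular_grid")
}

# Nearest atom index for each point; ties go to the lowest atom index
# (which.min's convention) -- a measure-zero deterministic tie-break.
.nearest_atom <- function(points, centers) {
  nat <- nrow(centers)
  d2 <- matrix(0, nrow(points), nat)
  for (a in seq_len(nat)) {
    d2[, a] <- (points[, 1] - centers[a, 1])^2 +
      (points[, 2] - centers[a, 2])^2 + (points[, 3] - centers[a, 3])^2
  }
  max.col(-d2, ties.method = "first")
}

#' @export
print.molecular_grid <- function(x, ...) {
  cat(sprintf(
    "molecular_grid: %d atoms, %d x %d product grid, %d points (%d contributing)\n",
    n_atoms(x$geometry), x$n_radial, x$n_angular, nrow(x$points),
    sum(x$weights > 0)))
  invisible(x)
}

#' Integrate a field over one atom's Wigner-Seitz cell
#'
#' @param values numeric vector of field values on `grid$points`
#' @param grid a `molecular_grid`
#' @param atom 1-based atom index
#' @return the cell integral (scalar)
#' @export
integrate_cell <- function(values, grid, atom) {
  stopifnot(inherits(grid, "molecular_grid"))
  if (length(values) != nrow(grid$points)) stop("values/grid length mismatch")
  nat <- n_atoms(grid$geometry)
  if (!(atom %in% seq_len(nat))) stop("atom index out of range: ", atom)
  idx <- grid$owner_atom == atom
  sum(grid$weights[idx] * values[idx])
}

#' Integrate a field over all space on the molecular grid
#' @param values numeric vector of field values on `grid$points`
#' @param grid a `molecular_grid`
#' @return the whole-space integral (scalar)
#' @export
integrate_grid <- function(values, grid) {
  sum(grid$weights * values)
}

#' Export a molecular grid to CSV (points, weights, parents, owners)
#' @param grid a `molecular_grid`
#' @param path output CSV path
#' @export
write_grid_csv <- function(grid, path) {
  df <- data.frame(
    x = grid$points[, 1], y = grid$points[, 2], z = grid$points[, 3],
    base_weight = grid$base_weights, weight = grid$weights,
    parent_atom = grid$parent_atom, owner_atom = grid$owner_atom)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
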