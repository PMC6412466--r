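# Gaussian basis shells and their evaluation on point sets.
#
# Shells hold primitives (exponent, contraction coefficient for normalized
# primitives) and are either pure (real solid harmonic) or Cartesian.
# Component orders follow the Molden convention:
#   pure:      m = 0, +1, -1, +2, -2, ... (p shells are x, y, z)
#   cart d:    xx yy zz xy xz yz
#   cart f:    xxx yyy zzz xyy xxy xxz xzz yzz yyz xyz
#   cart g:    xxxx yyyy zzzz xxxy xxxz yyyx yyyz zzzx zzzy xxyy xxzz yyzz
#              xxyz yyxz zzxy

#' Construct a Gaussian shell
#'
#' @param center_atom 1-based atom index of the shell center
#' @param l angular momentum (0..4 for s, p, d, f, g)
#' @param exponents primitive exponents (> 0, 1/bohr^2)
#' @param coefficients contraction coefficients over normalized primitives
#' @param pure logical; `TRUE` for real solid-harmonic components,
#'   `FALSE` for Cartesian components (s and p are identical either way)
#' @param normalize renormalize the contracted function (default `TRUE`)
#' @return an object of class `gaussian_shell`
#' @export
gaussian_shell <- function(center_atom, l, exponents, coefficients,
                           pure = TRUE, normalize = TRUE) {
  if (l < 0 || l > 4) stop("angular momentum l = ", l, " unsupported (max g, l = 4)")
  if (length(exponents) < 1) stop("shell needs at least one primitive")
  if (any(exponents <= 0)) stop("primitive exponents must be positive")
  if (length(exponents) != length(coefficients)) {
    stop("exponents/coefficients length mismatch")
  }
  coefficients <- as.numeric(coefficients)
  if (normalize) {
    # <prim_p | prim_q> for identically-normalized primitives of one l
    ap <- outer(exponents, exponents, function(a, b) (2 * sqrt(a * b) / (a + b))^(l + 1.5))
    nrm2 <- as.numeric(t(coefficients) %*% ap %*% coefficients)
    coefficients <- coefficients / sqrt(nrm2)
  }
  structure(
    list(center_atom = as.integer(center_atom), l = as.integer(l),
         exponents = as.numeric(exponents), coefficients = coefficients,
         pure = isTRUE(pure)),
    class = "gaussian_shell")
}

shell_ncomp <- function(shell) {
  if (shell$pure) 2L * shell$l + 1L else ((shell$l + 1L) * (shell$l + 2L)) %/% 2L
}

n_ao <- function(shells) sum(vapply(shells, shell_ncomp, integer(1)))

# Cartesian component exponent triples (i, j, k) in Molden order, per l.
.cart_components <- list(
  `0` = rbind(c(0, 0, 0)),
  `1` = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
  `2` = rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
              c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
  `3` = rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(1, 2, 0), c(2, 1, 0),
              c(2, 0, 1), c(1, 0, 2), c(0, 1, 2), c(0, 2, 1), c(1, 1, 1)),
  `4` = rbind(c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(3, 1, 0), c(3, 0, 1),
              c(1, 3, 0), c(0, 3, 1), c(1, 0, 3), c(0, 1, 3), c(2, 2, 0),
              c(2, 0, 2), c(0, 2, 2), c(2, 1, 1), c(1, 2, 1), c(1, 1, 2)))

.double_factorial <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

# Real solid harmonics r^l * Ybar_lm (orthonormal real spherical harmonics),
# in Molden pure order. x, y, z are coordinate vectors relative to the center.
.solid_harmonics <- function(l, x, y, z) {
  r2 <- x^2 + y^2 + z^2
  if (l == 0) {
    list(rep.int(sqrt(1 / (4 * pi)), length(x)))
  } else if (l == 1) {
    c1 <- sqrt(3 / (4 * pi))                        # Molden p order: x, y, z
    list(c1 * x, c1 * y, c1 * z)
  } else if (l == 2) {
    list(sqrt(5 / (16 * pi)) * (3 * z^2 - r2),       # m = 0
         sqrt(15 / (4 * pi)) * x * z,                # m = +1
         sqrt(15 / (4 * pi)) * y * z,                # m = -1
         sqrt(15 / (16 * pi)) * (x^2 - y^2),         # m = +2
         sqrt(15 / (4 * pi)) * x * y)                # m = -2
  } else if (l == 3) {
    list(sqrt(7 / (16 * pi)) * z * (5 * z^2 - 3 * r2),
         sqrt(21 / (32 * pi)) * x * (5 * z^2 - r2),
         sqrt(21 / (32 * pi)) * y * (5 * z^2 - r2),
         sqrt(105 / (16 * pi)) * z * (x^2 - y^2),
         sqrt(105 / (4 * pi)) * x * y * z,
         sqrt(35 / (32 * pi)) * x * (x^2 - 3 * y^2),
         sqrt(35 / (32 * pi)) * y * (3 * x^2 - y^2))
  } else if (l == 4) {
    list((3 / (16 * sqrt(pi))) * (35 * z^4 - 30 * z^2 * r2 + 3 * r2^2),
         sqrt(45 / (32 * pi)) * x * (7 * z^3 - 3 * z * r2),
         sqrt(45 / (32 * pi)) * y * (7 * z^3 - 3 * z * r2),
         sqrt(45 / (64 * pi)) * (7 * z^2 - r2) * (x^2 - y^2),
         sqrt(45 / (16 * pi)) * (7 * z^2 - r2) * x * y,
         sqrt(315 / (32 * pi)) * z * x * (x^2 - 3 * y^2),
         sqrt(315 / (32 * pi)) * z * y * (3 * x^2 - y^2),
         sqrt(315 / (256 * pi)) * (x^4 - 6 * x^2 * y^2 + y^4),
         sqrt(315 / (16 * pi)) * x * y * (x^2 - y^2))
  } else stop("l > 4 unsupported")
}

#' Evaluate contracted Gaussian basis functions on points
#'
#' @param shells list of [gaussian_shell]
#' @param geom a [geometry] giving the shell centers
#' @param points M x 3 matrix of evaluation points (bohr)
#' @return M x N_AO matrix of AO values
#' @export
eval_basis <- function(shells, geom, points) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("non-finite evaluation points")
  m <- nrow(points)
  out <- matrix(0, m, n_ao(shells))
  col <- 1L
  for (sh in shells) {
    ctr <- geom$xyz[sh$center_atom, ]
    x <- points[, 1] - ctr[1]
    y <- points[, 2] - ctr[2]
    z <- points[, 3] - ctr[3]
    r2 <- x^2 + y^2 + z^2
    l <- sh$l
    if (sh$pure || l <= 1) {
      # radial factor with solid-harmonic normalization
      rad <- rep.int(0, m)
      for (p in seq_along(sh$exponents)) {
        a <- sh$exponents[p]
        nl <- sqrt(2 * (2 * a)^(l + 1.5) / gamma(l + 1.5))
        rad <- rad + sh$coefficients[p] * nl * exp(-a * r2)
      }
      ang <- .solid_harmonics(l, x, y, z)
      for (comp in ang) {
        out[, col] <- rad * comp
        col <- col + 1L
      }
    } else {
      comps <- .cart_components[[as.character(l)]]
      # alpha-dependent common factor and alpha-independent component factor
      radc <- rep.int(0, m)
      for (p in seq_along(sh$exponents)) {
        a <- sh$exponents[p]
        nc <- (2 * a / pi)^0.75 * (4 * a)^(l / 2)
        radc <- radc + sh$coefficients[p] * nc * exp(-a * r2)
      }
      for (ci in seq_len(nrow(comps))) {
        ijk <- comps[ci, ]
        cf <- 1 / sqrt(.double_factorial(2 * ijk[1] - 1) *
                         .double_factorial(2 * ijk[2] - 1) *
                         .double_factorial(2 * ijk[3] - 1))
        out[, col] <- radc * cf * x^ijk[1] * y^ijk[2] * z^ijk[3]
        col <- col + 1L
      }
    }
  }
  out
}

#' Numerical AO overlap matrix on the molecular grid
#'
#' Overlaps are integrated on the same Wigner-Seitz quadrature used for
#' condensation, which doubles as a cross-check of the basis evaluation and
#' the grid (documented accuracy about 1e-6 for well-localized bases at the
#' default 50 x 302 grid).
#'
#' @param ao_values M x N_AO matrix from [eval_basis] on `grid$points`
#' @param grid a `molecular_grid`
#' @return symmetric N_AO x N_AO overlap matrix
#' @export
numerical_overlap <- function(ao_values, grid) {
  s <- crossprod(ao_values * sqrt(grid$weights))
  asym <- max(abs(s - t(s)))
  if (asym > 1e-8) {
    warning(sprintf("overlap asymmetry %.2e exceeds 1e-8: grid may not cover the basis support", asym))
  }
  (s + t(s)) / 2
}
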