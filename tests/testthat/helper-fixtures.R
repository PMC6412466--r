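# Shared fixtures. The standard broken-symmetry toy (theta = pi/8) and its
# default 50 x 302 Wigner-Seitz grid are memoized because several files use
# them; everything is built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# toy + grid + AO values + transition moments for a given mixing angle
toy_pipeline <- function(theta = pi / 8, ...) {
  toy <- build_two_site_toy(theta, ...)
  grid <- assemble_ws_grid(toy$geometry)
  ao <- eval_basis(toy$shells, toy$geometry, grid$points)
  list(toy = toy, grid = grid, ao = ao,
       tm = transition_moments(toy$mos, grid, ao))
}

std_pipeline <- function() memo("std_pi8", toy_pipeline(pi / 8))

closed_shell_pipeline <- function() memo("closed_shell", toy_pipeline(0))

# deep-well chain: rising site energies give a monotone gap profile and
# near-sighted (distance-decaying) responses
locality_chain <- function() {
  memo("locality_chain", {
    ch <- make_chain_toy(4, coupling = -0.1,
                         site_energy = c(-0.5, 0.1, 0.3, 0.6), n_occ = 1)
    grid <- assemble_ws_grid(ch$geometry)
    ao <- eval_basis(ch$shells, ch$geometry, grid$points)
    list(toy = ch, grid = grid, ao = ao,
         tm = transition_moments(ch$mos, grid, ao))
  })
}

# closed form for the two-site condensed response: K = 2 (cos(2 theta) s)^2
# / (eps_bond - eps_anti) * [[1, -1], [-1, 1]], with s the quadrature of
# (chi1^2 - chi2^2) / 2 over cell 1 evaluated directly from the site
# functions (independent of the transition-moment code path).
two_site_closed_form_K <- function(p) {
  chi <- p$ao %*% p$toy$site_coeff
  s <- 0.5 * integrate_cell(chi[, 1]^2 - chi[, 2]^2, p$grid, 1)
  gap <- p$toy$eps_bond - p$toy$eps_anti
  k1 <- 2 * (cos(2 * p$toy$theta) * s)^2 / gap
  list(s = s, K = k1 * rbind(c(1, -1), c(-1, 1)))
}

# analytic overlap of normalized s-Gaussians (Gaussian product theorem)
ss_overlap_exact <- function(a, b, r) {
  (2 * sqrt(a * b) / (a + b))^1.5 * exp(-a * b / (a + b) * r^2)
}

# random orthogonal matrix (QR of a Gaussian matrix, fixed by caller's seed)
random_orthogonal <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n)))
}

# rotation matrix about a random axis
random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  k <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(th) * k + (1 - cos(th)) * k %*% k
}

# --- inline Molden fixture texts -------------------------------------------

molden_h_sto3g <- function(occup = "2.0", units = "AU",
                           coords = c(0, 0, 0)) {
  c("[Molden Format]",
    paste0("[Atoms] ", units),
    sprintf("H 1 1 %.8f %.8f %.8f", coords[1], coords[2], coords[3]),
    "[GTO]",
    "  1 0",
    " s 3 1.00",
    "  3.42525091 0.15432897",
    "  0.62391373 0.53532814",
    "  0.16885540 0.44463454",
    "",
    "[MO]",
    " Sym= a1",
    " Ene= -0.4665819",
    " Spin= Alpha",
    paste0(" Occup= ", occup),
    "  1 1.0")
}

write_fixture <- function(lines) {
  f <- tempfile(fileext = ".molden")
  writeLines(lines, f)
  f
}

# one-atom file with an extra d shell, pure or cartesian
molden_h_with_d <- function(pure = TRUE) {
  c("[Molden Format]",
    if (pure) "[5D]" else NULL,
    "[Atoms] AU",
    "H 1 1 0.0 0.0 0.0",
    "[GTO]",
    "  1 0",
    " s 1 1.00",
    "  1.0 1.0",
    " d 1 1.00",
    "  0.8 1.0",
    "",
    "[MO]",
    " Sym= a1",
    " Ene= -0.5",
    " Spin= Alpha",
    " Occup= 2.0",
    "  1 1.0")
}
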