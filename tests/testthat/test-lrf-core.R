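# Sum-over-states response: transition moments, condensed matrices, fields,
# and the finite-difference cross-check.

test_that("transition moments respect cell symmetry and occupied-virtual orthogonality", {
  # closed shell: the occupied x virtual product is the odd function
  # phi_bond * phi_anti, so the two mirror cells carry opposite moments
  cs <- closed_shell_pipeline()
  m0 <- cs$tm$alpha$moments
  expect_equal(m0[1, 1, 1], -m0[1, 1, 2], tolerance = 1e-10)
  cf0 <- two_site_closed_form_K(cs)
  expect_lt(abs(abs(m0[1, 1, 1]) - abs(cf0$s)), 1e-8)
  # broken symmetry: the mirror maps the alpha product onto the beta
  # product, relating the channels across the two cells exactly
  p <- std_pipeline()
  m <- p$tm$alpha$moments
  mb <- p$tm$beta$moments
  expect_equal(m[1, 1, 1], -mb[1, 1, 2], tolerance = 1e-10)
  # direct quadrature oracle for the alpha moment, even term included:
  # M = cos(2 theta) s - sin(2 theta) u, u = cell-1 integral of chi1 chi2
  chi <- p$ao %*% p$toy$site_coeff
  s <- 0.5 * integrate_cell(chi[, 1]^2 - chi[, 2]^2, p$grid, 1)
  u <- integrate_cell(chi[, 1] * chi[, 2], p$grid, 1)
  th <- p$toy$theta
  expect_equal(m[1, 1, 1], cos(2 * th) * s - sin(2 * th) * u, tolerance = 1e-12)
  # summing cells recovers <psi_occ | psi_vir> = 0
  for (ch in list(p$tm$alpha, p$tm$beta)) {
    tot <- apply(ch$moments, c(1, 2), sum)
    expect_lt(max(abs(tot)), 1e-6)
  }
  # denominators strictly negative
  expect_true(all(p$tm$alpha$denom < 0))
})

test_that("near-degenerate occupied-virtual gaps abort with a clear error", {
  toy <- build_two_site_toy(pi / 8, eps_bond = 0.1, eps_anti = 0.1 + 1e-8)
  g <- assemble_ws_grid(toy$geometry)
  ao <- eval_basis(toy$shells, toy$geometry, g$points)
  expect_error(transition_moments(toy$mos, g, ao), "near-degeneracy")
})

test_that("the condensed density response matches its closed form on the two-level toy", {
  for (theta in c(0, pi / 8)) {
    p <- if (theta == 0) closed_shell_pipeline() else std_pipeline()
    cf <- two_site_closed_form_K(p)
    k <- condensed_lrf_density(p$tm)
    expect_lt(max(abs(k$matrix - cf$K)), 1e-8)
  }
})

test_that("condensed density responses are symmetric, charge conserving, and negative semidefinite", {
  for (p in list(std_pipeline(), closed_shell_pipeline(), locality_chain())) {
    k <- condensed_lrf_density(p$tm)$matrix
    expect_lt(max(abs(k - t(k))), 1e-6)
    expect_lt(max(abs(colSums(k))), 1e-3 * max(abs(k)))
    expect_lt(max(eigen(k, symmetric = TRUE, only.values = TRUE)$values), 1e-6)
  }
})

test_that("the spin response vanishes identically for duplicated-channel input", {
  cs <- closed_shell_pipeline()
  ch <- locality_chain()  # restricted closed-shell chain
  for (p in list(cs, ch)) {
    kz <- condensed_lrf_spin(transition_moments(p$toy$mos, p$grid, p$ao))
    expect_identical(unname(kz$matrix),
                     matrix(0, nrow(kz$matrix), ncol(kz$matrix)))
  }
})

test_that("the spin response equals the explicit channel difference and is symmetric", {
  p <- std_pipeline()
  kz <- condensed_lrf_spin(p$tm)
  ka <- spinlrf:::.channel_condensed(p$tm$alpha, 2)
  kb <- spinlrf:::.channel_condensed(p$tm$beta, 2)
  expect_lt(max(abs(kz$matrix - (ka - kb))), 1e-12)
  expect_lt(max(abs(kz$matrix - t(kz$matrix))), 1e-6)
})

test_that("response fields condense back to the matrix column and respect closed-shell nullity", {
  p <- std_pipeline()
  k <- condensed_lrf_density(p$tm)
  f1 <- lrf_field(p$toy$mos, p$toy$shells, p$toy$geometry, p$tm, 1,
                  p$grid$points, kind = "density")
  back <- condensed_density(f1, p$grid)
  expect_equal(unname(back), unname(k$matrix[, 1]), tolerance = 1e-4)
  # two-site field is proportional to the bond x antibond product shape
  chi <- p$ao %*% p$toy$site_coeff
  prod_ba <- (chi[, 1]^2 - chi[, 2]^2) / 2  # phi_bond * phi_anti, orthonormal sites
  cc <- stats::coef(stats::lm(f1 ~ prod_ba + 0))
  expect_lt(max(abs(f1 - cc * prod_ba)) / max(abs(f1)), 1e-6)
  # closed-shell spin field is identically zero
  cs <- closed_shell_pipeline()
  fz <- lrf_field(cs$toy$mos, cs$toy$shells, cs$toy$geometry,
                  transition_moments(cs$toy$mos, cs$grid, cs$ao), 1,
                  cs$grid$points[1:100, ], kind = "spin")
  expect_identical(fz, numeric(100))
})

test_that("the finite-difference oracle reproduces matrix columns and degrades linearly in lambda", {
  for (p in list(std_pipeline(), locality_chain())) {
    k <- condensed_lrf_density(p$tm)$matrix
    for (j in seq_len(ncol(k))) {
      fd <- finite_difference_oracle(p$toy$mos, p$grid, p$ao, j, 1e-4)
      expect_lt(max(abs(fd - k[, j])), 5e-4 * max(abs(k)))
    }
    # columns across J stay symmetric within the oracle's O(lambda) error
    fd1 <- finite_difference_oracle(p$toy$mos, p$grid, p$ao, 1, 1e-4)
    fd2 <- finite_difference_oracle(p$toy$mos, p$grid, p$ao, 2, 1e-4)
    expect_lt(abs(fd1[[2]] - fd2[[1]]), 1e-3 * max(abs(k)))
  }
  # Richardson: error shrinks ~10x from lambda = 1e-3 to 1e-4
  p <- std_pipeline()
  k <- condensed_lrf_density(p$tm)$matrix
  e3 <- max(abs(finite_difference_oracle(p$toy$mos, p$grid, p$ao, 1, 1e-3) - k[, 1]))
  e4 <- max(abs(finite_difference_oracle(p$toy$mos, p$grid, p$ao, 1, 1e-4) - k[, 1]))
  expect_lt(e4, e3 / 3)
  # lambda = 0 returns an exact zero vector
  expect_identical(unname(finite_difference_oracle(p$toy$mos, p$grid, p$ao, 1, 0)),
                   c(0, 0))
  # a perturbation strong enough to reorder orbitals invalidates the oracle
  expect_error(finite_difference_oracle(p$toy$mos, p$grid, p$ao, 1, 10),
               "reorder")
})

test_that("chain responses are near-sighted on a monotone-gap fixture", {
  p <- locality_chain()
  k <- condensed_lrf_density(p$tm)$matrix
  off <- abs(k[1, 2:4])
  expect_true(all(diff(off) < 0))
  # dual route: the finite-difference oracle sees the same ordering
  fd <- abs(finite_difference_oracle(p$toy$mos, p$grid, p$ao, 1, 1e-4)[2:4])
  expect_true(all(diff(fd) < 0))
  # 3-site monotone-gap chain: nearer neighbor responds more strongly
  ch3 <- make_chain_toy(3, coupling = c(-0.4, -0.2))
  g3 <- assemble_ws_grid(ch3$geometry)
  ao3 <- eval_basis(ch3$shells, ch3$geometry, g3$points)
  k3 <- condensed_lrf_density(transition_moments(ch3$mos, g3, ao3))$matrix
  expect_gt(abs(k3[1, 2]), abs(k3[1, 3]))
  expect_equal(k3[1, 3], k3[3, 1], tolerance = 1e-12)
})

test_that("a virtual-energy cutoff restricts the sums and is recorded in provenance", {
  p <- locality_chain()
  tm_cut <- transition_moments(p$toy$mos, p$grid, p$ao, virtual_cutoff = 0.2)
  expect_lt(ncol(tm_cut$alpha$denom), ncol(p$tm$alpha$denom))
  expect_equal(tm_cut$provenance$virtual_cutoff, 0.2)
  k_full <- condensed_lrf_density(p$tm)$matrix
  k_cut <- condensed_lrf_density(tm_cut)$matrix
  expect_false(isTRUE(all.equal(k_full, k_cut)))
})

test_that("condensed matrices export to labeled CSV/JSON and cubes are written", {
  p <- std_pipeline()
  k <- condensed_lrf_density(p$tm)
  f <- tempfile(fileext = ".csv")
  write_lrf_csv(k, f)
  expect_identical(unname(read_lrf_csv(f)), unname(k$matrix))
  fj <- tempfile(fileext = ".json")
  write_lrf_json(k, fj, source = "two-site toy")
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(j$kind, "density")
  expect_equal(j$provenance$n_angular, 302)
  fc <- tempfile(fileext = ".cube")
  write_lrf_cube(fc, p$toy$mos, p$toy$shells, p$toy$geometry, p$tm, 1,
                 n = 10, pad = 3)
  expect_gt(length(readLines(fc)), 8)
})
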