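# Threshold sections, QM-region suggestion, model-error reports, heat maps.

region_fixture <- function() {
  memo("region_fixture", {
    p <- std_pipeline()
    list(k_rho = condensed_lrf_density(p$tm),
         k_z = condensed_lrf_spin(p$tm),
         p = p)
  })
}

test_that("threshold sections mark the signed exceedances and nest across thresholds", {
  fx <- region_fixture()
  k <- fx$k_rho
  # tau above max |K|: empty
  empty <- threshold_sections(k, 2 * max(abs(k$matrix)), "+")
  expect_equal(sum(empty$members), 0)
  # closed-form membership for the two-site K (positive off-diagonal,
  # negative diagonal, |entries| = 0.5)
  pos <- threshold_sections(k, 0.1, "+")
  neg <- threshold_sections(k, 0.1, "-")
  expect_identical(unname(pos$members),
                   rbind(c(FALSE, TRUE), c(TRUE, FALSE)))
  expect_identical(unname(neg$members),
                   rbind(c(TRUE, FALSE), c(FALSE, TRUE)))
  expect_equal(unname(pos$atom_counts), c(1, 1))
  # nesting over the canonical thresholds
  ch <- locality_chain()
  kc <- condensed_lrf_density(ch$tm)
  for (sgn in c("+", "-")) {
    s1 <- threshold_sections(kc, 0.1, sgn)$members
    s2 <- threshold_sections(kc, 0.01, sgn)$members
    s3 <- threshold_sections(kc, 0.001, sgn)$members
    expect_true(all(s2[s1]))
    expect_true(all(s3[s2]))
  }
  expect_error(threshold_sections(kc, -1), "positive")
})

test_that("QM-region suggestion applies the coupling criteria over the reaction center", {
  fx <- region_fixture()
  # thresholds above every coupling: the reaction center only
  only_rc <- suggest_qm_region(fx$k_rho, fx$k_z, rc = 1,
                               tau_rho = 10, tau_m = 10)
  expect_equal(only_rc$selected, 1L)
  expect_equal(only_rc$rule[1], "reaction_center")
  # tau below |K[1, 2]| = 0.5: both atoms enter
  both <- suggest_qm_region(fx$k_rho, fx$k_z, rc = 1, tau_rho = 0.01)
  expect_equal(both$selected, c(1L, 2L))
  expect_equal(both$rule[2], "density")
  expect_error(suggest_qm_region(fx$k_rho, fx$k_z, rc = 9), "outside")
  expect_error(suggest_qm_region(fx$k_rho, fx$k_z, rc = integer(0)), "non-empty")
})

test_that("region selection grows monotonically with looser thresholds and larger reaction centers", {
  ch <- locality_chain()
  kc <- condensed_lrf_density(ch$tm)
  kz <- condensed_lrf_spin(ch$tm)
  taus <- c(0.3, 0.05, 0.005, 1e-6)
  prev <- integer(0)
  for (tau in taus) {
    sel <- suggest_qm_region(kc, kz, rc = 1, tau_rho = tau, tau_m = tau)$selected
    expect_true(all(prev %in% sel))
    prev <- sel
  }
  sel_small <- suggest_qm_region(kc, kz, rc = 1, tau_rho = 0.05)$selected
  sel_large <- suggest_qm_region(kc, kz, rc = c(1, 4), tau_rho = 0.05)$selected
  expect_true(all(sel_small %in% sel_large))
})

test_that("fragment completion pulls in whole covalent fragments and reports cut bonds", {
  ch <- locality_chain()
  kc <- condensed_lrf_density(ch$tm)
  kz <- condensed_lrf_spin(ch$tm)
  # chain spacing 3.2 bohr exceeds 1.3 x (0.31 + 0.31) A for H-H, so use a
  # constructed geometry: two bonded pairs far apart
  geom <- geometry(rep("H", 4),
                   rbind(c(0, 0, 0), c(0, 0, 1.3),
                         c(20, 0, 0), c(20, 0, 1.3)))
  # reuse the 4-atom chain matrices but with the bonded geometry
  sel <- suggest_qm_region(kc, kz, rc = 1, tau_rho = 10, tau_m = 10,
                           complete_fragments = TRUE, geom = geom)
  expect_equal(sel$selected, c(1L, 2L))
  expect_equal(sel$rule[2], "fragment")
  expect_error(suggest_qm_region(kc, kz, rc = 1, complete_fragments = TRUE),
               "geometry")
  # without completion, crossing bonds are listed for capping
  sel2 <- suggest_qm_region(kc, kz, rc = 1, tau_rho = 10, tau_m = 10,
                            geom = geom)
  expect_equal(sel2$cut_bonds, data.frame(inside = 1L, outside = 2L))
})

test_that("model-error reports difference mapped atoms as model minus full", {
  full <- list(rho = c(6.1, 1.2, 0.9), rhoz = c(0.4, -0.1, 0))
  # identical model: all zeros
  same <- model_error_report(full, full,
                             data.frame(model = 1:3, full = 1:3))
  expect_equal(same$delta_rho, c(0, 0, 0))
  expect_equal(same$max_abs_rhoz, 0)
  # a single shifted cell shows up as exactly that entry
  model <- full
  model$rho[2] <- model$rho[2] + 0.05
  rep1 <- model_error_report(full, model, data.frame(model = 1:3, full = 1:3))
  expect_equal(rep1$delta_rho, c(0, 0.05, 0))
  expect_equal(rep1$max_abs_rho, 0.05)
  expect_error(model_error_report(full, model,
                                  data.frame(model = c(1, 1), full = c(1, 2))),
               "injective")
  expect_error(model_error_report(full, model,
                                  data.frame(model = 4, full = 1)),
               "unmapped")
})

test_that("a single-site cluster model of the toy dimer reproduces the hand-computed cell difference", {
  p <- std_pipeline()
  full_cd <- density_on_grid(p$toy$mos, p$ao)
  full <- list(rho = condensed_density(full_cd$rho, p$grid),
               rhoz = condensed_density(full_cd$rhoz, p$grid))
  # "cluster model": an isolated one-site system with a single electron pair
  geom1 <- geometry("H", rbind(c(0, 0, -p$toy$separation / 2)))
  sh1 <- list(gaussian_shell(1, 0, p$toy$exponent, 1))
  mos1 <- spin_orbitals(coeff = list(alpha = diag(1), beta = diag(1)),
                        energy = list(alpha = -0.25, beta = -0.25),
                        occ = list(alpha = 1, beta = 1), restricted = TRUE)
  g1 <- assemble_ws_grid(geom1)
  d1 <- density_on_grid(mos1, eval_basis(sh1, geom1, g1$points))
  model <- list(rho = condensed_density(d1$rho, g1),
                rhoz = condensed_density(d1$rhoz, g1))
  rep1 <- model_error_report(full, model, data.frame(model = 1, full = 1),
                             label = "one-site cluster")
  expect_equal(rep1$delta_rho, unname(model$rho[1] - full$rho[1]),
               tolerance = 1e-12)
  expect_equal(rep1$delta_rhoz, unname(-full$rhoz[1]), tolerance = 1e-12)
})

test_that("heat-map export round-trips the matrix with 1-based atom labels", {
  fx <- region_fixture()
  f <- tempfile(fileext = ".csv")
  heatmap_export(fx$k_rho, f)
  m <- read_lrf_csv(f)
  expect_identical(unname(m), unname(fx$k_rho$matrix))
  expect_identical(rownames(m), c("H(1)", "H(2)"))
  expect_identical(unname(m), unname(t(m)))
  j <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(j$thresholds, c(0.1, 0.01, 0.001))
  expect_equal(j$color_rule$positive, "blue")
})
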