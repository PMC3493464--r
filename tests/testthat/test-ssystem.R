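test_that("S-system aggregation takes flux-weighted means of exponents", {
  cfg <- default_configs
  m <- build_gma(new_design(config_by_label("A", cfg)))
  # caffeoyl CoA has two consumers (CCR2, methylation) sharing variable X1:
  # fluxes 0.75/0.25 with exponents 0.8/0.4 must aggregate to 0.7
  flux <- c(influx = 1, CCR2 = 0.75, OMT_CCoA = 0.25, free_COMT = 0.375,
            S_channel = 0.375, free_CCR1 = 0.125, G_channel = 0.125,
            free_CAD = 0.25, free_F5H = 0.25, OMT_5OH = 0.425,
            efflux_G = 0.375, efflux_5HG = 0.2, efflux_S = 0.425)
  b <- default_bounds(m)
  k <- sample_kinetic_orders(b, n = 1, seed = 1)[1, ]
  k["CCR2:X1"] <- 0.8
  k["OMT_CCoA:X1"] <- 0.4
  ss <- derive_ssystem(m, flux, k)
  expect_equal(ss$H["X1", "X1"], 0.7)
  expect_equal(ss$alpha[["X1"]], 1)
  expect_equal(ss$beta[["X1"]], 1)
  # alpha equals the sum of production fluxes for every pool
  expect_equal(ss$alpha[["X4"]], 0.5)

  # independent oracle: numerical log-derivative of ln(sum of terms) at the
  # operating point
  f <- function(ly) log(0.75 * exp(0.8 * ly) + 0.25 * exp(0.4 * ly))
  h <- 1e-6
  expect_equal((f(h) - f(-h)) / (2 * h), 0.7, tolerance = 1e-8)

  # a pool with single production and consumption keeps exponents unchanged
  expect_equal(ss$H["X7", "X7"], k[["efflux_S:X7"]])
  expect_equal(ss$G["X7", "X6"], k[["OMT_5OH:X6"]])
})

test_that("derive_ssystem rejects non-positive fluxes", {
  m <- build_gma(new_design(config_by_label("S", default_configs)))
  pt <- enumerate_vertices(build_flux_constraints(m, 0.5))
  flux <- sample_fluxes(pt, n = 1, seed = 1)[1, ]
  k <- sample_kinetic_orders(default_bounds(m), n = 1, seed = 2)[1, ]
  bad <- flux; bad["CCR2"] <- 0
  expect_error(derive_ssystem(m, bad, k), "strictly positive")
})

test_that("identity perturbation returns the wild-type operating point", {
  inst <- random_instance(new_design(config_by_label("A", default_configs),
                                     "M1"), seed = 5)
  sol <- solve_steady_state(inst$ssys, c(CCR1 = 1), rho_wt = 0.5)
  expect_equal(max(abs(sol$y)), 0)
  expect_equal(unname(sol$flux_factors), rep(1, 13))
  expect_equal(sol$sg_ratio, 0.5)
  expect_false(sol$ill_behaved)
  expect_false(sol$degenerate)
  expect_equal(compute_sg_ratio(sol, 0.8), 0.8)
})

test_that("single-pool closed forms, including the 1000-fold rule", {
  # efflux exponent 0.5, enzyme at 25%: Y* = 4^2 = 16-fold rise
  toy <- make_single_pool(h = 0.5)
  sol <- solve_steady_state(toy, c(E1 = 0.25), rho_wt = 1)
  expect_equal(exp(sol$y[["P1"]]), 16, tolerance = 1e-12)
  expect_false(sol$ill_behaved)

  # exponent 0.2: Y* = 4^5 = 1024 > 1000 -> ill-behaved (strict rule)
  toy2 <- make_single_pool(h = 0.2)
  sol2 <- solve_steady_state(toy2, c(E1 = 0.25), rho_wt = 1)
  expect_equal(exp(sol2$y[["P1"]]), 1024, tolerance = 1e-9)
  expect_true(sol2$ill_behaved)

  # exactly 1000-fold is not "more than 1000-fold"
  m1000 <- exp(-log(1000) * 0.2)
  sol3 <- solve_steady_state(make_single_pool(0.2), c(E1 = m1000),
                             rho_wt = 1)
  expect_equal(exp(sol3$y[["P1"]]), 1000, tolerance = 1e-9)
  expect_false(sol3$ill_behaved)

  # GMA oracle reproduces the closed form to 1e-10
  g <- gma_numerical_steady_state(toy, c(E1 = 0.25), rho_wt = 1)
  expect_true(g$converged)
  expect_equal(g$y[["P1"]], log(16), tolerance = 1e-10)
})

test_that("degenerate systems are flagged, not thrown", {
  toy <- make_single_pool(h = 0.5)
  toy$G <- toy$H   # production and consumption exponents cancel
  sol <- solve_steady_state(toy, c(E1 = 0.5), rho_wt = 1)
  expect_true(sol$degenerate)
  expect_false(sol$ok)
  expect_error(compute_sg_ratio(sol, 1), "degenerate")
})

test_that("S-system and GMA solutions coincide at the operating point", {
  cfg <- default_configs
  for (lab in c("A", "I", "S")) {
    inst <- random_instance(new_design(config_by_label(lab, cfg), "M1"),
                            seed = 11)
    ident <- c(CCR1 = 1)
    ss <- solve_steady_state(inst$ssys, ident, 0.5)
    gm <- gma_numerical_steady_state(inst$ssys, ident, 0.5)
    expect_true(gm$converged)
    expect_equal(max(abs(ss$y - gm$y)), 0, tolerance = 1e-10)
  }
})

test_that("GMA and S-system agree to first order on a perturbation ladder", {
  inst <- random_instance(new_design(config_by_label("A", default_configs)),
                          seed = 3)
  errs <- vapply(c(0.1, 0.01, 0.001), function(eps) {
    mult <- c(CCR2 = 1 - eps)
    ss <- solve_steady_state(inst$ssys, mult, 0.5)
    gm <- gma_numerical_steady_state(inst$ssys, mult, 0.5)
    expect_true(gm$converged)
    max(abs(ss$y - gm$y))
  }, numeric(1))
  # second-order convergence: error shrinks ~100x per decade
  expect_lt(errs[2], errs[1] / 20)
  expect_lt(errs[3], errs[2] / 20)
  # 1% perturbations agree to 1e-3 in log space
  expect_lt(errs[2], 1e-3)
})

test_that("channels-only topology responds monotonically to CCR2", {
  d <- new_design(config_by_label("S", default_configs))
  for (seed in 1:20) {
    inst <- random_instance(d, seed = seed)
    sols <- lapply(c(1, 0.5, 0.2), function(v) {
      solve_steady_state(inst$ssys, c(CCR2 = v), 0.5)
    })
    sgs <- vapply(sols, `[[`, numeric(1), "sg_ratio")
    sfac <- vapply(sols, function(s) s$flux_factors[["efflux_S"]],
                   numeric(1))
    expect_true(all(diff(sgs) < 0))
    expect_true(all(diff(sfac) < 0))
  }
})

test_that("solutions are invariant to rescaling all wild-type fluxes", {
  inst <- random_instance(new_design(config_by_label("A", default_configs),
                                     "M1"), seed = 9)
  ss2 <- derive_ssystem(inst$model, 3.7 * inst$flux, inst$korders)
  mult <- c(CCR2 = 0.3, CCR1 = 1.4)
  a <- solve_steady_state(inst$ssys, mult, 0.5)
  b <- solve_steady_state(ss2, mult, 0.5)
  expect_equal(a$y, b$y, tolerance = 1e-10)
  expect_equal(a$sg_ratio, b$sg_ratio, tolerance = 1e-10)
})

test_that("effective multipliers apply hierarchy only when asked", {
  sc <- default_scenarios()$scenarios$ccr2_ko
  m0 <- effective_multipliers(sc, hierarchical = FALSE)
  expect_equal(m0[["CCR2"]], 0.05)
  expect_equal(m0[["CCR1"]], 1)
  m1 <- effective_multipliers(sc, hierarchical = TRUE)
  expect_equal(m1[["CCR1"]], 1.5)
  expect_equal(m1[["CCoAOMT"]], 1.5)
  bad <- sc; bad$multipliers$CCR2 <- -1
  expect_error(effective_multipliers(bad), "positive")
})
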