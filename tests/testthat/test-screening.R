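pred <- function(sg, ill = FALSE, degen = FALSE) {
  list(sg_ratio = sg, ill_behaved = ill, degenerate = degen)
}

obs_set <- function(rho = 0.5, ccoaomt = 0.5, comt = 0.2) {
  ss <- default_scenarios(rho_wt = rho)
  ss$scenarios$CCoAOMT_down$observed_sg <- ccoaomt
  ss$scenarios$COMT_down$observed_sg <- comt
  ss
}

test_that("instantiation verdicts follow the quantitative and qualitative rules", {
  obs <- obs_set()
  ok <- list(CCoAOMT_down = pred(0.5), COMT_down = pred(0.2),
             ccr1_ko = pred(0.25), ccr2_ko = pred(0.75))
  expect_equal(evaluate_instantiation(ok, obs), "valid")

  # the stated MSE arithmetic: (0.45, 0.25) vs (0.50, 0.20) -> 0.0025 < 0.01
  quant <- ok
  quant$CCoAOMT_down <- pred(0.45); quant$COMT_down <- pred(0.25)
  expect_equal(mean(c(0.05, 0.05)^2), 0.0025)
  expect_equal(evaluate_instantiation(quant, obs), "valid")

  # prediction inside the 5% strip fails the qualitative test
  strip <- ok; strip$ccr1_ko <- pred(0.96 * 0.5)
  expect_equal(evaluate_instantiation(strip, obs), "invalid")
  up_strip <- ok; up_strip$ccr2_ko <- pred(1.04 * 0.5)
  expect_equal(evaluate_instantiation(up_strip, obs), "invalid")

  # quantitative miss beyond MSE but within 25% relative error
  obs_big <- obs_set(ccoaomt = 1.0)
  rel <- ok; rel$CCoAOMT_down <- pred(1.24); rel$COMT_down <- pred(0.24)
  expect_gt(mean((c(1.24, 0.24) - c(1.0, 0.2))^2), 0.01)
  expect_equal(evaluate_instantiation(rel, obs_big), "valid_relaxed_only")

  ill <- ok; ill$COMT_down <- pred(0.2, ill = TRUE)
  expect_equal(evaluate_instantiation(ill, obs), "ill_behaved")
  degen <- ok; degen$ccr1_ko <- pred(NA_real_, degen = TRUE)
  expect_equal(evaluate_instantiation(degen, obs), "ill_behaved")

  expect_error(evaluate_instantiation(ok[-1], obs), "missing prediction")
})

test_that("criteria constructor validates its thresholds", {
  cr <- validity_criteria()
  expect_equal(cr$mse_threshold, 0.01)
  expect_equal(cr$qual_margin, 0.05)
  expect_equal(cr$relaxed_pct, 0.25)
  expect_equal(cr$fold_limit, 1000)
  expect_error(validity_criteria(mse_threshold = -1))
})

test_that("screen_design is deterministic and internally consistent", {
  d <- new_design(config_by_label("A", default_configs), c("M2", "M5"))
  obs <- obs_set()
  r1 <- suppressWarnings(screen_design(d, obs, n = 500, seed = 21))
  r2 <- suppressWarnings(screen_design(d, obs, n = 500, seed = 21))
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$Q, r2$Q)
  expect_identical(r1$valid_records, r2$valid_records)

  expect_lte(r1$Q, r1$Q_prime)
  expect_lte(r1$Q_prime, r1$n - r1$n_ill_behaved - r1$n_degenerate)
  expect_gte(r1$n_nw, r1$Q)   # validity implies the northwest quadrant

  expect_error(screen_design(d, obs, n = 0, seed = 1))
})

test_that("tightening thresholds never increases Q", {
  d <- new_design(config_by_label("A", default_configs), c("M2", "M5"))
  obs <- obs_set()
  loose <- suppressWarnings(screen_design(
    d, obs, n = 2000, seed = 8,
    criteria = validity_criteria(mse_threshold = 0.05, qual_margin = 0.05)
  ))
  tight <- suppressWarnings(screen_design(
    d, obs, n = 2000, seed = 8,
    criteria = validity_criteria(mse_threshold = 0.002, qual_margin = 0.10)
  ))
  expect_lte(tight$Q, loose$Q)
  expect_lte(tight$Q_prime, loose$Q_prime)
})

test_that("a planted ground-truth instantiation is recovered as valid", {
  d <- new_design(config_by_label("S", default_configs))
  synth <- generate_synthetic_scenario(d, seed = 100, noise_sd = 0)
  iseed <- attr(synth, "instantiation_seed")
  # the screen's first draw at that seed is the generating instantiation
  r <- screen_design(d, synth, n = 1, seed = iseed)
  expect_equal(r$Q, 1L)
  expect_equal(unname(r$predictions[1, ]),
               unname(attr(synth, "predictions")), tolerance = 1e-12)
})

test_that("impossible qualitative margins empty the screen matrix", {
  cfg <- default_configs[default_configs$label %in% c("A", "S"), ]
  designs <- enumerate_designs(cfg, enumerate_crosstalk_patterns("none"))
  res <- screen_all(designs, obs_set(), n = 50, seed = 2,
                    criteria = validity_criteria(qual_margin = 1e6))
  expect_true(all(res$Q == 0))
  expect_false(any(res$filled))
  expect_false(any(res$row_flagged))
})

test_that("screen_all assembles the pattern-by-topology matrices", {
  cfg <- default_configs[default_configs$label %in% c("A", "O", "S"), ]
  pats <- list(character(0), "M3")
  designs <- enumerate_designs(cfg, pats)
  obs <- obs_set()
  res <- screen_all(designs, obs, n = 100, seed = 5)
  expect_equal(dim(res$Q), c(2L, 3L))
  expect_equal(rownames(res$Q), c("none", "M3"))
  expect_equal(colnames(res$Q), c("A", "O", "S"))
  expect_length(res$results, 6L)
  expect_identical(res$filled, res$Q > 0)
  # determinism across runs
  res2 <- screen_all(designs, obs, n = 100, seed = 5)
  expect_identical(res$Q, res2$Q)
  expect_identical(res$nw, res2$nw)
})

test_that("metabolite summaries are medians and IQRs of relative levels", {
  recs <- data.frame(instantiation = 1:3,
                     `y.ccr2_ko.X2` = log(c(2, 4, 8)),
                     `y.ccr1_ko.X2` = c(0, 0, 0),
                     check.names = FALSE)
  s <- summarize_metabolite(recs, "X2", "ccr2_ko")
  expect_equal(s$median, 4)
  expect_equal(s$n, 3L)
  s0 <- summarize_metabolite(recs, "X2", "ccr1_ko")
  expect_equal(s0$median, 1)
  expect_equal(s0$iqr, 0)
  expect_error(summarize_metabolite(recs[0, ], "X2", "ccr2_ko"), "no valid")
  expect_error(summarize_metabolite(recs, "X9", "ccr2_ko"), "no record")
})

test_that("valid records carry predictions and pool deviations", {
  d <- new_design(config_by_label("S", default_configs))
  synth <- generate_synthetic_scenario(d, seed = 31, noise_sd = 0)
  r <- screen_design(d, synth, n = 300, seed = attr(synth,
                                                    "instantiation_seed"))
  expect_gte(r$Q, 1L)
  expect_equal(nrow(r$valid_records), r$Q)
  expect_true(all(c("sg.ccr2_ko", "y.ccr2_ko.X2") %in%
                    names(r$valid_records)))
  # caffeyl aldehyde responds to the ccr2 knockout in every valid record
  expect_true(all(is.finite(r$valid_records$`y.ccr2_ko.X2`)))
})
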