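test_that("expected slopes hit their exact limits", {
  # no measurement error, no baseline genetics: beta_r exactly
  expect_equal(expected_slope(model_params(0, -0.07, sigma_measure = 0),
                              "logdiff_adj"), -0.07, tolerance = 1e-12)
  # no measurement error with baseline genetics: the two-stage procedure
  # attenuates by sb^2 / Var(lnX) but creates nothing spurious
  p0 <- model_params(beta_baseline = 0.3, beta_response = -0.07,
                     sigma_measure = 0)
  v <- 2 * 0.3 * 0.7
  atten <- 0.25^2 / (0.3^2 * v + 0.25^2)
  expect_equal(expected_slope(p0, "logdiff_adj"), -0.07 * atten,
               tolerance = 1e-12)
  expect_equal(expected_slope(model_params(0.3, 0, sigma_measure = 0),
                              "logdiff_adj"), 0, tolerance = 1e-12)
  # no baseline genetics: no bias pathway, adjusted == unadjusted == beta_r
  p1 <- model_params(beta_baseline = 0, beta_response = -0.07)
  expect_equal(expected_slope(p1, "logdiff_adj"), -0.07, tolerance = 1e-12)
  expect_equal(expected_slope(p1, "logdiff_unadj"), -0.07)
  # level phenotypes
  p2 <- model_params(beta_baseline = 0.1, beta_response = -0.05)
  expect_equal(expected_slope(p2, "baseline_level"), 0.1)
  expect_equal(expected_slope(p2, "ontreat_level"), 0.05)
  # the unadjusted change score is always beta_r, across a parameter grid
  for (bb in c(-0.2, 0, 0.15)) for (sm in c(0, 0.1, 0.3))
    expect_equal(expected_slope(model_params(bb, 0.04, sigma_measure = sm),
                                "logdiff_unadj"), 0.04)
  # no closed form is claimed for rank-normalized percent definitions
  expect_error(expected_slope(p2, "pct_adj"), "no closed form")
})

test_that("adjusted-slope bias is odd in beta_b and vanishes continuously with sigma_m", {
  bias <- function(bb, sm) {
    p <- model_params(beta_baseline = bb, beta_response = 0,
                      sigma_measure = sm)
    expected_slope(p, "logdiff_adj")
  }
  for (sm in c(0.05, 0.18, 0.3)) {
    expect_equal(bias(0.1, sm), -bias(-0.1, sm), tolerance = 1e-12)
  }
  # monotone decay to zero along a sigma_m grid
  grid <- abs(vapply(c(0.3, 0.2, 0.1, 0.05, 0.01, 0),
                     function(sm) bias(0.1, sm), numeric(1)))
  expect_true(all(diff(grid) < 0))
  expect_equal(grid[length(grid)], 0)
  # the bias term carries the sign of beta_b (spurious apparent response
  # tracking the baseline effect)
  expect_gt(bias(0.1, 0.18), 0)
  expect_lt(bias(-0.1, 0.18), 0)
})

test_that("closed-form adjusted slope matches the Monte-Carlo oracle", {
  p <- model_params(beta_baseline = 0.10, beta_response = 0, maf = 0.3,
                    sigma_biology = 0.25, sigma_measure = 0.18)
  th <- expected_slope(p, "logdiff_adj")
  set.seed(331)
  n <- 200000
  s <- sim_single(n, bb = 0.10, br = 0)
  D <- s$lnY - s$lnX
  res <- residualize(D, data.frame(lnX = s$lnX))
  emp <- cov(res, s$g) / var(s$g)
  expect_lt(abs(emp - th) / abs(th), 0.05)
  expect_gt(emp, 0)

  # on-treatment-adjusted-for-baseline carries the same bias term
  th_on <- expected_slope(p, "ontreat_adj_baseline")
  res_on <- residualize(s$lnY, data.frame(lnX = s$lnX))
  emp_on <- cov(res_on, s$g) / var(s$g)
  expect_lt(abs(emp_on - th_on) / abs(th_on), 0.05)
  expect_equal(th_on, th, tolerance = 1e-12)  # beta_r = 0: identical terms
})

test_that("expected rejection rate is exact at the null and monotone in n", {
  p0 <- model_params(beta_baseline = 0, beta_response = 0)  # true null
  expect_equal(expected_slope(p0, "logdiff_adj"), 0)
  expect_equal(expected_rejection_rate(p0, "logdiff_adj", n = 500,
                                       alpha = 0.05), 0.05, tolerance = 1e-10)
  expect_equal(expected_rejection_rate(p0, "logdiff_unadj", n = 500,
                                       alpha = 0.17), 0.17, tolerance = 1e-10)
  # a constant phenotype (no noise at all) cannot be scanned
  expect_error(expected_rejection_rate(
    model_params(0.2, 0, sigma_measure = 0), "logdiff_adj", n = 500),
    "zero residual variance")
  p <- model_params(beta_baseline = 0.1, beta_response = 0)
  rates <- vapply(c(200, 1000, 5000, 20000), function(n)
    expected_rejection_rate(p, "logdiff_adj", n = n), numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_error(expected_rejection_rate(p, "logdiff_adj", 1000, alpha = 1.5),
               "alpha")
  expect_error(expected_rejection_rate(p, "logdiff_adj", n = 5), "n must")
})

test_that("predicted rejection rate matches replicate simulation", {
  # baseline-only variant, adjusted scan, moderate n: theory vs 200 reps
  p <- model_params(beta_baseline = 0.10, beta_response = 0)
  n <- 1000
  pred <- expected_rejection_rate(p, "logdiff_adj", n = n, alpha = 0.05)
  set.seed(337)
  B <- 200
  rej <- vapply(seq_len(B), function(i) {
    s <- sim_single(n, bb = 0.10, br = 0)
    res <- residualize(s$lnY - s$lnX, data.frame(lnX = s$lnX))
    panel <- panel_from_matrix(matrix(s$g, ncol = 1))
    assoc_scan(phen_from_values(res, panel), panel)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - pred), 3 * sqrt(pred * (1 - pred) / B))
})

test_that("rank-INT percent scans agree in sign and rejection with log scans", {
  set.seed(347)
  n <- 20000
  s <- sim_single(n, bb = 0.10, br = -0.05)
  panel <- panel_from_matrix(matrix(s$g, ncol = 1))
  pairs <- data.frame(id = rownames(panel$dosages), baseline = exp(s$lnX),
                      ontreat = exp(s$lnY))
  out <- lapply(c("logdiff_adj", "pct_adj", "logdiff_unadj", "pct_unadj"),
                function(d) assoc_scan(build_response(pairs,
                  spec = phenotype_spec(d)), panel))
  names(out) <- c("logdiff_adj", "pct_adj", "logdiff_unadj", "pct_unadj")
  expect_equal(sign(out$pct_adj$beta), sign(out$logdiff_adj$beta))
  expect_equal(sign(out$pct_unadj$beta), sign(out$logdiff_unadj$beta))
  expect_equal(out$pct_adj$p < 5e-8, out$logdiff_adj$p < 5e-8)
  expect_equal(out$pct_unadj$p < 5e-8, out$logdiff_unadj$p < 5e-8)
})

test_that("bias_table tabulates the grid consistently with expected_slope", {
  tb <- bias_table(beta_baseline = c(-0.1, 0.1), sigma_measure = c(0, 0.18))
  expect_equal(nrow(tb), 4)
  expect_equal(tb$bias_adj[tb$sigma_measure == 0], c(0, 0))
  row <- tb[tb$beta_baseline == 0.1 & tb$sigma_measure == 0.18, ]
  expect_equal(row$slope_adj,
               expected_slope(model_params(0.1, 0, sigma_measure = 0.18),
                              "logdiff_adj"))
})
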