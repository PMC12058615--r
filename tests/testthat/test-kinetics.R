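test_that("noiseless pseudo-first-order curves are recovered exactly", {
  cs <- synth_coverage_curve(0.9, 0.01, noise_sigma = 0, n_points = 600)
  fit <- fit_pseudo_first_order(cs)
  expect_equal(fit$theta_inf, 0.9, tolerance = 1e-6)
  expect_equal(fit$k, 0.01, tolerance = 1e-4)  # relative 1e-6 on k
  expect_lt(fit$rss, 1e-12)
  tml <- time_to_monolayer(cs, fit)
  expect_equal(tml$t_ml_analytic, -log(0.05) / 0.01, tolerance = 1e-4)
  expect_true(tml$reached)
})

test_that("degenerate series are rejected", {
  expect_error(fit_pseudo_first_order(
    as_coverage_series(0:99, rep(0.5, 100))), "unidentifiable")
  expect_error(fit_pseudo_first_order(
    as_coverage_series(0:5, seq(0, 0.5, length.out = 6))), "at least 10")
})

test_that("noisy recovery has small median relative error", {
  errs <- vapply(1:50, function(s) {
    cs <- synth_coverage_curve(0.9, 0.01, noise_sigma = 0.02,
                               n_points = 600, seed = s)
    fit <- fit_pseudo_first_order(cs)
    c(abs(fit$k - 0.01) / 0.01, abs(fit$theta_inf - 0.9) / 0.9)
  }, numeric(2))
  expect_lte(median(errs[1, ]), 0.05)
  expect_lte(median(errs[2, ]), 0.05)
})

test_that("rate bias vanishes as noise goes to zero", {
  bias <- vapply(c(0.04, 0.01, 0.002), function(sg) {
    ks <- vapply(1:12, function(s)
      fit_pseudo_first_order(synth_coverage_curve(
        0.85, 0.008, noise_sigma = sg, n_points = 400,
        seed = 300 + s))$k, numeric(1))
    abs(mean(ks) - 0.008) / 0.008
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 1e-9)
  expect_lt(bias[3], 0.01)
})

test_that("fit residuals are invariant under time re-origin", {
  cs <- synth_coverage_curve(0.8, 0.02, noise_sigma = 0.02, n_points = 200,
                             seed = 9)
  f1 <- fit_pseudo_first_order(cs)
  shifted <- as_coverage_series(cs$t + 500, cs$theta)
  f2 <- fit_pseudo_first_order(shifted)
  expect_equal(f2$rss, f1$rss, tolerance = 1e-6)
  expect_equal(f2$k, f1$k, tolerance = 1e-6)
})

test_that("time to monolayer flags series truncated before saturation", {
  cs <- synth_coverage_curve(0.9, 0.001, noise_sigma = 0, n_points = 300)
  fit <- fit_pseudo_first_order(cs)
  tml <- time_to_monolayer(cs, fit, fraction = 0.95)
  expect_false(tml$reached)
  expect_true(is.na(tml$t_ml))
  expect_gt(tml$t_ml_analytic, max(cs$t))
})

test_that("F-test separates different rates and accepts identical curves", {
  same <- synth_coverage_curve(0.9, 0.01, 0, 600)
  r0 <- compare_datasets_ftest(list(same, same))
  expect_equal(r0$omnibus$F, 0)
  expect_equal(r0$omnibus$p, 1)
  expect_error(compare_datasets_ftest(list(same)), "at least 2")

  reps <- vapply(1:20, function(s) {
    a <- synth_coverage_curve(0.9, 0.005, 0.01, 600, seed = 2 * s)
    b <- synth_coverage_curve(0.9, 0.02, 0.01, 600, seed = 2 * s + 1)
    compare_datasets_ftest(list(a, b))$omnibus$p
  }, numeric(1))
  expect_gte(mean(reps < 0.001), 0.95)
})

test_that("F-test type-I error stays near nominal under the null", {
  reps <- vapply(1:100, function(s) {
    a <- synth_coverage_curve(0.9, 0.01, 0.02, 150, seed = 5000 + 2 * s)
    b <- synth_coverage_curve(0.9, 0.01, 0.02, 150, seed = 5001 + 2 * s)
    compare_datasets_ftest(list(a, b))$omnibus$p
  }, numeric(1))
  expect_lte(mean(reps < 0.05), 0.10)
})

test_that("three-series comparison reports Holm-adjusted pairs", {
  sl <- lapply(1:3, function(s)
    synth_coverage_curve(0.9, 0.01 * s, 0.01, 300, seed = 70 + s))
  r <- compare_datasets_ftest(sl)
  expect_equal(nrow(r$pairwise), 3)
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p))
})

test_that("one-way ANOVA behaves on power and degenerate cases", {
  # identical constants: F = 0, p = 1 by stated convention
  r <- final_order_anova(list(a = c(80, 80), b = c(80, 80)))
  expect_equal(r$F, 0); expect_equal(r$p, 1)
  expect_error(final_order_anova(list(a = 1:5)), "2 groups")
  expect_error(final_order_anova(list(a = 1:5, b = 3)), ">= 2 values")

  # two-group ANOVA equals the squared two-sample t test
  g1 <- with_seed(3, rnorm(5, 80, 3)); g2 <- with_seed(4, rnorm(5, 95, 3))
  r2 <- final_order_anova(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-9)

  # power at the separation used for the final-order comparison
  hits <- vapply(1:50, function(s) {
    g1 <- with_seed(1000 + s, rnorm(5, 80, 3))
    g2 <- with_seed(2000 + s, rnorm(5, 95, 3))
    final_order_anova(list(a = g1, b = g2))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("final-order sampler takes five spread values from the last 50 s", {
  t <- seq(0, 600, by = 2)
  v <- seq_along(t)
  sel <- select_final_orders(t, v, window_s = 50, n_values = 5)
  expect_length(sel, 5)
  expect_true(all(t[match(sel, v)] >= 550))
})
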