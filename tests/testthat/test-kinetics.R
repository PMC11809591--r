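# Logistic / exponential labeling-curve fits, group statistics and
# cross-instrument regression.

times6 <- c(0, 5, 10, 15, 30, 60)

test_that("noise-free logistic curves are recovered to machine precision", {
  v <- gen_logistic(times6, i_max = 1, a = 0.8, t_mid = 6)
  f <- fit_logistic(times6, v, n_starts = 1000, seed = 1)
  expect_equal(f$i_max, 1, tolerance = 1e-6)
  expect_equal(f$a, 0.8, tolerance = 1e-6)
  expect_equal(f$t_mid, 6, tolerance = 1e-6)
  expect_equal(f$a13c, 0.2, tolerance = 1e-6)
  expect_equal(f$fit_class, "sigmoidal")
})

test_that("the closed-form maximum slope equals the numerical maximum", {
  set.seed(7)
  for (i in 1:10) {
    im <- runif(1, 0.5, 3); a <- runif(1, 0.2, 1.5); tm <- runif(1, 3, 12)
    tt <- seq(0, 60, 1e-3)
    num <- max(diff(gen_logistic(tt, im, a, tm)) / 1e-3)
    expect_equal(im * a / 4, num, tolerance = 1e-6)
  }
})

test_that("replicate fits at 10% noise recover midpoint and rate", {
  set.seed(55)
  tm <- c(); am <- c()
  for (r in 1:3) {
    v <- gen_logistic(times6, 1.3, 1.0, 5.4) * rlnorm(6, 0, 0.1)
    f <- fit_logistic(times6, v, n_starts = 500, seed = 100 + r)
    tm <- c(tm, f$t_mid); am <- c(am, f$a13c)
  }
  expect_lt(abs(mean(tm) - 5.4), 1)
  expect_lt(abs(mean(am) - 1.3 * 0.25) / (1.3 * 0.25), 0.15)
})

test_that("series without a plateau are classified ambiguous", {
  v <- times6 / 60  # monotone ramp, no saturation inside the window
  f <- fit_logistic(times6, v, n_starts = 500, seed = 2)
  expect_equal(f$fit_class, "ambiguous")
})

test_that("zero series are classified no_signal", {
  f <- fit_logistic(times6, rep(0, 6))
  expect_equal(f$fit_class, "no_signal")
  expect_true(is.na(f$a13c))
  fe <- fit_exponential(times6, rep(0, 6))
  expect_equal(fe$fit_class, "no_signal")
})

test_that("labeling-fit methods behave like standard model objects", {
  v <- gen_logistic(times6, 1, 0.8, 6)
  f <- fit_logistic(times6, v, n_starts = 300, seed = 3)
  expect_named(coef(f), c("i_max", "a", "t_mid"))
  expect_equal(predict(f), v, tolerance = 1e-6)
  expect_equal(unname(residuals(f)), rep(0, 6), tolerance = 1e-6)
  expect_output(print(f), "logistic")
  expect_silent(grDevices::pdf(NULL))
  plot(f)
  grDevices::dev.off()
})

test_that("noise-free exponential recovery and lag-phase discrepancy", {
  v <- 1 * (1 - exp(-0.2 * times6))
  fe <- fit_exponential(times6, v, seed = 4)
  expect_equal(fe$i_max, 1, tolerance = 1e-6)
  expect_equal(fe$k, 0.2, tolerance = 1e-6)
  expect_equal(fe$initial_slope, 0.2, tolerance = 1e-6)
  # a lagged sigmoid is not well modeled by the exponential: its initial
  # slope disagrees with the logistic maximum slope by more than 25%
  vl <- gen_logistic(times6, 1, 0.8, 8)
  fl <- fit_logistic(times6, vl, n_starts = 500, seed = 5)
  fe2 <- fit_exponential(times6, vl, seed = 6)
  expect_gt(abs(fe2$initial_slope - fl$a13c) / fl$a13c, 0.25)
})

test_that("group comparison is the heteroscedastic Welch t-test", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")
  sep <- compare_groups(c(0, 0.01, -0.01), c(1, 1.01, 0.99))
  expect_lt(sep$p_value, 0.001)
  expect_equal(sep$stars, "***")
  # hand-computed Welch example
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  res <- compare_groups(x, y)
  se2 <- var(x) / 4 + var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand),
               tolerance = 1e-12)
  expect_error(compare_groups(1, c(1, 2)), ">= 2")
})

test_that("Welch p agrees with a permutation test within Monte-Carlo error", {
  set.seed(61)
  x <- rnorm(6, 0, 1); y <- rnorm(6, 1.0, 1.5)
  p_w <- compare_groups(x, y)$p_value
  p_perm <- oracle_perm_p(x, y, n_perm = 4000, seed = 62)
  expect_lt(abs(p_w - p_perm), 0.08)
})

test_that("cross-instrument regression detects systematic bias", {
  x <- seq(0, 1, length.out = 20)
  r <- correlate_instruments(x, x)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  r2 <- correlate_instruments(x, 2 * x + 0.1)
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$intercept, 0.1, tolerance = 1e-12)
  expect_true(r2$biased)
  expect_true(is.na(correlate_instruments(rep(1, 12), rep(2, 12))$slope))
  expect_error(correlate_instruments(1:5, 1:5), "10 pairs")
})
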