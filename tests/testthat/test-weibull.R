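test_that("model evaluation: lag, plateau, single-Weibull reduction", {
  p <- wb_truth_min()
  expect_identical(eval_double_weibull(p, p$Tlag), 0)
  expect_identical(eval_double_weibull(p, -5), 0)
  expect_equal(eval_double_weibull(p, p$Tlag + 50 * max(p$MDT1, p$MDT2)),
               p$F_inf, tolerance = 1e-9)
  s <- double_weibull(0.8, 1, MDT1 = 20, b1 = 1.4, time_unit = "min")
  t <- seq(0, 120, by = 2.5)
  expect_equal(eval_double_weibull(s, t),
               0.8 * (1 - exp(-(t / 20)^1.4)))
})

test_that("evaluation is monotone non-decreasing over random parameters", {
  set.seed(77)
  t <- seq(0, 300, by = 1)
  for (i in 1:40) {
    p <- double_weibull(runif(1, 0.1, 1.05), runif(1), exp(runif(1, 0, 4)),
                        runif(1, 0.2, 5), exp(runif(1, 0, 4)),
                        runif(1, 0.2, 5), runif(1, 0, 20))
    expect_true(all(diff(eval_double_weibull(p, t)) >= -1e-12))
  }
})

test_that("time-unit conversion rescales only scale and lag", {
  p <- wb_truth_min()
  ph <- weibull_convert_time(p, "h")
  expect_equal(ph$MDT1, p$MDT1 / 60)
  expect_equal(ph$Tlag, p$Tlag / 60)
  expect_equal(ph$b1, p$b1)
  t_min <- c(5, 30, 90)
  expect_equal(eval_double_weibull(ph, t_min / 60),
               eval_double_weibull(p, t_min))
})

test_that("noise-free double-Weibull data are recovered within 1%", {
  p <- wb_truth_min()
  t <- seq(0, 180, length.out = 60)
  fit <- fit_dissolution(timeseries(t, eval_double_weibull(p, t), "min"),
                         "weibull2", seed = 2)
  fields <- c("F_inf", "f1", "MDT1", "b1", "MDT2", "b2", "Tlag")
  truth <- unlist(p[fields])
  est <- unlist(fit$params[fields])
  expect_true(all(rel_err(est, truth) < 0.01))
  expect_lt(fit$rss, 1e-8)
})

test_that("final RSS is at least as good as every multistart local fit", {
  p <- wb_truth_min()
  t <- seq(0, 180, length.out = 50)
  set.seed(3)
  y <- pmin(pmax(eval_double_weibull(p, t) * rlnorm(50, 0, 0.03), 0), 1.05)
  fit <- fit_dissolution(timeseries(t, y, "min"), "weibull2", seed = 3)
  expect_lte(fit$rss, min(fit$start_rss, na.rm = TRUE) + 1e-12)
  expect_identical(fit$k_params, 7L)
  expect_identical(fit$n_obs, 50L)
  expect_equal(fit$aic, 50 * log(fit$rss / 50) + 14)
})

test_that("AIC prefers the single Weibull when it is the truth", {
  # scaled down from the spec-scale replicate count to stay in budget:
  # 25 seeded noisy replicates, parsimony must win in at least 95%
  s <- double_weibull(0.9, 1, MDT1 = 25, b1 = 1.2, time_unit = "min")
  t <- seq(0, 180, length.out = 40)
  mu <- eval_double_weibull(s, t)
  set.seed(12)
  wins <- vapply(1:25, function(i) {
    y <- pmin(pmax(mu * rlnorm(length(t), 0, 0.02), 0), 1.05)
    ts <- timeseries(t, y, "min")
    f1 <- fit_dissolution(ts, "weibull1", n_starts = 6, seed = i)
    f2 <- fit_dissolution(ts, "weibull2", n_starts = 6, seed = i)
    f1$aic < f2$aic
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("degenerate series and bad fractions are rejected", {
  t <- seq(0, 100, by = 5)
  expect_error(fit_dissolution(timeseries(t, rep(0, length(t)), "min")),
               "identically zero")
  expect_error(fit_dissolution(timeseries(t, rep(2, length(t)), "min")),
               "\\[0, 1.05\\]")
  expect_error(fit_dissolution(timeseries(c(0, 10), c(0, 0.5), "min")),
               "at least")
})

test_that("the per-process-lag variant reproduces a staggered truth", {
  p <- double_weibull(0.9, 0.5, 8, 1.5, 40, 2, Tlag = 2, Tlag2 = 25,
                      time_unit = "min")
  t <- seq(0, 240, length.out = 80)
  fit <- fit_dissolution(timeseries(t, eval_double_weibull(p, t), "min"),
                         "weibull2", per_process_lag = TRUE, seed = 4)
  expect_lt(fit$rss, 1e-6)
})
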