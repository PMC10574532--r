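pk0 <- pk_disposition()
uir0 <- uir_params(pk0$A, pk0$lambda)

test_that("noise-free biexponential i.v. data are recovered within 1%", {
  iv <- simulate_plasma(pk = pk0, route = "iv", t_out = tv_design)
  fit <- fit_uir(iv, dose_iv = pk0$dose_iv_mg_kg * pk0$weight_kg)
  expect_identical(attr(fit, "n_terms"), 2L)
  expect_true(all(rel_err(sort(fit$A), sort(pk0$A)) < 0.01))
  expect_true(all(rel_err(sort(fit$lambda), sort(pk0$lambda)) < 0.01))
})

test_that("order selection is parsimonious for mono-exponential truth", {
  # scaled down from the spec-scale replicate count to stay in budget:
  # 20 noisy replicates, >= 95% must select a single term
  t <- tv_design
  mono <- uir_params(50000, 0.8)
  set.seed(33)
  hits <- vapply(1:20, function(i) {
    y <- eval_uir(mono, t) * rlnorm(length(t), 0, 0.03)
    iv <- timeseries(t, y, "h", "ng/mL")
    fit <- fit_uir(iv, dose_iv = 1, n_starts = 4, seed = i)
    attr(fit, "n_terms") == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fitted rate constants are positive by construction", {
  set.seed(8)
  for (i in 1:5) {
    y <- eval_uir(uir0, tv_design) * rlnorm(length(tv_design), 0, 0.1)
    fit <- fit_uir(timeseries(tv_design, y, "h"), dose_iv = 0.5,
                   n_starts = 3, seed = i)
    expect_true(all(fit$lambda > 0))
    expect_error(uir_params(1, -0.5), "lambda > 0")
  }
})

test_that("deconvolution recovers a known staircase input exactly", {
  edges <- c(0, tv_design)
  rates <- c(4, 3, 2.5, 1.5, 0.5, 0.1, 0, 0, 0)     # mg/h
  conc <- numeric(length(tv_design))
  for (j in seq_along(rates)) {
    conc <- conc + rates[j] *
      dgim:::conv_interval_unit_rate(uir0, edges[j], edges[j + 1], tv_design)
  }
  oral <- timeseries(tv_design, conc, "h", "ng/mL")
  fabs <- deconvolve(oral, uir0, dose_oral = sum(rates * diff(edges)))
  expect_equal(attr(fabs, "rate"), rates, tolerance = 1e-6)
  expect_equal(ts_values(fabs)[1], 0)
  expect_true(all(diff(ts_values(fabs)) >= 0))
  expect_equal(ts_values(fabs)[length(edges)], 1, tolerance = 1e-9)
})

test_that("a zero oral curve deconvolves to zero absorption", {
  oral <- timeseries(tv_design, numeric(length(tv_design)), "h")
  fabs <- deconvolve(oral, uir0, dose_oral = 2)
  expect_true(all(ts_values(fabs) == 0))
})

test_that("deconvolve/convolve round trip reproduces the plasma curve", {
  fabs_true <- timeseries(c(0, 0.25, 0.5, 1, 2, 4),
                          c(0, 0.3, 0.55, 0.8, 0.93, 0.97), "h")
  oral <- simulate_plasma(fabs_true, pk_disposition(F_true = 0.9), "oral",
                          t_out = tv_design)
  dose <- 2
  fabs <- deconvolve(oral, uir0, dose_oral = dose)
  back <- convolve_predict_plasma(fabs, uir0, dose_oral = dose, F_ref = 1,
                                  t_out = tv_design)
  rmse <- sqrt(mean((ts_values(back) - ts_values(oral))^2))
  expect_lt(rmse, 0.01 * max(ts_values(oral)))
})

test_that("correlation fitting recovers its generating parameters", {
  w <- double_weibull(0.95, 0.6, 0.3, 1.2, 1.5, 1.8, Tlag = 0.05,
                      time_unit = "h")
  truth <- ivivc_params(0.9757, 1.629, 4.397e-5)
  fa <- predict_fabs(truth, w, tv_design)
  fit <- fit_correlation(list(fa), list(w))
  expect_lt(rel_err(fit$AbsScale, truth$AbsScale), 0.01)
  expect_lt(rel_err(fit$Tscale, truth$Tscale), 0.01)
  expect_lt(abs(fit$Tshift - truth$Tshift), 1e-3)

  # identity mapping: Fabs == Diss on the same grid
  fa_id <- timeseries(tv_design, eval_double_weibull(w, tv_design), "h")
  fit_id <- fit_correlation(list(fa_id), list(w))
  expect_equal(fit_id$AbsScale, 1, tolerance = 1e-6)
  expect_equal(fit_id$Tscale, 1, tolerance = 1e-6)
  expect_lt(abs(fit_id$Tshift), 1e-6)
})

test_that("pooling two training groups beats a single-group fit", {
  # scaled down replicate count (30 seeds) for budget
  w1 <- double_weibull(0.9, 0.5, 0.4, 1.3, 2.0, 1.6, time_unit = "h")
  w2 <- double_weibull(0.95, 0.7, 0.25, 1.1, 1.2, 2.2, time_unit = "h")
  truth <- ivivc_params(0.95, 1.5, 0)
  f1 <- predict_fabs(truth, w1, tv_design)
  f2 <- predict_fabs(truth, w2, tv_design)
  set.seed(55)
  errs <- vapply(1:30, function(i) {
    n1 <- add_noise(f1, 0.05)
    n2 <- add_noise(f2, 0.05)
    pooled <- fit_correlation(list(n1, n2), list(w1, w2), n_starts = 4,
                              seed = i)
    single <- fit_correlation(list(n1), list(w1), n_starts = 4, seed = i)
    c(pooled$Tscale - 1.5, single$Tscale - 1.5)
  }, numeric(2))
  rmse_pooled <- sqrt(mean(errs[1, ]^2))
  rmse_single <- sqrt(mean(errs[2, ]^2))
  expect_lt(rmse_pooled, rmse_single)
})

test_that("forward prediction is the plain time-scaled evaluation", {
  w <- double_weibull(0.9, 0.5, 0.4, 1.3, 2.0, 1.6, Tlag = 0.1,
                      time_unit = "h")
  id <- predict_fabs(ivivc_params(1, 1, 0), w, tv_design)
  expect_equal(ts_values(id), eval_double_weibull(w, tv_design))
  lagged <- predict_fabs(ivivc_params(1, 1, 5), w, c(0.5, 1, 2))
  expect_true(all(ts_values(lagged) == 0))        # Tshift > Tscale * t
  p3 <- ivivc_params(0.9757, 1.629, 4.397e-5)
  direct <- 0.9757 * eval_double_weibull(w, pmax(1.629 * tv_design - 4.397e-5, 0))
  expect_equal(ts_values(predict_fabs(p3, w, tv_design)), direct,
               tolerance = 1e-12)
  expect_error(predict_fabs(p3, wb_truth_min(), 1:3), "hours")
})

test_that("convolution prediction: delta input and grid invariance", {
  step <- timeseries(c(0, 10), c(1, 1), "h")
  pl <- convolve_predict_plasma(step, uir0, dose_oral = 2, F_ref = 1,
                                t_out = tv_design)
  expect_equal(ts_values(pl), 2 * eval_uir(uir0, tv_design),
               tolerance = 1e-12)

  w <- double_weibull(0.95, 0.6, 0.3, 1.2, 1.5, 1.8, time_unit = "h")
  coarse_grid <- seq(0, 10, by = 0.5)
  fine_grid <- seq(0, 10, by = 0.05)
  # the same piecewise-linear curve on nested grids
  coarse <- timeseries(coarse_grid, eval_double_weibull(w, coarse_grid), "h")
  fine <- ts_interp(timeseries(coarse_grid,
                               eval_double_weibull(w, coarse_grid), "h"),
                    fine_grid)
  p1 <- convolve_predict_plasma(coarse, uir0, 2, t_out = tv_design)
  p2 <- convolve_predict_plasma(fine, uir0, 2, t_out = tv_design)
  expect_equal(ts_values(p1), ts_values(p2), tolerance = 1e-6)
  dec <- timeseries(c(0, 1, 2), c(0, 0.5, 0.4), "h")
  expect_error(convolve_predict_plasma(dec, uir0, 2), "non-decreasing")
})

test_that("prediction errors match the reference exposure table", {
  expect_equal(prediction_error(41300, 45529), 10.24, tolerance = 0.005 / 10.24)
  expect_equal(prediction_error(112853, 108727), -3.66,
               tolerance = 0.005 / 3.66)
  expect_equal(prediction_error(100, 100), 0)
  expect_equal(prediction_error(100, 110, convention = "obs_minus_pred"), -10)
  expect_error(prediction_error(0, 10), "positive")

  ref <- ktz_pe_reference()
  pe <- prediction_error(ref$observed, ref$predicted)
  expect_true(all(abs(pe - ref$pe_printed) <= 0.02))
  for (app in unique(ref$apparatus)) {
    for (metric in unique(ref$metric)) {
      sel <- ref$apparatus == app & ref$metric == metric
      expect_equal(mean_absolute_pe(pe[sel]), ref$mean_printed[sel][1],
                   tolerance = 0.01)
    }
  }
})

test_that("mean absolute PE", {
  expect_equal(mean_absolute_pe(c(10.24, 12.83, 6.80)), 9.96,
               tolerance = 0.01 / 9.96)
  expect_equal(mean_absolute_pe(c(3.66, 2.45, 6.65)), 4.25,
               tolerance = 0.01 / 4.25)
  expect_equal(mean_absolute_pe(-7), 7)
  expect_error(mean_absolute_pe(numeric(0)), "empty")
})

test_that("qualification verdicts follow the FDA-style limits", {
  ref <- ktz_pe_reference()
  mk_report <- function(app) {
    sub <- ref[ref$apparatus == app, ]
    obs <- data.frame(
      Cmax = sub$observed[sub$metric == "Cmax"],
      AUC = sub$observed[sub$metric == "AUC"])
    pred <- data.frame(
      Cmax = sub$predicted[sub$metric == "Cmax"],
      AUC = sub$predicted[sub$metric == "AUC"])
    pe_report(obs, pred, groups = sub$group[sub$metric == "Cmax"])
  }
  v_dgim <- validate_ivivc(mk_report("DGIM"))
  expect_true(all(v_dgim$pass))
  v_usp <- validate_ivivc(mk_report("USPII"))
  expect_false(v_usp$pass[v_usp$metric == "Cmax"])
  expect_equal(v_usp$mean_abs_pe[v_usp$metric == "Cmax"], 19.30,
               tolerance = 0.01)

  zero <- pe_report(data.frame(Cmax = c(1, 2), AUC = c(3, 4)),
                    data.frame(Cmax = c(1, 2), AUC = c(3, 4)),
                    groups = c("a", "b"))
  expect_true(all(validate_ivivc(zero)$pass))
})
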