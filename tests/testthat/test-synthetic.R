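cfg <- dgim_config()

test_that("drug mass is conserved in every transfer simulation", {
  set.seed(5)
  for (i in 1:4) {
    kin <- luminal_kinetics(kp = runif(1, 0, 0.3), ka_d = runif(1, 0, 0.03),
                            ka_j = runif(1, 0, 0.03),
                            pH_dip_gain = runif(1, 0, 1.5))
    run <- simulate_dgim(cfg, group_scenario("control"), kin,
                         grid = seq(0, 180, by = 5))
    mb <- ts_values(run$mass_balance)
    expect_lt(max(abs(mb - mb[1])) / mb[1], 1e-6)
  }
})

test_that("with no kinetics the duodenal curve is pure dilution", {
  # effectively infinite solubility: nothing precipitates
  sc <- group_scenario("control",
                       solubility_fit = ph_solubility_fit(1e7, 6.3))
  kin <- luminal_kinetics(kp = 0, ka_d = 0, ka_j = 0)
  grid <- c(2, 5, 10, 20, 40)
  run <- simulate_dgim(cfg, sc, kin, grid = grid)
  # independent fine-Euler oracle of the dilution-only mass balance
  deriv <- function(tt, y) {
    va <- pump_rate_a(tt, cfg); vb <- pump_rate_b(tt, cfg)
    Vg <- cfg$Vg0 * 2^(-min(tt, cfg$pump_stop) / cfg$th)
    c(-y[1] / Vg * va, y[1] / Vg * va - y[2] / cfg$Vd * vb)
  }
  for (k in seq_along(grid)) {
    y <- euler_path(deriv, c(5.2 * 300, 0), grid[k], dt = 5e-4)
    expect_equal(ts_values(run$duodenal_aq)[k], y[2] / cfg$Vd * 1000,
                 tolerance = 1e-4)
  }
})

test_that("default kinetics give the spring-and-parachute shape", {
  for (g in c("control", "PVPVA", "HPMC")) {
    run <- simulate_dgim(cfg, group_scenario(g), grid = seq(0, 180, by = 1))
    aq <- ts_values(run$duodenal_aq)
    t <- ts_times(run$duodenal_aq)
    peak <- which.max(aq)
    expect_lt(t[peak], 10)                       # early supersaturation peak
    expect_gt(peak, 1)
    expect_true(all(diff(aq[peak:length(aq)]) <= 1e-9))  # decays after peak
    # late aqueous level has relaxed to at most its solubility scale
    cs_late <- eval_solubility(run$scenario$solubility_fit,
                               ts_values(run$pH_d)[length(aq)])
    expect_lt(aq[length(aq)], 1.5 * cs_late)
    # octanol amounts only accumulate
    expect_true(all(diff(ts_values(run$duodenal_org)) >= 0))
    expect_true(all(diff(ts_values(run$jejunal_org)) >= 0))
  }
})

test_that("more drug ends in the jejunal than the duodenal octanol", {
  run <- simulate_dgim(cfg, group_scenario("control"),
                       grid = seq(0, 180, by = 5))
  d <- ts_values(run$duodenal_org)
  j <- ts_values(run$jejunal_org)
  expect_gt(j[length(j)] / d[length(d)], 1)
})

test_that("inhibitor groups keep higher peaks than control", {
  peaks <- vapply(c("control", "PVPVA", "HPMC"), function(g) {
    run <- simulate_dgim(cfg, group_scenario(g), grid = seq(0, 30, by = 1))
    max(ts_values(run$duodenal_aq))
  }, numeric(1))
  expect_gt(peaks[["PVPVA"]], peaks[["control"]])
  expect_gt(peaks[["HPMC"]], peaks[["control"]])
})

test_that("pH-shift test: exact 3-fold dilution and two-plateau limit", {
  kin0 <- luminal_kinetics(kp = 0, ka_d = 0, ka_j = 0)
  grid <- seq(0, 180, by = 1)
  run <- simulate_usp2_ph_shift(group_scenario("control"), kin0, grid)
  aq <- ts_values(run$aqueous); t <- ts_times(run$aqueous)
  expect_equal(aq[t == 19], 5200)
  expect_equal(aq[t == 20], 5200 / 3)              # 250 -> 750 mL
  expect_equal(aq[t == 19] / aq[t == 20], 3)
  expect_true(all(aq[t < 20] == aq[1]))
  expect_equal(max(abs(aq[t >= 20] - aq[t == 20])), 0)   # second plateau

  run2 <- simulate_usp2_ph_shift(group_scenario("control"), grid = grid)
  org <- ts_values(run2$organic)
  expect_true(all(org[t < 20] == 0))               # starts at the shift
  expect_true(all(diff(org) >= 0))
  expect_gt(org[length(org)], 0)
  mb <- ts_values(run2$mass_balance)
  expect_lt(max(abs(mb - mb[1])) / mb[1], 1e-6)
  expect_error(simulate_usp2_ph_shift(grid = seq(30, 60)), "shift_time")
})

test_that("plasma generator: delta input reproduces the scaled kernel", {
  pk <- pk_disposition(F_true = 1)
  step <- timeseries(c(0, 10), c(1, 1), time_unit = "h")
  oral <- simulate_plasma(step, pk, "oral", t_out = tv_design)
  dose <- pk$dose_oral_mg_kg * pk$weight_kg
  kern <- dose * eval_uir(uir_params(pk$A, pk$lambda), tv_design)
  expect_equal(ts_values(oral), kern, tolerance = 1e-12)
})

test_that("dose-normalized AUC ratio recovers F_true within 1%", {
  pk <- pk_disposition(F_true = 0.70)
  t_long <- seq(0, 48, by = 0.05)      # >= 7 half-lives of the slow phase
  fabs <- timeseries(c(0, 0.25, 0.5, 1, 2), c(0, 0.4, 0.7, 0.95, 1), "h")
  oral <- simulate_plasma(fabs, pk, "oral", t_out = t_long)
  iv <- simulate_plasma(pk = pk, route = "iv", t_out = t_long)
  f <- absolute_bioavailability(
    auc_linear_trapezoid(oral), pk$dose_oral_mg_kg,
    auc_linear_trapezoid(iv), pk$dose_iv_mg_kg)
  expect_equal(f, 70, tolerance = 0.01)
})

test_that("non-monotone or out-of-range input fractions are rejected", {
  pk <- pk_disposition()
  expect_error(simulate_plasma(timeseries(c(0, 1, 2), c(0, 0.5, 0.4), "h"),
                               pk, "oral"), "non-decreasing")
  expect_error(simulate_plasma(timeseries(c(0, 1), c(0, 1.2), "h"),
                               pk, "oral"), "\\[0, 1\\]")
})

test_that("noisy replicates average back to the clean curve", {
  pk <- pk_disposition()
  fabs <- timeseries(c(0, 0.5, 1, 2), c(0, 0.5, 0.8, 0.9), "h")
  clean <- simulate_plasma(fabs, pk, "oral", t_out = tv_design)
  set.seed(99)
  sims <- replicate(500, ts_values(add_noise(clean, 0.05)))
  mc_mean <- rowMeans(sims)
  tol <- 3 * 0.05 * ts_values(clean) / sqrt(500)
  expect_true(all(abs(mc_mean - ts_values(clean)) <= tol))
})
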