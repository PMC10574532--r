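#' Run the complete in vitro - in vivo correlation pipeline
#'
#' Orchestrates the full analysis on synthetic data with known ground
#' truth: (1) fit the pH-solubility model to synthetic solubility points;
#' (2) simulate the three-cup transfer run per group and derive the in
#' vitro absorbed fraction from the combined duodenal + jejunal octanol
#' amounts (normalized to the final absorbed amount); (3) compute
#' supersaturation metrics per cup; (4) fit the double Weibull model per
#' group; (5) generate in vivo oral plasma from the ground-truth Level-A
#' correlation applied to the fitted Weibull curves, plus an i.v. arm;
#' (6) fit the unit impulse response, deconvolve each oral arm, fit the
#' correlation on the training groups, predict the external group, and
#' validate with FDA-style prediction errors. All intermediates are
#' persisted as CSV under `outdir` with a JSON manifest that fully
#' determines a rerun.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Integer master seed; every stochastic stage derives its
#'   seed from it.
#' @param noise_sigma Relative measurement noise applied to the synthetic
#'   plasma profiles (0 for a noise-free run).
#' @param truth Ground-truth [ivivc_params()] linking in vitro to in vivo.
#' @param training_groups,external_group Group routing: training groups
#'   establish the correlation, the external group is predicted only.
#' @param cfg A [dgim_config()].
#' @param pk A [pk_disposition()] for the i.v. disposition kernel.
#' @param t_vivo In vivo sampling times, hours.
#' @param grid_vitro In vitro sampling grid, minutes.
#' @return Invisibly, a list with the fitted objects: `solubility_fits`,
#'   `weibull_fits`, `ds`, `uir`, `correlation`, `report`
#'   ([pe_report()]), `validation`, `truth`, `manifest_path`.
#' @export
run_pipeline <- function(outdir, seed = 1L, noise_sigma = 0.05,
                         truth = ivivc_params(0.9757, 1.629, 4.397e-5),
                         training_groups = c("control", "PVPVA"),
                         external_group = "HPMC",
                         cfg = dgim_config(), pk = pk_disposition(),
                         t_vivo = c(0.083, 0.25, 0.5, 1, 2, 4, 6, 8, 10),
                         grid_vitro = seq(0, 180, by = 1)) {
  seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  groups <- c(training_groups, external_group)
  paths <- list()
  put <- function(df, name) {
    p <- file.path(outdir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[[name]] <<- p
    p
  }

  # -- stage 1: solubility fits on synthetic measurement tables ----------
  ph_grid <- c(2, 3, 4, 4.7, 5, 6, 6.5)
  sol_fits <- list()
  sol_rows <- list()
  for (g in groups) {
    preset <- ktz_solubility_preset(g)
    truth_cs <- eval_solubility(preset, ph_grid)
    meas <- ts_values(add_noise(
      timeseries(seq_along(ph_grid), truth_cs, "h"),
      sigma = 0.03, seed = seed * 101L + match(g, groups)))
    sol_fits[[g]] <- fit_ph_solubility(ph_grid, meas)
    sol_rows[[g]] <- data.frame(group = g, pH = ph_grid,
                                solubility_ug_per_ml = meas)
  }
  put(do.call(rbind, sol_rows), "solubility_points")
  put(data.frame(group = groups,
                 C_U = vapply(sol_fits, `[[`, 0, "C_U"),
                 pKa = vapply(sol_fits, `[[`, 0, "pKa"),
                 rss = vapply(sol_fits, `[[`, 0, "rss")),
      "solubility_fits")

  # -- stage 2+3: transfer simulation, in vitro Fabs, DS metrics ---------
  runs <- list(); fabs_vitro <- list(); ds_rows <- list()
  for (g in groups) {
    run <- simulate_dgim(cfg, group_scenario(g), grid = grid_vitro)
    runs[[g]] <- run
    tot <- ts_values(run$duodenal_org) + ts_values(run$jejunal_org)
    # in vitro absorbed fraction of the dose (combined octanol phases)
    fabs_vitro[[g]] <- timeseries(grid_vitro, tot / run$dose_mg,
                                  time_unit = "min",
                                  value_unit = "fraction", group = g)
    for (cup in c("duodenal", "jejunal")) {
      conc <- run[[paste0(cup, "_aq")]]
      pH <- run[[if (cup == "duodenal") "pH_d" else "pH_j"]]
      m <- ds_metrics(ds_profile(conc, pH, run$scenario$solubility_fit))
      ds_rows[[paste(g, cup)]] <- data.frame(
        group = g, cup = cup, DS_max = m$DS_max, DS_auc = m$DS_auc,
        t_at_DSmax_min = m$t_at_DSmax)
    }
    curves <- data.frame(
      time_min = grid_vitro,
      duodenal_aq = ts_values(run$duodenal_aq),
      jejunal_aq = ts_values(run$jejunal_aq),
      duodenal_org = ts_values(run$duodenal_org),
      jejunal_org = ts_values(run$jejunal_org),
      pH_d = ts_values(run$pH_d), pH_j = ts_values(run$pH_j))
    put(curves, paste0("dgim_curves_", g))
  }
  put(do.call(rbind, ds_rows), "ds_metrics")

  # -- stage 4: in vitro Weibull fits ------------------------------------
  # fitted on the dose-fraction curve; the correlation input `Diss` is the
  # same model normalized to unit plateau (percent-of-final convention)
  wb <- lapply(groups, function(g) {
    fit_dissolution(fabs_vitro[[g]], "weibull2", seed = seed)
  })
  names(wb) <- groups
  diss_norm <- lapply(wb, function(f) {
    p <- f$params
    p$F_inf <- 1
    p
  })
  put(data.frame(group = groups,
                 t(vapply(wb, function(f) unlist(f$params[
                   c("F_inf", "f1", "MDT1", "b1", "MDT2", "b2", "Tlag")]),
                   numeric(7))),
      rss = vapply(wb, `[[`, 0, "rss"),
      aic = vapply(wb, `[[`, 0, "aic")), "weibull_fits")

  # -- stage 5: synthetic in vivo arms -----------------------------------
  dose_oral <- pk$dose_oral_mg_kg * pk$weight_kg
  dose_iv <- pk$dose_iv_mg_kg * pk$weight_kg
  pk1 <- pk; pk1$F_true <- 1     # the truth correlation carries the scale
  oral_obs <- list()
  for (g in groups) {
    wh <- weibull_convert_time(diss_norm[[g]], "h")
    fabs_true <- predict_fabs(truth, wh, t_grid = c(0, t_vivo))
    pl <- simulate_plasma(fabs_true, pk1, route = "oral", t_out = t_vivo)
    pl <- add_noise(pl, noise_sigma, seed = seed * 211L + match(g, groups))
    attr(pl, "group") <- g
    oral_obs[[g]] <- pl
    put(data.frame(time_h = t_vivo, conc_ng_per_ml = ts_values(pl),
                   group = g), paste0("plasma_oral_", g))
  }
  iv_obs <- add_noise(simulate_plasma(pk = pk, route = "iv",
                                      t_out = t_vivo),
                      noise_sigma, seed = seed * 307L)
  put(data.frame(time_h = t_vivo, conc_ng_per_ml = ts_values(iv_obs),
                 group = "iv"), "plasma_iv")

  # -- stage 6: IVIVC chain ----------------------------------------------
  uir <- fit_uir(iv_obs, dose_iv, seed = seed)
  fabs_vivo <- lapply(oral_obs, deconvolve, uir = uir,
                      dose_oral = dose_oral)
  corr <- fit_correlation(fabs_vivo[training_groups],
                          diss_norm[training_groups],
                          seed = seed)
  obs <- t(vapply(oral_obs, function(pl) {
    r <- nca(pl); c(Cmax = r$Cmax, AUC = r$AUC_last)
  }, numeric(2)))
  pred <- t(vapply(groups, function(g) {
    wh <- weibull_convert_time(diss_norm[[g]], "h")
    fp <- predict_fabs(corr, wh, t_grid = c(0, t_vivo))
    pp <- convolve_predict_plasma(fp, uir, dose_oral, F_ref = 1,
                                  t_out = t_vivo)
    r <- nca(pp)
    c(Cmax = r$Cmax, AUC = r$AUC_last)
  }, numeric(2)))
  report <- pe_report(obs, pred, groups = groups)
  report$table$role <- ifelse(report$table$group %in% training_groups,
                              "internal", "external")
  validation <- validate_ivivc(report)
  put(report$table, "pe_report")
  put(validation, "validation")

  manifest <- list(
    package = "dgim", version = as.character(utils::packageVersion("dgim")),
    seed = seed, noise_sigma = noise_sigma,
    truth = unclass(truth),
    training_groups = training_groups, external_group = external_group,
    correlation = unclass(corr),
    uir = list(A = uir$A, lambda = uir$lambda),
    timestamp = format(Sys.time(), tz = "UTC"),
    files = paths)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(solubility_fits = sol_fits, runs = runs,
                 fabs_vitro = fabs_vitro, weibull_fits = wb,
                 uir = uir, fabs_vivo = fabs_vivo, correlation = corr,
                 report = report, validation = validation, truth = truth,
                 manifest_path = manifest_path))
}
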