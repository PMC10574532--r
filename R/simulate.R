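#' Luminal kinetics of the synthetic-data generator
#'
#' Mechanistic parameters driving the supersaturation-precipitation
#' ("spring and parachute") structure of the simulated in vitro curves.
#' Precipitation is first order in the supersaturation excess
#' `max(C - Cs(pH), 0)` with no redissolution and no nucleation lag;
#' aqueous-to-octanol transfer is one-way and first order in the aqueous
#' concentration (the octanol layer acts as an absorptive sink). The pH of
#' each intestinal cup is depressed below its set point in proportion to
#' the fraction of its fluid that originated in the acidic gastric cup.
#'
#' @param kp Precipitation rate constant, 1/min. Encodes inhibitor
#'   strength: control > HPMC > PVPVA.
#' @param ka_d,ka_j Apparent aqueous-to-octanol transfer rates in the
#'   duodenal and jejunal cups, 1/min.
#' @param pH_dip_gain pH depression per unit gastric-origin fraction.
#' @param noise_sigma Relative measurement noise applied by the caller.
#' @param seed Integer seed recorded with generated data.
#' @return An object of class `luminal_kinetics`.
#' @export
luminal_kinetics <- function(kp = 0.2, ka_d = 0.010, ka_j = 0.008,
                             pH_dip_gain = 1.0, noise_sigma = 0,
                             seed = 1L) {
  stopifnot(kp >= 0, ka_d >= 0, ka_j >= 0, pH_dip_gain >= 0,
            noise_sigma >= 0)
  structure(list(kp = kp, ka_d = ka_d, ka_j = ka_j,
                 pH_dip_gain = pH_dip_gain, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "luminal_kinetics")
}

#' Experimental group scenario
#'
#' @param label Group label: `"control"`, `"PVPVA"` or `"HPMC"`.
#' @param solubility_fit A [ph_solubility_fit()] giving the equilibrium
#'   solubility of the drug for this group's medium.
#' @param dose_conc_gastric Drug concentration pre-dissolved in the gastric
#'   medium, mg/mL.
#' @param inhibitor_conc Precipitation-inhibitor concentration, mg/mL.
#' @return An object of class `group_scenario`.
#' @export
group_scenario <- function(label = c("control", "PVPVA", "HPMC"),
                           solubility_fit = NULL,
                           dose_conc_gastric = 5.2,
                           inhibitor_conc = NULL) {
  label <- match.arg(label)
  stopifnot(dose_conc_gastric > 0)
  if (is.null(solubility_fit)) solubility_fit <- ktz_solubility_preset(label)
  if (is.null(inhibitor_conc)) {
    inhibitor_conc <- if (label == "control") 0 else 10
  }
  structure(list(label = label, solubility_fit = solubility_fit,
                 dose_conc_gastric = dose_conc_gastric,
                 inhibitor_conc = inhibitor_conc),
            class = "group_scenario")
}

#' Default kinetics per group
#'
#' Precipitation rate constants ordered control > HPMC > PVPVA so that the
#' inhibitors prolong supersaturation, with common absorption rates.
#'
#' @param label Group label.
#' @return A [luminal_kinetics()].
#' @export
ktz_kinetics_preset <- function(label = c("control", "PVPVA", "HPMC")) {
  label <- match.arg(label)
  kp <- switch(label, control = 0.20, PVPVA = 0.04, HPMC = 0.06)
  luminal_kinetics(kp = kp)
}

#' Simulate the three-cup transfer dissolution run
#'
#' Integrates the drug mass balance of the apparatus: the pre-dissolved
#' gastric solution empties into the duodenal cup, whose overflow feeds the
#' jejunal cup; drug-free secretion dilutes the gastric and duodenal cups;
#' in each intestinal cup drug precipitates at rate
#' `kp V max(C - Cs(pH), 0)` and transfers into the octanol layer at rate
#' `ka V C`. The cup pH is its set point depressed by
#' `pH_dip_gain * gastric_origin_fraction(t)` (clamped to `[1.5, 7]`),
#' which reproduces the early pH dip and recovery of the duodenal cup and
#' hence the transient supersaturation peak. Total drug mass (gastric
#' residual + dissolved + precipitated + organic) is conserved by
#' construction; the integrator preserves it to floating-point accuracy.
#'
#' @param cfg A [dgim_config()].
#' @param scenario A [group_scenario()].
#' @param kin A [luminal_kinetics()].
#' @param grid Output time grid, min, within `[0, duration]`.
#' @param dt Integrator step, min (classical Runge-Kutta; the pump-stop
#'   breakpoint is an exact grid node).
#' @return A list of class `dgim_run` with `dgim_ts` elements
#'   `duodenal_aq`, `jejunal_aq` (ug/mL), `duodenal_org`, `jejunal_org`
#'   (mg in the octanol layer), `pH_d`, `pH_j`,
#'   `precipitated_mass_d`, `precipitated_mass_j` (mg), plus `mass_balance`
#'   (total drug mass over time, mg), `dose_mg`, and the inputs.
#' @export
simulate_dgim <- function(cfg = dgim_config(), scenario = group_scenario(),
                          kin = ktz_kinetics_preset(scenario$label),
                          grid = seq(0, cfg$duration, by = 1), dt = 0.05) {
  if (any(grid < 0) || any(grid > cfg$duration)) {
    stop(sprintf("grid must lie within [0, %g] min", cfg$duration))
  }
  fit <- scenario$solubility_fit
  stopifnot(inherits(fit, "ph_solubility_fit"))
  M0 <- scenario$dose_conc_gastric * cfg$Vg0        # mg
  pHs <- cfg$pH_set
  gain <- kin$pH_dip_gain

  ph_of <- function(set, frac) pmin(pmax(set - gain * frac, 1.5), 7)
  # solubility in mg/mL from the ug/mL fit
  cs_of <- function(pH) fit$C_U * (1 + 10^(fit$pKa - pH)) / 1000

  # state: Mg, Md, Mj, Od, Oj, Pd, Pj, Gd, Gj  (mg; G* in mL)
  deriv <- function(tt, y) {
    va <- pump_rate_a(tt, cfg); vb <- pump_rate_b(tt, cfg)
    te <- min(tt, cfg$pump_stop)
    Vg <- cfg$Vg0 * 2^(-te / cfg$th)
    Vj <- cfg$Vj0 + cfg$Vg0 * (1 - 2^(-te / cfg$th)) +
      2 * cfg$secretion_rate * te
    Cg <- y[1L] / Vg
    Cd <- y[2L] / cfg$Vd
    Cj <- y[3L] / Vj
    fd <- min(max(y[8L] / cfg$Vd, 0), 1)
    fj <- min(max(y[9L] / Vj, 0), 1)
    cs_d <- cs_of(ph_of(pHs[2L], fd))
    cs_j <- cs_of(ph_of(pHs[3L], fj))
    J_gd <- Cg * va                               # gastric -> duodenal
    J_dj <- Cd * vb                               # duodenal -> jejunal
    J_pd <- kin$kp * cfg$Vd * max(Cd - cs_d, 0)   # precipitation
    J_pj <- kin$kp * Vj * max(Cj - cs_j, 0)
    J_ad <- kin$ka_d * cfg$Vd * Cd                # absorption into octanol
    J_aj <- kin$ka_j * Vj * Cj
    c(-J_gd,
      J_gd - J_dj - J_pd - J_ad,
      J_dj - J_pj - J_aj,
      J_ad, J_aj, J_pd, J_pj,
      va - fd * vb,
      vb * fd)
  }

  times <- sort(unique(c(seq(0, cfg$duration, by = dt), grid,
                         cfg$pump_stop, cfg$duration)))
  path <- rk4_path(deriv, c(M0, 0, 0, 0, 0, 0, 0, 0, 0), times)
  idx <- match(grid, times)
  te <- pmin(grid, cfg$pump_stop)
  Vj <- cfg$Vj0 + cfg$Vg0 * (1 - 2^(-te / cfg$th)) + 2 * cfg$secretion_rate * te
  fd <- pmin(pmax(path[idx, 8L] / cfg$Vd, 0), 1)
  fj <- pmin(pmax(path[idx, 9L] / Vj, 0), 1)
  gl <- scenario$label
  mk <- function(v, unit, lab) {
    timeseries(grid, v, time_unit = "min", value_unit = unit,
               label = lab, group = gl)
  }
  structure(list(
    duodenal_aq = mk(path[idx, 2L] / cfg$Vd * 1000, "ug/mL", "duodenal_aq"),
    jejunal_aq  = mk(path[idx, 3L] / Vj * 1000, "ug/mL", "jejunal_aq"),
    duodenal_org = mk(path[idx, 4L], "mg", "duodenal_org"),
    jejunal_org  = mk(path[idx, 5L], "mg", "jejunal_org"),
    pH_d = mk(ph_of(pHs[2L], fd), "pH", "pH_d"),
    pH_j = mk(ph_of(pHs[3L], fj), "pH", "pH_j"),
    precipitated_mass_d = mk(path[idx, 6L], "mg", "precipitated_mass_d"),
    precipitated_mass_j = mk(path[idx, 7L], "mg", "precipitated_mass_j"),
    mass_balance = mk(rowSums(path[idx, 1:7, drop = FALSE]), "mg",
                      "total_mass"),
    dose_mg = M0, cfg = cfg, scenario = scenario, kin = kin),
    class = "dgim_run")
}

#' Simulate the single-vessel pH-shift biphasic test
#'
#' The drug is pre-dissolved in 250 mL of gastric medium under 200 mL of
#' octanol. At the shift time, 500 mL of concentrated intestinal medium is
#' added: the aqueous volume jumps to 750 mL (an exact 3-fold dilution of
#' the concentration) and the pH jumps to the intestinal set point. Before
#' the shift the drug is essentially fully ionized at gastric pH, so
#' neither precipitation nor octanol transfer occurs; after the shift both
#' proceed with the same first-order laws as in [simulate_dgim()].
#'
#' @param scenario A [group_scenario()].
#' @param kin A [luminal_kinetics()]; `ka_d` is used as the transfer rate.
#' @param grid Output grid, min.
#' @param V_pre,V_post Aqueous volumes before/after the shift, mL.
#' @param octanol Octanol volume, mL (metadata).
#' @param shift_time Shift time, min; must lie inside the grid range.
#' @param pH_pre,pH_post Gastric and post-shift pH.
#' @param dt Integrator step, min.
#' @return A list of class `usp2_run` with `dgim_ts` elements `aqueous`
#'   (ug/mL), `organic` (mg), `precipitated_mass` (mg), `mass_balance`
#'   (mg), and `dose_mg`. At exactly `shift_time` the reported aqueous
#'   value is the post-dilution one.
#' @export
simulate_usp2_ph_shift <- function(scenario = group_scenario(),
                                   kin = ktz_kinetics_preset(scenario$label),
                                   grid = seq(0, 180, by = 1),
                                   V_pre = 250, V_post = 750, octanol = 200,
                                   shift_time = 20,
                                   pH_pre = 2.0, pH_post = 6.0, dt = 0.05) {
  if (shift_time <= min(grid) || shift_time >= max(grid)) {
    stop("shift_time must lie strictly inside the time grid")
  }
  fit <- scenario$solubility_fit
  M0 <- scenario$dose_conc_gastric * V_pre     # mg
  cs_post <- eval_solubility(fit, pH_post) / 1000
  # post-shift state: M (dissolved, mg), O (organic), P (precipitate)
  deriv <- function(tt, y) {
    C <- y[1L] / V_post
    J_p <- kin$kp * V_post * max(C - cs_post, 0)
    J_a <- kin$ka_d * V_post * C
    c(-J_p - J_a, J_a, J_p)
  }
  post_t <- sort(unique(c(seq(shift_time, max(grid), by = dt),
                          grid[grid >= shift_time], max(grid))))
  path <- rk4_path(deriv, c(M0, 0, 0), post_t)
  pre <- grid < shift_time
  aq <- ifelse(pre, M0 / V_pre, NA_real_)
  org <- ifelse(pre, 0, NA_real_)
  prec <- ifelse(pre, 0, NA_real_)
  idx <- match(grid[!pre], post_t)
  aq[!pre] <- path[idx, 1L] / V_post
  org[!pre] <- path[idx, 2L]
  prec[!pre] <- path[idx, 3L]
  gl <- scenario$label
  mk <- function(v, unit, lab) {
    timeseries(grid, v, time_unit = "min", value_unit = unit,
               label = lab, group = gl)
  }
  total <- ifelse(pre, M0, NA_real_)
  total[!pre] <- rowSums(path[idx, , drop = FALSE])
  structure(list(
    aqueous = mk(aq * 1000, "ug/mL", "aqueous"),
    organic = mk(org, "mg", "organic"),
    precipitated_mass = mk(prec, "mg", "precipitated_mass"),
    mass_balance = mk(total, "mg", "total_mass"),
    dose_mg = M0, scenario = scenario, kin = kin,
    V_pre = V_pre, V_post = V_post, octanol = octanol,
    shift_time = shift_time, pH_pre = pH_pre, pH_post = pH_post),
    class = "usp2_run")
}

#' Linear-disposition pharmacokinetic parameters
#'
#' The i.v. disposition of the drug is a dose-normalized polyexponential
#' unit impulse response `K(t) = sum A_i exp(-lambda_i t)` (ng/mL per mg,
#' t in hours). Defaults describe a biexponential disposition with an
#' effective terminal half-life of about 2 h in a 0.2 kg rat, with oral
#' and i.v. doses of 10 and 2.5 mg/kg.
#'
#' @param A Coefficients, (ng/mL)/mg.
#' @param lambda Rate constants, 1/h (all > 0), at most 2 terms here
#'   (the fitting side allows up to 3).
#' @param dose_oral_mg_kg,dose_iv_mg_kg Doses, mg/kg.
#' @param weight_kg Body weight used to convert to absolute mg.
#' @param F_true True absolute oral bioavailability in (0, 1].
#' @return An object of class `pk_disposition`.
#' @export
pk_disposition <- function(A = c(60000, 30000), lambda = c(2.0, 0.35),
                           dose_oral_mg_kg = 10, dose_iv_mg_kg = 2.5,
                           weight_kg = 0.2, F_true = 0.70) {
  stopifnot(length(A) == length(lambda), length(A) <= 2L,
            all(lambda > 0), F_true > 0, F_true <= 1,
            dose_oral_mg_kg > 0, dose_iv_mg_kg > 0, weight_kg > 0)
  structure(list(A = A, lambda = lambda,
                 dose_oral_mg_kg = dose_oral_mg_kg,
                 dose_iv_mg_kg = dose_iv_mg_kg,
                 weight_kg = weight_kg, F_true = F_true),
            class = "pk_disposition")
}

#' Simulate plasma concentration profiles
#'
#' The i.v. profile is the dose-scaled unit impulse response. The oral
#' profile is the convolution of the absorption input rate -- the
#' derivative of `F_true * dose * Fabs(t)` for a piecewise-linear absorbed
#' fraction -- with the impulse response, evaluated segment-exactly in
#' closed form. A non-zero `Fabs` at `t = 0` is treated as an instantaneous
#' bolus of that fraction (so a unit step at zero reproduces the scaled
#' kernel exactly).
#'
#' @param input_fraction A `dgim_ts` on hours, non-decreasing in `[0, 1]`:
#'   the absorbed-fraction ground truth. Ignored for `route = "iv"`.
#' @param pk A [pk_disposition()].
#' @param route `"oral"` or `"iv"`.
#' @param t_out Output grid, hours; defaults to the input grid (oral) or
#'   a standard sparse sampling design (iv).
#' @return A `dgim_ts` of plasma concentration, ng/mL, on hours.
#' @export
simulate_plasma <- function(input_fraction = NULL, pk = pk_disposition(),
                            route = c("oral", "iv"), t_out = NULL) {
  route <- match.arg(route)
  uir <- uir_params(pk$A, pk$lambda)
  if (route == "iv") {
    if (is.null(t_out)) t_out <- c(0.083, 0.25, 0.5, 1, 2, 4, 6, 8, 10)
    dose_iv <- pk$dose_iv_mg_kg * pk$weight_kg
    return(timeseries(t_out, dose_iv * eval_uir(uir, t_out),
                      time_unit = "h", value_unit = "ng/mL",
                      label = "iv_plasma"))
  }
  stopifnot(inherits(input_fraction, "dgim_ts"))
  if (ts_time_unit(input_fraction) != "h") {
    input_fraction <- ts_convert_time(input_fraction, "h")
  }
  v <- ts_values(input_fraction)
  if (any(diff(v) < -1e-9)) stop("input_fraction must be non-decreasing")
  if (any(v < -1e-9) || any(v > 1 + 1e-9)) {
    stop("input_fraction must lie in [0, 1]")
  }
  if (is.null(t_out)) t_out <- ts_times(input_fraction)
  dose_oral <- pk$dose_oral_mg_kg * pk$weight_kg
  conc <- convolve_pwl_input(ts_times(input_fraction), v, uir,
                             amount = pk$F_true * dose_oral, t_out = t_out)
  timeseries(t_out, conc, time_unit = "h", value_unit = "ng/mL",
             label = "oral_plasma")
}
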