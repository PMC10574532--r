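#' Degree of supersaturation
#'
#' The ratio of the apparent (measured) concentration to the equilibrium
#' solubility at the prevailing pH. `DS > 1` indicates a thermodynamically
#' unstable, supersaturated solution.
#'
#' @param C Apparent concentration(s), ug/mL, >= 0.
#' @param Cs Equilibrium solubility(ies), ug/mL, > 0.
#' @return `C / Cs`, dimensionless.
#' @examples
#' degree_of_supersaturation(1819, 150)
#' @export
degree_of_supersaturation <- function(C, Cs) {
  if (any(Cs <= 0)) stop("equilibrium solubility must be positive")
  if (any(C < 0)) stop("concentration must be non-negative")
  C / Cs
}

#' Supersaturation profile from concentration and pH series
#'
#' Evaluates the pointwise degree of supersaturation of a concentration
#' curve, computing the equilibrium solubility at each time from the
#' concurrent pH via the fitted pH-solubility model. If the pH series is
#' on a different grid it is linearly interpolated onto the concentration
#' grid (which must lie within the pH observation range).
#'
#' @param conc A `dgim_ts` of concentration, ug/mL.
#' @param pH A `dgim_ts` of pH on the same time unit.
#' @param fit A [ph_solubility_fit()].
#' @return A `dgim_ts` of DS values on `conc`'s grid.
#' @export
ds_profile <- function(conc, pH, fit) {
  stopifnot(inherits(conc, "dgim_ts"), inherits(pH, "dgim_ts"),
            inherits(fit, "ph_solubility_fit"))
  if (ts_time_unit(conc) != ts_time_unit(pH)) {
    pH <- ts_convert_time(pH, ts_time_unit(conc))
  }
  tgt <- ts_times(conc)
  if (identical(tgt, ts_times(pH))) {
    phv <- ts_values(pH)
  } else {
    phv <- ts_values(ts_interp(pH, tgt))
  }
  cs <- eval_solubility(fit, phv)
  timeseries(tgt, degree_of_supersaturation(ts_values(conc), cs),
             time_unit = ts_time_unit(conc), value_unit = "DS",
             label = "DS", group = attr(conc, "group"))
}

#' Summary metrics of a supersaturation profile
#'
#' `DS_max` measures the intensity of supersaturation (peak value, earliest
#' time on ties) and `DS_auc` its endurance (linear-trapezoid integral over
#' the observation window, reported in dimensionless-hours regardless of
#' the series' native time unit).
#'
#' @param ds A non-empty `dgim_ts` of DS values.
#' @return A list of class `ds_metrics`: `DS_max`, `DS_auc`
#'   (dimensionless * h), `t_at_DSmax` (native time unit).
#' @export
ds_metrics <- function(ds) {
  stopifnot(inherits(ds, "dgim_ts"))
  if (nrow(ds) == 0L) stop("empty series")
  v <- ts_values(ds); t <- ts_times(ds)
  i <- which.max(v)                 # which.max returns the earliest maximum
  th <- if (ts_time_unit(ds) == "min") t / 60 else t
  auc <- if (length(t) > 1L) {
    sum(diff(th) * (v[-length(v)] + v[-1L]) / 2)
  } else 0
  structure(list(DS_max = v[i], DS_auc = auc, t_at_DSmax = t[i]),
            class = "ds_metrics")
}

#' @export
print.ds_metrics <- function(x, ...) {
  cat(sprintf("<DS metrics: DS_max = %.4g at t = %.4g, DS_auc = %.4g h>\n",
              x$DS_max, x$t_at_DSmax, x$DS_auc))
  invisible(x)
}
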