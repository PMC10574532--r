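#' Area under the curve by the linear trapezoidal rule
#'
#' `AUC_last`: the integral up to the last observation. No extrapolation to
#' infinity is performed (a terminal-slope rule is deliberately not
#' invented).
#'
#' @param ts A `dgim_ts` with at least two points and strictly increasing
#'   times.
#' @return The integral in (value unit) x (time unit of the series).
#' @examples
#' auc_linear_trapezoid(timeseries(c(0, 1, 2), c(0, 1, 1), "h", "ng/mL"))
#' @export
auc_linear_trapezoid <- function(ts) {
  stopifnot(inherits(ts, "dgim_ts"))
  t <- ts_times(ts); v <- ts_values(ts)
  if (length(t) < 2L) stop("need at least 2 points")
  sum(diff(t) * (v[-length(v)] + v[-1L]) / 2)
}

#' Peak concentration and its time
#'
#' @param ts A non-empty `dgim_ts`.
#' @return A list `(Cmax, Tmax)`; ties in the maximum resolve to the
#'   earliest time.
#' @export
cmax_tmax <- function(ts) {
  stopifnot(inherits(ts, "dgim_ts"))
  if (nrow(ts) == 0L) stop("empty series")
  i <- which.max(ts_values(ts))
  list(Cmax = ts_values(ts)[i], Tmax = ts_times(ts)[i])
}

#' Absolute oral bioavailability from dose-normalized exposures
#'
#' @param auc_po,auc_iv AUCs of the oral and i.v. profiles (> 0).
#' @param dose_po,dose_iv The corresponding doses (> 0), any common unit.
#' @return Percent: `100 * (auc_po/dose_po) / (auc_iv/dose_iv)`.
#' @examples
#' absolute_bioavailability(auc_po = 70, dose_po = 10,
#'                          auc_iv = 25, dose_iv = 2.5)
#' @export
absolute_bioavailability <- function(auc_po, dose_po, auc_iv, dose_iv) {
  if (any(c(auc_po, dose_po, auc_iv, dose_iv) <= 0)) {
    stop("AUCs and doses must be positive")
  }
  100 * (auc_po / dose_po) / (auc_iv / dose_iv)
}

#' Non-compartmental analysis of a plasma profile
#'
#' @param ts A `dgim_ts` of plasma concentration; converted to hours if
#'   supplied in minutes.
#' @param iv_ref Optional list `(ts, dose)` of an i.v. reference profile
#'   and its dose, enabling absolute bioavailability.
#' @param dose Dose of the analyzed profile (same unit as `iv_ref$dose`).
#' @return A list of class `nca_result`: `Cmax`, `Tmax` (h), `AUC_last`
#'   (h.ng/mL), and `F_abs_percent` when the i.v. reference is given.
#' @export
nca <- function(ts, dose = NULL, iv_ref = NULL) {
  ts <- ts_convert_time(ts, "h")
  ct <- cmax_tmax(ts)
  out <- list(Cmax = ct$Cmax, Tmax = ct$Tmax,
              AUC_last = auc_linear_trapezoid(ts),
              F_abs_percent = NULL)
  if (!is.null(iv_ref)) {
    if (is.null(dose)) stop("dose is required for bioavailability")
    auc_iv <- auc_linear_trapezoid(ts_convert_time(iv_ref$ts, "h"))
    out$F_abs_percent <- absolute_bioavailability(out$AUC_last, dose,
                                                  auc_iv, iv_ref$dose)
  }
  class(out) <- "nca_result"
  out
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<NCA: Cmax = %.4g at %.3g h, AUC_last = %.6g h.ng/mL%s>\n",
              x$Cmax, x$Tmax, x$AUC_last,
              if (!is.null(x$F_abs_percent))
                sprintf(", F = %.3g%%", x$F_abs_percent) else ""))
  invisible(x)
}
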