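#' Double Weibull dissolution model parameters
#'
#' A two-process mixture of Weibull dissolution processes with a shared lag:
#' \deqn{F(t) = F_\infty [ f_1 (1 - e^{-((t-T_{lag})/MDT_1)^{b_1}})
#'            + (1-f_1)(1 - e^{-((t-T_{lag})/MDT_2)^{b_2}}) ]}
#' and `F(t) = 0` for `t <= Tlag`. With `f1 = 1` it reduces to the single
#' Weibull model. A per-process-lag variant replaces the shared `Tlag` with
#' `Tlag2` for the second process.
#'
#' @param F_inf Plateau fraction, in (0, 1.05].
#' @param f1 Weight of the first process, in `[0, 1]`.
#' @param MDT1,MDT2 Scale (mean-dissolution-time-like) parameters, > 0,
#'   in the model's time unit.
#' @param b1,b2 Shape parameters, > 0.
#' @param Tlag Shared lag time, >= 0.
#' @param Tlag2 Optional separate lag for the second process (per-process
#'   lag variant); default `NULL` means shared lag.
#' @param time_unit Time unit of the scale/lag parameters.
#' @return An object of class `double_weibull`.
#' @export
double_weibull <- function(F_inf, f1 = 1, MDT1, b1, MDT2 = MDT1, b2 = b1,
                           Tlag = 0, Tlag2 = NULL,
                           time_unit = c("min", "h")) {
  time_unit <- match.arg(time_unit)
  stopifnot(F_inf > 0, F_inf <= 1.05, f1 >= 0, f1 <= 1,
            MDT1 > 0, MDT2 > 0, b1 > 0, b2 > 0, Tlag >= 0,
            is.null(Tlag2) || Tlag2 >= 0)
  structure(list(F_inf = F_inf, f1 = f1, MDT1 = MDT1, b1 = b1,
                 MDT2 = MDT2, b2 = b2, Tlag = Tlag, Tlag2 = Tlag2,
                 time_unit = time_unit),
            class = "double_weibull")
}

#' @export
print.double_weibull <- function(x, ...) {
  cat(sprintf(paste0("<double Weibull: F_inf = %.4g, f1 = %.3g, ",
                     "MDT = (%.4g, %.4g) %s, b = (%.3g, %.3g), ",
                     "Tlag = %.4g>\n"),
              x$F_inf, x$f1, x$MDT1, x$MDT2, x$time_unit,
              x$b1, x$b2, x$Tlag))
  invisible(x)
}

#' Evaluate the (double) Weibull dissolution model
#'
#' @param p A [double_weibull()].
#' @param t Times (same unit as the parameters); values at or before the
#'   lag evaluate to 0, and negative times are allowed (also 0).
#' @return Dissolved/absorbed fraction, non-decreasing in `t`.
#' @export
eval_double_weibull <- function(p, t) {
  stopifnot(inherits(p, "double_weibull"))
  lag2 <- if (is.null(p$Tlag2)) p$Tlag else p$Tlag2
  x1 <- pmax(t - p$Tlag, 0)
  x2 <- pmax(t - lag2, 0)
  p$F_inf * (p$f1 * (1 - exp(-(x1 / p$MDT1)^p$b1)) +
             (1 - p$f1) * (1 - exp(-(x2 / p$MDT2)^p$b2)))
}

#' Re-express Weibull time parameters in another unit
#'
#' Scale and lag parameters are converted (factor 60); shapes, weights and
#' the plateau are unit-free. Used at the in vitro (minutes) to in vivo
#' (hours) boundary of the correlation engine.
#'
#' @param p A [double_weibull()].
#' @param to Target unit.
#' @return A `double_weibull` in the target unit.
#' @export
weibull_convert_time <- function(p, to = c("h", "min")) {
  to <- match.arg(to)
  if (p$time_unit == to) return(p)
  fac <- if (p$time_unit == "min") 1 / 60 else 60
  double_weibull(p$F_inf, p$f1, p$MDT1 * fac, p$b1, p$MDT2 * fac, p$b2,
                 p$Tlag * fac,
                 if (is.null(p$Tlag2)) NULL else p$Tlag2 * fac,
                 time_unit = to)
}

#' Fit a Weibull dissolution model to a fraction-time curve
#'
#' Bounded least squares with multistart. Starting scale parameters come
#' from quantile heuristics (the times at which the curve reaches 35% and
#' 70% of its final level), jittered per start under a fixed seed; the
#' best of all converged starts is returned. The report's AIC uses the
#' least-squares form `n log(RSS/n) + 2k`.
#'
#' @param ts A `dgim_ts` of dissolved/absorbed fraction (values within
#'   `[0, 1.05]`).
#' @param model `"weibull1"` (single) or `"weibull2"` (double).
#' @param n_starts Number of multistart initializations.
#' @param seed Seed for start jitter.
#' @param per_process_lag Fit the variant with a separate lag for the
#'   second process (double model only).
#' @return A list of class `dissolution_fit`: `params`
#'   ([double_weibull()]), `rss`, `n_obs`, `k_params`, `aic`,
#'   `start_rss` (RSS achieved from each start).
#' @export
fit_dissolution <- function(ts, model = c("weibull2", "weibull1"),
                            n_starts = 20, seed = 1L,
                            per_process_lag = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(ts, "dgim_ts"))
  t <- ts_times(ts); y <- ts_values(ts)
  if (any(y < -1e-9) || any(y > 1.05 + 1e-9)) {
    stop("fraction values must lie in [0, 1.05]")
  }
  k <- switch(model, weibull1 = 4L, weibull2 = if (per_process_lag) 8L else 7L)
  if (length(t) < 2L * k) {
    stop(sprintf("need at least %d points to fit %s, have %d",
                 2L * k, model, length(t)))
  }
  tu <- ts_time_unit(ts)
  plateau <- max(y)
  if (plateau <= 1e-8) {
    stop("series is identically zero; no dissolution to fit")
  }
  t35 <- t[which(y >= 0.35 * plateau)[1L]]
  t70 <- t[which(y >= 0.70 * plateau)[1L]]
  tmax <- max(t)
  lag_ub <- max(tmax / 2, 1e-6)

  unpack <- function(par) {
    if (model == "weibull1") {
      double_weibull(par[1L], 1, par[2L], par[3L], par[2L], par[3L],
                     par[4L], time_unit = tu)
    } else if (!per_process_lag) {
      double_weibull(par[1L], par[2L], par[3L], par[4L], par[5L], par[6L],
                     par[7L], time_unit = tu)
    } else {
      double_weibull(par[1L], par[2L], par[3L], par[4L], par[5L], par[6L],
                     par[7L], par[8L], time_unit = tu)
    }
  }
  obj <- function(par) {
    p <- try(unpack(par), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    sum((y - eval_double_weibull(p, t))^2)
  }
  lo_hi <- switch(model,
    weibull1 = list(lo = c(1e-4, 1e-4, 0.05, 0), hi = c(1.05, 10 * tmax, 8, lag_ub)),
    weibull2 = if (!per_process_lag) {
      list(lo = c(1e-4, 0, 1e-4, 0.05, 1e-4, 0.05, 0),
           hi = c(1.05, 1, 10 * tmax, 8, 10 * tmax, 8, lag_ub))
    } else {
      list(lo = c(1e-4, 0, 1e-4, 0.05, 1e-4, 0.05, 0, 0),
           hi = c(1.05, 1, 10 * tmax, 8, 10 * tmax, 8, lag_ub, lag_ub))
    })
  base <- switch(model,
    weibull1 = c(min(plateau, 1.04), max(t35, 1e-3), 1, 0),
    weibull2 = {
      b <- c(min(plateau, 1.04), 0.5, max(t35, 1e-3), 1,
             max(t70, 1e-3), 1, 0)
      if (per_process_lag) c(b, 0) else b
    })
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  best <- NULL
  start_rss <- rep(NA_real_, n_starts)
  for (s in seq_len(n_starts)) {
    p0 <- base
    if (s > 1L) {
      jit <- stats::rlnorm(length(base), 0, 0.5)
      p0 <- base * jit
      if (model != "weibull1") p0[2L] <- stats::runif(1)
      p0[length(p0)] <- stats::runif(1, 0, min(t35, lag_ub))
      if (per_process_lag) p0[7L] <- stats::runif(1, 0, min(t35, lag_ub))
    }
    p0 <- pmin(pmax(p0, lo_hi$lo + 1e-9), lo_hi$hi - 1e-9)
    o <- try(stats::optim(p0, obj, method = "L-BFGS-B",
                          lower = lo_hi$lo, upper = lo_hi$hi,
                          control = list(maxit = 300)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    start_rss[s] <- o$value
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("all multistart fits failed")
  # polish only the incumbent to solver precision
  pol <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-15))
  if (pol$value < best$value) best <- pol
  pol <- stats::optim(best$par, obj, method = "L-BFGS-B",
                      lower = lo_hi$lo, upper = lo_hi$hi,
                      control = list(maxit = 2000, factr = 1))
  if (pol$value < best$value) best <- pol
  n <- length(t)
  pbest <- unpack(best$par)
  # canonical labeling: process 1 is the faster one (MDT1 <= MDT2)
  if (model == "weibull2" && pbest$MDT1 > pbest$MDT2) {
    pbest <- double_weibull(pbest$F_inf, 1 - pbest$f1,
                            pbest$MDT2, pbest$b2, pbest$MDT1, pbest$b1,
                            if (per_process_lag) pbest$Tlag2 else pbest$Tlag,
                            if (per_process_lag) pbest$Tlag else NULL,
                            time_unit = tu)
  }
  structure(list(params = pbest, rss = best$value, n_obs = n,
                 k_params = k,
                 aic = n * log(max(best$value, 1e-300) / n) + 2 * k,
                 start_rss = start_rss),
            class = "dissolution_fit")
}

#' @export
print.dissolution_fit <- function(x, ...) {
  cat(sprintf("<dissolution fit: RSS = %.4g, n = %d, k = %d, AIC = %.4g>\n",
              x$rss, x$n_obs, x$k_params, x$aic))
  print(x$params)
  invisible(x)
}
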