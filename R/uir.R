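#' Polyexponential unit impulse response
#'
#' The dose-normalized plasma kernel of a linear-disposition drug:
#' `K(t) = sum_i A_i exp(-lambda_i t)`, in (ng/mL) per mg of dose reaching
#' the circulation, with `t` in hours. Up to three exponential terms.
#'
#' @param A Coefficients, (ng/mL)/mg.
#' @param lambda Positive rate constants, 1/h.
#' @return An object of class `uir_params`.
#' @export
uir_params <- function(A, lambda) {
  stopifnot(length(A) == length(lambda), length(A) >= 1L, length(A) <= 3L,
            all(is.finite(A)), all(is.finite(lambda)), all(lambda > 0))
  structure(list(A = as.numeric(A), lambda = as.numeric(lambda)),
            class = "uir_params")
}

#' @rdname uir_params
#' @param uir A `uir_params`.
#' @param t Times, hours.
#' @export
eval_uir <- function(uir, t) {
  stopifnot(inherits(uir, "uir_params"))
  out <- numeric(length(t))
  for (i in seq_along(uir$A)) out <- out + uir$A[i] * exp(-uir$lambda[i] * t)
  out
}

#' @export
print.uir_params <- function(x, ...) {
  cat("<unit impulse response:",
      paste(sprintf("%.4g*exp(-%.4g t)", x$A, x$lambda), collapse = " + "),
      "ng/mL per mg>\n")
  invisible(x)
}

# Exact convolution of a constant input rate on [a, b] with the
# exponential kernel, evaluated at times t (vector): per term,
#   a <= t <  b : (A/lambda) (1 - exp(-lambda (t - a)))
#   t >= b      : (A/lambda) (exp(-lambda (t - b)) - exp(-lambda (t - a)))
conv_interval_unit_rate <- function(uir, a, b, t) {
  out <- numeric(length(t))
  for (i in seq_along(uir$A)) {
    Ai <- uir$A[i]; li <- uir$lambda[i]
    inside <- t > a & t < b
    after <- t >= b
    v <- numeric(length(t))
    v[inside] <- Ai / li * (1 - exp(-li * (t[inside] - a)))
    v[after] <- Ai / li * (exp(-li * (t[after] - b)) - exp(-li * (t[after] - a)))
    out <- out + v
  }
  out
}

# Plasma from a piecewise-linear cumulative input (fraction grid ft/fv
# scaled by `amount` in mg), convolved segment-exactly with the kernel.
# A non-zero fraction at the first time point is applied as a bolus there.
convolve_pwl_input <- function(ft, fv, uir, amount, t_out) {
  stopifnot(length(ft) == length(fv))
  conc <- numeric(length(t_out))
  if (fv[1L] > 0) {
    dt0 <- t_out - ft[1L]
    ok <- dt0 >= 0
    conc[ok] <- conc[ok] + amount * fv[1L] * eval_uir(uir, dt0[ok])
  }
  if (length(ft) > 1L) {
    for (s in seq_len(length(ft) - 1L)) {
      a <- ft[s]; b <- ft[s + 1L]
      rate <- amount * (fv[s + 1L] - fv[s]) / (b - a)
      if (rate != 0) {
        conc <- conc + rate * conv_interval_unit_rate(uir, a, b, t_out)
      }
    }
  }
  conc
}

#' Fit a polyexponential unit impulse response to i.v. plasma data
#'
#' Dose-normalizes the i.v. profile and fits a sum of 1 to `max_terms`
#' exponentials by weighted least squares with `1/y^2` (relative) weights,
#' the standard choice for plasma assays whose error is proportional to
#' the measured concentration; without it the high early concentrations
#' dominate the objective and spurious exponential terms absorb their
#' noise. Coefficients and rates are kept positive by optimizing on the
#' log scale, with multistart. The model order is chosen
#' by the small-sample corrected least-squares AIC,
#' `n log(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with `k = 2 * n_terms`: sparse
#' i.v. designs (about 9 samples) leave the uncorrected AIC with a
#' noise-independent overfitting probability of roughly 15 percent per
#' extra exponential, which the correction removes.
#'
#' @param iv_plasma A `dgim_ts` of i.v. plasma concentration (ng/mL, hours).
#' @param dose_iv Administered i.v. dose, mg.
#' @param max_terms Maximum number of exponential terms (1-3).
#' @param n_starts Multistart count per order.
#' @param seed Seed for the start jitter.
#' @return A `uir_params` with attributes `rss`, `aic`, `n_terms` and
#'   `aic_by_order`.
#' @export
fit_uir <- function(iv_plasma, dose_iv, max_terms = 3, n_starts = 10,
                    seed = 1L) {
  stopifnot(inherits(iv_plasma, "dgim_ts"), dose_iv > 0)
  t <- ts_times(ts_convert_time(iv_plasma, "h"))
  y <- ts_values(iv_plasma) / dose_iv
  if (length(t) < 4L) stop("need at least 4 i.v. points")
  w <- 1 / pmax(y, max(y) * 1e-6)^2
  rss_of <- function(par, k) {
    if (any(!is.finite(par)) || any(abs(par) > 50)) return(1e300)
    A <- exp(par[seq_len(k)]); l <- exp(par[k + seq_len(k)])
    r <- sum(w * (y - eval_uir(uir_params(A, l), t))^2)
    if (!is.finite(r)) 1e300 else r
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  best <- NULL
  aics <- rep(NA_real_, max_terms)
  n <- length(t)
  for (k in seq_len(max_terms)) {
    if (n <= 2 * k + 1L) break
    # crude init: log-linear tail rate, amplitude from the first point
    l0 <- max((log(max(y[1L], 1e-12)) - log(max(y[n], 1e-12))) /
                max(t[n] - t[1L], 0.1), 0.1)
    base <- c(log(rep(max(y) / k, k)),
              log(l0 * 4^(seq_len(k) - (k + 1) / 2)))
    kb <- NULL
    for (s in seq_len(n_starts)) {
      p0 <- base + if (s == 1L) 0 else stats::rnorm(2 * k, 0, 0.7)
      o <- try(stats::optim(p0, rss_of, k = k, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14)),
               silent = TRUE)
      if (inherits(o, "try-error")) next
      o2 <- stats::optim(o$par, rss_of, k = k, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
      cand <- if (o2$value < o$value) o2 else o
      if (is.null(kb) || cand$value < kb$value) kb <- cand
    }
    if (is.null(kb)) next
    kk <- 2 * k
    aic <- n * log(max(kb$value, 1e-300) / n) + 2 * kk +
      2 * kk * (kk + 1) / max(n - kk - 1, 1)
    aics[k] <- aic
    if (is.null(best) || aic < attr(best, "aic")) {
      A <- exp(kb$par[seq_len(k)]); l <- exp(kb$par[k + seq_len(k)])
      ord <- order(l, decreasing = TRUE)
      best <- uir_params(A[ord], l[ord])
      attr(best, "rss") <- kb$value
      attr(best, "aic") <- aic
      attr(best, "n_terms") <- k
    }
  }
  if (is.null(best)) stop("unit-impulse-response fit failed for all orders")
  attr(best, "aic_by_order") <- aics
  best
}

# Lawson-Hanson non-negative least squares: min ||Ax - b||, x >= 0.
nnls_solve <- function(A, b, tol = NULL) {
  m <- ncol(A)
  x <- numeric(m)
  passive <- logical(m)
  w <- crossprod(A, b - A %*% x)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(A)) * max(dim(A))
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol && iter < 30L * m) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(m)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

#' Deconvolve an oral plasma profile into an absorbed-fraction curve
#'
#' Estimates a piecewise-constant, non-negative drug input rate on the
#' observation intervals (from zero to each successive sampling time) by
#' least squares against its exact convolution with the fitted unit
#' impulse response, then accumulates it into the fraction of the dose
#' absorbed. With as many intervals as observations the system interpolates
#' the data exactly (up to active non-negativity constraints), which is
#' what makes the deconvolution-convolution round trip a usable
#' correctness contract.
#'
#' @param oral_plasma A `dgim_ts` of oral plasma concentration (hours).
#' @param uir A [uir_params()].
#' @param dose_oral Oral dose, mg.
#' @param ridge Optional Tikhonov penalty on the input rates (default 0)
#'   for noisy or ill-conditioned grids.
#' @return A `dgim_ts` of absorbed fraction `Fabs(t)` at `t = 0` and the
#'   observation times: non-decreasing, `Fabs(0) = 0`. Attribute `rate`
#'   carries the estimated interval rates (mg/h).
#' @export
deconvolve <- function(oral_plasma, uir, dose_oral, ridge = 0) {
  stopifnot(inherits(oral_plasma, "dgim_ts"), inherits(uir, "uir_params"),
            dose_oral > 0, ridge >= 0)
  ts <- ts_convert_time(oral_plasma, "h")
  t <- ts_times(ts); y <- ts_values(ts)
  edges <- c(0, t[t > 0])
  if (t[1L] == 0) { y <- y[-1L]; t <- t[-1L] }
  nint <- length(edges) - 1L
  if (nint < 1L) stop("need at least one positive observation time")
  M <- matrix(0, length(t), nint)
  for (j in seq_len(nint)) {
    M[, j] <- conv_interval_unit_rate(uir, edges[j], edges[j + 1L], t)
  }
  cn <- tryCatch(kappa(M, exact = FALSE), error = function(e) Inf)
  if (!is.finite(cn) || cn > 1e10) {
    if (ridge <= 0) {
      stop(paste("deconvolution system is ill-conditioned;",
                 "coarsen the grid or set ridge > 0"))
    }
  }
  if (ridge > 0) {
    M <- rbind(M, sqrt(ridge) * diag(nint))
    y <- c(y, numeric(nint))
  }
  r <- nnls_solve(M, y)
  fabs <- c(0, cumsum(r * diff(edges))) / dose_oral
  out <- timeseries(edges, fabs, time_unit = "h", value_unit = "fraction",
                    label = "Fabs", group = attr(oral_plasma, "group"))
  attr(out, "rate") <- r
  out
}
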