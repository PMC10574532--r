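#' pH-dependent solubility of a weak base
#'
#' A monoprotic weak base dissolves as the sum of its unionized and ionized
#' forms. With the unionized-form solubility `C_U` and acid dissociation
#' constant `pKa`, the equilibrium solubility at a given pH follows a
#' modified Henderson-Hasselbalch relation
#' \deqn{C_s(pH) = C_U (1 + 10^{pKa - pH}).}
#' Solubility is strictly decreasing in pH and tends to `C_U` as the drug
#' becomes fully unionized at high pH.
#'
#' @param C_U Unionized-form solubility, ug/mL (> 0).
#' @param pKa Acid dissociation constant (dimensionless).
#' @param pKa_bounds Admissible pKa range, used by the fitter.
#' @return An object of class `ph_solubility_fit`.
#' @examples
#' fit <- ph_solubility_fit(C_U = 11, pKa = 6.322)
#' eval_solubility(fit, c(2, 5.9, 6.5))
#' @export
ph_solubility_fit <- function(C_U, pKa, pKa_bounds = c(2, 10)) {
  stopifnot(is.numeric(C_U), length(C_U) == 1L, is.finite(C_U),
            is.numeric(pKa), length(pKa) == 1L, is.finite(pKa))
  if (C_U <= 0) stop("C_U must be positive")
  if (pKa < pKa_bounds[1L] || pKa > pKa_bounds[2L]) {
    stop(sprintf("pKa %.4g outside bounds [%g, %g]", pKa,
                 pKa_bounds[1L], pKa_bounds[2L]))
  }
  structure(list(C_U = C_U, pKa = pKa, pKa_bounds = pKa_bounds),
            class = "ph_solubility_fit")
}

#' @export
print.ph_solubility_fit <- function(x, ...) {
  cat(sprintf("<pH-solubility fit: C_U = %.4g ug/mL, pKa = %.4g>\n",
              x$C_U, x$pKa))
  invisible(x)
}

#' Evaluate equilibrium solubility at given pH
#'
#' @param fit A [ph_solubility_fit()].
#' @param pH Numeric vector of pH values in (0, 14).
#' @return Solubility in ug/mL, same length as `pH`.
#' @export
eval_solubility <- function(fit, pH) {
  stopifnot(inherits(fit, "ph_solubility_fit"))
  if (any(pH <= 0) || any(pH >= 14)) stop("pH must lie strictly in (0, 14)")
  out <- fit$C_U * (1 + 10^(fit$pKa - pH))
  if (any(!is.finite(out))) {
    bad <- pH[which(!is.finite(out))[1L]]
    stop(sprintf("solubility overflow at pH %.3g (pKa - pH too large)", bad))
  }
  out
}

#' Fit the pH-solubility model to measured points
#'
#' Least squares on log(solubility): measured solubilities typically span
#' about two orders of magnitude between pH 3 and 6.5, and the log scale
#' equalizes the relative weight of acidic and near-neutral points. For a
#' fixed pKa the intercept log(C_U) has a closed form (the mean log
#' residual), so the problem reduces to a one-dimensional bounded
#' optimization over pKa.
#'
#' @param pH,solubility Numeric vectors of measurements (ug/mL).
#' @param exclude_pH Optional pH values to drop before fitting; matched
#'   within `exclude_tol`. Measurements at strongly acidic pH can be biased
#'   (assay dilution, buffer capacity) and are commonly excluded.
#' @param exclude_tol Matching tolerance for the exclusion list.
#' @param pKa_bounds Search interval for pKa.
#' @return A `ph_solubility_fit` with diagnostics attached: `rss`
#'   (residual sum of squares on the log scale), `residuals` (per-point,
#'   log scale), `n` and `at_bound` (TRUE when pKa hit a search bound,
#'   e.g. for degenerate pH-independent data).
#' @export
fit_ph_solubility <- function(pH, solubility, exclude_pH = NULL,
                              exclude_tol = 0.05, pKa_bounds = c(2, 10)) {
  stopifnot(length(pH) == length(solubility))
  keep <- rep(TRUE, length(pH))
  for (ex in exclude_pH) keep <- keep & abs(pH - ex) > exclude_tol
  pH <- pH[keep]; sol <- solubility[keep]
  if (any(sol <= 0)) stop("solubility values must be positive")
  if (any(pH <= 0 | pH >= 14)) stop("pH values must lie in (0, 14)")
  if (length(pH) < 3L) {
    stop(sprintf("need at least 3 usable points after exclusion, have %d",
                 length(pH)))
  }
  ls <- log(sol)
  # profiled objective: for fixed pKa, log(C_U) = mean(ls - log1p(10^(pKa-pH)))
  obj <- function(pKa) {
    g <- log1p(10^(pKa - pH))
    mu <- mean(ls - g)
    sum((ls - g - mu)^2)
  }
  opt <- stats::optimize(obj, interval = pKa_bounds, tol = 1e-10)
  # optimize() can stop short of a flat boundary; polish with a local search
  pKa <- opt$minimum
  pol <- stats::optim(pKa, obj, method = "Brent",
                      lower = pKa_bounds[1L], upper = pKa_bounds[2L],
                      control = list(reltol = 1e-14))
  if (pol$value < opt$objective) pKa <- pol$par
  g <- log1p(10^(pKa - pH))
  logCU <- mean(ls - g)
  fit <- ph_solubility_fit(exp(logCU), pKa, pKa_bounds = pKa_bounds)
  fit$rss <- sum((ls - g - logCU)^2)
  fit$residuals <- ls - g - logCU
  fit$n <- length(pH)
  fit$at_bound <- min(pKa - pKa_bounds[1L], pKa_bounds[2L] - pKa) < 1e-6
  fit
}

#' Bundled pH-solubility parameter presets for ketoconazole
#'
#' Synthetic reference fits anchored to published characteristics of
#' ketoconazole in biorelevant media at 37 C: a control pKa of 6.322 that
#' precipitation inhibitors reduce to 6.077 (PVPVA) and 6.087 (HPMC), with
#' unionized-form solubilities chosen so the inhibitors raise near-neutral
#' solubility by the reported 1.25- and 1.16-fold at pH 6.5. These are
#' stand-ins for laboratory fits, used as generator ground truth.
#'
#' @param group One of `"control"`, `"PVPVA"`, `"HPMC"`.
#' @return A [ph_solubility_fit()].
#' @export
ktz_solubility_preset <- function(group = c("control", "PVPVA", "HPMC")) {
  group <- match.arg(group)
  switch(group,
    control = ph_solubility_fit(C_U = 11.0, pKa = 6.322),
    PVPVA   = ph_solubility_fit(C_U = 16.6, pKa = 6.077),
    HPMC    = ph_solubility_fit(C_U = 15.3, pKa = 6.087))
}
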