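#' DGIM apparatus configuration
#'
#' Geometry and pump programme of the three-cup transfer apparatus: a
#' gastric cup emptying with first-order kinetics into a constant-volume
#' duodenal cup, whose overflow feeds a jejunal cup. Gastric and duodenal
#' cups each receive 1 mL/min of four-fold concentrated biorelevant
#' secretion; the jejunal cup receives none (this keeps the duodenal volume
#' exactly constant and the gastric volume purely exponential). Pumps run
#' until `pump_stop`, after which all flows are zero and volumes freeze,
#' while measurement continues to `duration`.
#'
#' @param Vg0 Initial gastric volume, mL.
#' @param Vd Constant duodenal aqueous volume, mL.
#' @param Vj0 Initial jejunal aqueous volume, mL.
#' @param th Gastric half-emptying time, min.
#' @param secretion_rate Secretion into each secreted cup, mL/min.
#' @param secretion_concentration_factor Concentration factor of the
#'   secreted media (recorded metadata; the secretion is drug-free).
#' @param pump_stop Time at which the pumps stop, min.
#' @param duration Total observed time, min.
#' @param octanol_d,octanol_j Octanol absorptive-phase volumes, mL.
#' @param pH_set Set-point pH of gastric, duodenal and jejunal media.
#' @param paddle_rpm Paddle speed, metadata only.
#' @return An object of class `dgim_config`.
#' @examples
#' cfg <- dgim_config()
#' pump_rate_a(c(0, 8, 41), cfg)
#' @export
dgim_config <- function(Vg0 = 300, Vd = 50, Vj0 = 100, th = 8,
                        secretion_rate = 1,
                        secretion_concentration_factor = 4,
                        pump_stop = 40, duration = 180,
                        octanol_d = 100, octanol_j = 100,
                        pH_set = c(gastric = 2.0, duodenal = 5.9,
                                   jejunal = 6.1),
                        paddle_rpm = 50) {
  stopifnot(Vg0 > 0, Vd > 0, Vj0 > 0, th > 0,
            secretion_rate >= 0, pump_stop > 0, pump_stop <= duration,
            octanol_d > 0, octanol_j > 0, length(pH_set) == 3L)
  structure(list(Vg0 = Vg0, Vd = Vd, Vj0 = Vj0, th = th,
                 secretion_rate = secretion_rate,
                 secretion_concentration_factor = secretion_concentration_factor,
                 pump_stop = pump_stop, duration = duration,
                 octanol_d = octanol_d, octanol_j = octanol_j,
                 pH_set = pH_set, paddle_rpm = paddle_rpm),
            class = "dgim_config")
}

#' @export
print.dgim_config <- function(x, ...) {
  cat(sprintf(paste0("<DGIM config: Vg0 = %g mL, Vd = %g mL, Vj0 = %g mL, ",
                     "th = %g min, pumps until %g min, observed %g min>\n"),
              x$Vg0, x$Vd, x$Vj0, x$th, x$pump_stop, x$duration))
  invisible(x)
}

#' Pump rates of the transfer apparatus
#'
#' Pump A empties the gastric cup at the first-order rate
#' `(ln2/th) * Vg0 * exp(-ln2 t/th)` plus the 1 mL/min gastric secretion it
#' carries along; pump B moves the duodenal overflow, which exceeds pump A
#' by exactly the duodenal secretion rate, guaranteeing a constant duodenal
#' volume. Both are zero after `pump_stop`.
#'
#' The apparatus programme is sometimes quoted without the `1/th` factor in
#' the exponential prefactor, which is dimensionally inconsistent (mL
#' instead of mL/min) and does not halve the gastric volume every `th`;
#' `as_printed = TRUE` evaluates that literal form for comparison.
#'
#' @param t Time(s), min, non-negative.
#' @param cfg A [dgim_config()].
#' @param as_printed Use the literal (dimensionally inconsistent) prefactor
#'   `ln2 * Vg0` instead of `ln2/th * Vg0`.
#' @return Pump rate(s), mL/min.
#' @export
pump_rate_a <- function(t, cfg = dgim_config(), as_printed = FALSE) {
  if (any(t < 0)) stop("t must be non-negative")
  pref <- if (as_printed) log(2) * cfg$Vg0 else log(2) / cfg$th * cfg$Vg0
  va <- pref * exp(-log(2) * t / cfg$th) + cfg$secretion_rate
  ifelse(t <= cfg$pump_stop, va, 0)
}

#' @rdname pump_rate_a
#' @export
pump_rate_b <- function(t, cfg = dgim_config(), as_printed = FALSE) {
  if (any(t < 0)) stop("t must be non-negative")
  ifelse(t <= cfg$pump_stop,
         pump_rate_a(t, cfg, as_printed) + cfg$secretion_rate, 0)
}

#' Compartment volumes over time
#'
#' Closed forms: the gastric secretion exactly offsets the secretion term of
#' pump A, so `Vg(t) = Vg0 * 2^(-t/th)`; `Vd` is constant; the jejunal
#' volume accumulates the pump B inflow,
#' `Vj(t) = Vj0 + Vg0 (1 - 2^(-t/th)) + 2 * secretion_rate * t`.
#' All volumes freeze at `pump_stop`.
#'
#' @param t Time(s) in `[0, duration]`, min.
#' @param cfg A [dgim_config()].
#' @return A data frame with columns `t`, `va`, `vb`, `Vg`, `Vd`, `Vj`.
#' @export
dgim_volumes <- function(t, cfg = dgim_config()) {
  if (any(t < 0) || any(t > cfg$duration)) {
    stop(sprintf("t must lie in [0, %g] min", cfg$duration))
  }
  te <- pmin(t, cfg$pump_stop)   # volumes freeze when the pumps stop
  Vg <- cfg$Vg0 * 2^(-te / cfg$th)
  Vj <- cfg$Vj0 + cfg$Vg0 * (1 - 2^(-te / cfg$th)) +
    2 * cfg$secretion_rate * te
  data.frame(t = t, va = pump_rate_a(t, cfg), vb = pump_rate_b(t, cfg),
             Vg = Vg, Vd = rep(cfg$Vd, length(t)), Vj = Vj)
}

#' Fraction of aqueous volume of gastric origin in an intestinal cup
#'
#' Tracks how much of the fluid in the duodenal (or jejunal) cup originated
#' in the gastric cup, under the well-mixed assumption. The duodenal cup
#' receives pure gastric fluid at rate `va` and drug-free secretion; its
#' outflow `vb` carries the current mixture, giving
#' `d f_d/dt = (va - f_d vb) / Vd`. The jejunal cup accumulates the pump B
#' mixture with no outflow. Fractions are frozen after `pump_stop`. The
#' duodenal fraction rises steeply toward `va/vb` and then relaxes toward
#' `secretion-only` proportions as gastric emptying decays: a unimodal
#' curve. It drives the transient pH depression of the intestinal cups.
#'
#' @param t Time(s), min, within `[0, duration]`.
#' @param cfg A [dgim_config()].
#' @param cup `"duodenum"` or `"jejunum"`.
#' @param dt Integration step, min.
#' @return Fraction(s) in `[0, 1]` at `t`.
#' @export
gastric_origin_fraction <- function(t, cfg = dgim_config(),
                                    cup = c("duodenum", "jejunum"),
                                    dt = 0.05) {
  cup <- match.arg(cup)
  if (any(t < 0) || any(t > cfg$duration)) {
    stop(sprintf("t must lie in [0, %g] min", cfg$duration))
  }
  grid <- origin_fraction_grid(cfg, dt)
  col <- if (cup == "duodenum") grid$fd else grid$fj
  stats::approx(grid$t, col, xout = t, rule = 2)$y
}

# RK4 on [0, pump_stop] for the origin-volume states (Gd, Gj); frozen after.
origin_fraction_grid <- function(cfg, dt = 0.05) {
  deriv <- function(tt, y) {
    va <- pump_rate_a(tt, cfg); vb <- pump_rate_b(tt, cfg)
    c(va - y[1L] / cfg$Vd * vb, vb * (y[1L] / cfg$Vd))
  }
  tt <- unique(c(seq(0, cfg$pump_stop, by = dt), cfg$pump_stop))
  y <- rk4_path(deriv, c(0, 0), tt)
  fd <- pmin(pmax(y[, 1L] / cfg$Vd, 0), 1)
  Vj <- cfg$Vj0 + cfg$Vg0 * (1 - 2^(-tt / cfg$th)) + 2 * cfg$secretion_rate * tt
  fj <- pmin(pmax(y[, 2L] / Vj, 0), 1)
  if (cfg$duration > cfg$pump_stop) {
    tt <- c(tt, cfg$duration)
    fd <- c(fd, fd[length(fd)])
    fj <- c(fj, fj[length(fj)])
  }
  list(t = tt, fd = fd, fj = fj)
}

# Fixed-step classical Runge-Kutta along a supplied (possibly uneven) grid.
# deriv(t, y) returns dy/dt; returns the matrix of states at each grid time.
rk4_path <- function(deriv, y0, times) {
  n <- length(times)
  out <- matrix(NA_real_, n, length(y0))
  out[1L, ] <- y <- y0
  for (i in seq_len(n - 1L)) {
    h <- times[i + 1L] - times[i]
    t0 <- times[i]
    k1 <- deriv(t0, y)
    k2 <- deriv(t0 + h / 2, y + h / 2 * k1)
    k3 <- deriv(t0 + h / 2, y + h / 2 * k2)
    k4 <- deriv(t0 + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- y
  }
  out
}
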