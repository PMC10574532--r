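# Independent oracles used across the suite. These deliberately avoid the
# package's own solvers: explicit Euler instead of RK4, grid search instead
# of profiled optimization, cumulative sums instead of closed forms.

# Fine-step midpoint (second-order Runge-Kutta) integration of
# dy/dt = deriv(t, y); deliberately a different scheme and step policy
# than the package's classical RK4.
euler_path <- function(deriv, y0, t_end, dt = 1e-3) {
  n <- ceiling(t_end / dt)
  y <- y0
  tt <- 0
  for (i in seq_len(n)) {
    h <- min(dt, t_end - tt)
    k <- deriv(tt, y)
    y <- y + h * deriv(tt + h / 2, y + h / 2 * k)
    tt <- tt + h
  }
  y
}

# Grid-search solubility fit: pKa on a fixed grid, C_U profiled in closed
# form on the log scale.
grid_search_solubility <- function(pH, sol, pKa_grid = seq(2, 10, by = 1e-3)) {
  ls <- log(sol)
  rss <- vapply(pKa_grid, function(pKa) {
    g <- log1p(10^(pKa - pH))
    mu <- mean(ls - g)
    sum((ls - g - mu)^2)
  }, numeric(1))
  i <- which.min(rss)
  g <- log1p(10^(pKa_grid[i] - pH))
  list(pKa = pKa_grid[i], C_U = exp(mean(ls - g)), rss = rss[i])
}

# Riemann-midpoint integral of the piecewise-linear interpolant of (t, v).
riemann_pwl <- function(t, v, n = 2e5) {
  tt <- seq(min(t), max(t), length.out = n)
  vv <- approx(t, v, xout = tt)$y
  mean((vv[-1] + vv[-n]) / 2) * (max(t) - min(t))
}

# Synthetic i.v. sampling design used throughout (hours).
tv_design <- c(0.083, 0.25, 0.5, 1, 2, 4, 6, 8, 10)

# A fixed, well-separated double-Weibull truth (minutes) for recovery tests.
wb_truth_min <- function() {
  double_weibull(0.92, 0.55, 12, 1.3, 45, 2.0, Tlag = 3, time_unit = "min")
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
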