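#' Ordered time series
#'
#' The universal exchange container of the package: an ordered set of
#' `(time, value)` samples with explicit units. Concentration curves,
#' fraction-dissolved curves, absorbed-fraction curves and plasma profiles
#' are all `dgim_ts` objects.
#'
#' @param time Numeric vector of strictly increasing sampling times.
#' @param value Numeric vector, same length as `time`.
#' @param time_unit One of `"min"` or `"h"`.
#' @param value_unit Free-text unit label (e.g. `"ug/mL"`, `"ng/mL"`,
#'   `"fraction"`).
#' @param label Optional series label (e.g. `"duodenal_aq"`).
#' @param group Optional group label (e.g. `"control"`).
#' @return An object of class `dgim_ts`: a data frame with columns `time`
#'   and `value` and unit/label attributes.
#' @examples
#' ts <- timeseries(c(0, 1, 2), c(0, 0.5, 1), time_unit = "h",
#'                  value_unit = "fraction")
#' ts_values(ts)
#' @export
timeseries <- function(time, value, time_unit = c("min", "h"),
                       value_unit = "", label = NULL, group = NULL) {
  time_unit <- match.arg(time_unit)
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) {
    stop("`time` and `value` must have the same length")
  }
  if (anyNA(time) || anyNA(value)) stop("time series must not contain NA")
  if (length(time) > 1L && any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1L] + 1L
    stop(sprintf("times must be strictly increasing (violated at row %d)", bad))
  }
  structure(
    data.frame(time = time, value = value),
    time_unit = time_unit,
    value_unit = value_unit,
    label = label,
    group = group,
    class = c("dgim_ts", "data.frame")
  )
}

#' @rdname timeseries
#' @param x A `dgim_ts` object.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "dgim_ts"))
  x$time
}

#' @rdname timeseries
#' @export
ts_values <- function(x) {
  stopifnot(inherits(x, "dgim_ts"))
  x$value
}

#' @rdname timeseries
#' @export
ts_time_unit <- function(x) attr(x, "time_unit")

#' Convert the time axis of a series between minutes and hours
#'
#' @param x A `dgim_ts`.
#' @param to Target unit, `"min"` or `"h"`.
#' @return A `dgim_ts` on the requested time unit (factor 1/60 or 60).
#' @export
ts_convert_time <- function(x, to = c("h", "min")) {
  to <- match.arg(to)
  from <- ts_time_unit(x)
  if (from == to) return(x)
  fac <- if (from == "min" && to == "h") 1 / 60 else 60
  timeseries(ts_times(x) * fac, ts_values(x), time_unit = to,
             value_unit = attr(x, "value_unit"),
             label = attr(x, "label"), group = attr(x, "group"))
}

#' @export
print.dgim_ts <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<time series%s: %d points, t in [%g, %g] %s, value unit '%s'>\n",
              if (!is.null(lab)) paste0(" '", lab, "'") else "",
              nrow(x), min(x$time), max(x$time),
              attr(x, "time_unit"), attr(x, "value_unit")))
  invisible(x)
}

#' Read / write a time series as CSV
#'
#' The on-disk dialect is comma-separated, period decimal, UTF-8, with a
#' header. The time column must be named `time_min` or `time_h` (fixing the
#' unit), the value column `value`; optional columns `label` and `group`
#' carry series metadata. Times must be strictly increasing.
#'
#' @param path File path.
#' @param unit Optional target time unit; if the file unit differs the axis
#'   is converted explicitly (factor 1/60 or 60).
#' @return `read_timeseries()` returns a `dgim_ts`; `write_timeseries()`
#'   returns `path` invisibly.
#' @export
read_timeseries <- function(path, unit = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("time_min", "time_h"), names(df))
  if (length(tcol) != 1L || !"value" %in% names(df)) {
    stop("CSV must have one of time_min/time_h plus a value column")
  }
  file_unit <- if (tcol == "time_min") "min" else "h"
  if (length(df[[tcol]]) > 1L && any(diff(df[[tcol]]) <= 0)) {
    bad <- which(diff(df[[tcol]]) <= 0)[1L] + 1L
    stop(sprintf("times in %s are not strictly increasing at data row %d",
                 path, bad))
  }
  ts <- timeseries(df[[tcol]], df$value, time_unit = file_unit,
                   value_unit = if ("value_unit" %in% names(df))
                     df$value_unit[1L] else "",
                   label = if ("label" %in% names(df)) df$label[1L] else NULL,
                   group = if ("group" %in% names(df)) df$group[1L] else NULL)
  if (!is.null(unit)) ts <- ts_convert_time(ts, unit)
  ts
}

#' @rdname read_timeseries
#' @param x A `dgim_ts` to write.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "dgim_ts"))
  df <- data.frame(time = ts_times(x), value = ts_values(x))
  names(df)[1L] <- paste0("time_", ts_time_unit(x))
  vu <- attr(x, "value_unit")
  if (!is.null(vu) && nzchar(vu)) df$value_unit <- vu
  if (!is.null(attr(x, "label"))) df$label <- attr(x, "label")
  if (!is.null(attr(x, "group"))) df$group <- attr(x, "group")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Linear interpolation of a series onto a new grid
#'
#' @param x A `dgim_ts`.
#' @param times New time grid (same unit as `x`); must lie within the
#'   observed range.
#' @return A `dgim_ts` on `times`.
#' @export
ts_interp <- function(x, times) {
  rng <- range(ts_times(x))
  if (any(times < rng[1L] - 1e-12) || any(times > rng[2L] + 1e-12)) {
    stop("interpolation grid extends beyond the observed time range")
  }
  v <- stats::approx(ts_times(x), ts_values(x), xout = times, rule = 1)$y
  timeseries(times, v, time_unit = ts_time_unit(x),
             value_unit = attr(x, "value_unit"),
             label = attr(x, "label"), group = attr(x, "group"))
}

#' Multiplicative lognormal measurement noise
#'
#' Each value is multiplied by an independent lognormal deviate with unit
#' median and coefficient of variation approximately `sigma`. Reproducible
#' under a fixed seed; `sigma = 0` returns the input unchanged.
#'
#' @param x A `dgim_ts`.
#' @param sigma Relative noise level (e.g. 0.05 for 5 percent).
#' @param seed Integer seed; if `NULL` the current RNG stream is used.
#' @return A `dgim_ts` with perturbed values.
#' @export
add_noise <- function(x, sigma, seed = NULL) {
  stopifnot(inherits(x, "dgim_ts"), sigma >= 0)
  if (sigma == 0) return(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  sdlog <- sqrt(log(1 + sigma^2))
  mult <- stats::rlnorm(nrow(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  timeseries(ts_times(x), ts_values(x) * mult, time_unit = ts_time_unit(x),
             value_unit = attr(x, "value_unit"),
             label = attr(x, "label"), group = attr(x, "group"))
}
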