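#' Regularly sampled time series
#'
#' A `uniform_series` is the package's basic container for a scalar signal on
#' a regular time grid: a start time `t0` (minutes), a grid spacing `dt`
#' (minutes), the sample values, and a unit label.  Each sample is interpreted
#' as the value over the half-open interval `[t, t + dt)`.
#'
#' @param values numeric vector of samples (no `NA` after imputation).
#' @param t0 start time in minutes.
#' @param dt grid spacing in minutes (> 0).
#' @param unit unit label, e.g. `"mU/min"`.
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, t0 = 0, dt = 5, unit = "") {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number of minutes", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), t0 = as.numeric(t0),
         dt = as.numeric(dt), unit = unit),
    class = "uniform_series"
  )
}

#' Sample times of a uniform series
#'
#' @param x a [uniform_series()].
#' @return Numeric vector of sample times (minutes, left edges).
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0 + (seq_along(x$values) - 1L) * x$dt
}

#' End of the span covered by a uniform series
#' @param x a [uniform_series()].
#' @return The right edge `t0 + n * dt` of the last half-open interval.
#' @export
series_end <- function(x) x$t0 + length(x$values) * x$dt

#' Construct an empty (all-zero) grid template
#'
#' Convenience constructor for the grid argument of the rasterization
#' operations: a zero-valued [uniform_series()] spanning `[t0, t_end)`.
#'
#' @param t0,t_end span in minutes (`t_end` > `t0`).
#' @param dt grid spacing in minutes.
#' @return A zero-filled `uniform_series`.
#' @export
time_grid <- function(t0, t_end, dt = 5) {
  stopifnot(t_end > t0)
  n <- ceiling((t_end - t0) / dt - 1e-9)
  uniform_series(numeric(n), t0 = t0, dt = dt)
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples, t0 = %g min, dt = %g min%s\n",
              length(x$values), x$t0, x$dt,
              if (nzchar(x$unit)) paste0(", unit = ", x$unit) else ""))
  cat("  range: [", format(min(x$values)), ", ", format(max(x$values)),
      "]\n", sep = "")
  invisible(x)
}

# Zero-order-hold lookup function for a uniform series (constant on each
# half-open cell, clamped to the first/last value outside the span).
series_fun <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  v <- x$values; t0 <- x$t0; dt <- x$dt; n <- length(v)
  function(t) {
    i <- floor((t - t0) / dt) + 1
    v[pmin(pmax(i, 1), n)]
  }
}

# Continuous (linear-interpolation) lookup, for signals that are samples of
# a continuous process (meal appearance, exercise intensity) rather than
# piecewise-constant pump rates.
series_fun_lin <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  if (length(x$values) == 1L) return(function(t) rep(x$values, length(t)))
  approxfun(series_times(x), x$values, method = "linear", rule = 2)
}

# Rasterize piecewise-constant rate segments onto a grid by exact cell
# averaging: each cell receives (mass delivered inside the cell) / dt, so the
# integral over the grid equals the integral of the segments regardless of
# alignment.  `seg` is a data.frame with columns a, b, rate (half-open [a,b)).
rasterize_segments <- function(seg, grid) {
  stopifnot(inherits(grid, "uniform_series"))
  out <- numeric(length(grid$values))
  if (is.null(seg) || nrow(seg) == 0L) {
    return(uniform_series(out, grid$t0, grid$dt, unit = "mU/min"))
  }
  t0 <- grid$t0; dt <- grid$dt; n <- length(out)
  for (k in seq_len(nrow(seg))) {
    a <- seg$a[k]; b <- seg$b[k]; r <- seg$rate[k]
    if (b <= a || r == 0) next
    i0 <- max(1L, floor((a - t0) / dt) + 1L)
    i1 <- min(n, ceiling((b - t0) / dt - 1e-12))
    if (i1 < i0) next
    idx <- i0:i1
    lo <- t0 + (idx - 1L) * dt
    hi <- lo + dt
    overlap <- pmin(hi, b) - pmax(lo, a)
    out[idx] <- out[idx] + r * overlap / dt
  }
  uniform_series(out, t0, dt, unit = "mU/min")
}

# Centered rolling mean with edge shrinkage (window truncated at the ends so
# the output has the same length and no NA).
roll_mean <- function(v, window) {
  if (is.null(window) || window <= 1L) return(v)
  n <- length(v)
  half <- floor(window / 2)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
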