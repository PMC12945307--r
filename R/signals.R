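#' Rasterize a single bolus event to an infusion-rate series
#'
#' A pump bolus of total dose `x` mU is released into the bloodstream
#' according to its pump mode:
#'
#' * `normal`: released at rate `x / 10` over ten minutes from `t_start`
#'   (ten minutes approximates the release time of a standard bolus);
#' * `square`: released at the constant rate `x / (t_end - t_start)` over
#'   `[t_start, t_end)`;
#' * `normal_dual` / `square_dual`: the dose is split 50/50 and the halves
#'   are released sequentially over the two half-intervals, with the
#'   first-named mode first.
#'
#' For dual modes the "normal" half is, by default, released at its nominal
#' ten-minute profile from the start of its half-interval — truncated and
#' rescaled to `min(10, half-interval)` minutes so that each half integrates
#' exactly to `x / 2` (total delivered insulin must equal the logged dose).
#' `strict = TRUE` instead spreads the nominal rate `0.5 x / 10` over the
#' whole half-interval, reproducing the release formula literally at the
#' cost of dose conservation when the half-interval differs from 10 min.
#'
#' Rasterization is by exact cell averaging, so the time-integral of the
#' returned series equals the delivered dose irrespective of grid alignment.
#'
#' @param rec a single-row bolus event (see [event_records()]).
#' @param grid a [uniform_series()] template (e.g. from [time_grid()]).
#' @param strict logical; reproduce the literal dual-mode release profile
#'   (see Details).
#' @return A `uniform_series` of the bolus rate contribution (mU/min).
#' @export
bolus_to_rate <- function(rec, grid, strict = FALSE) {
  rec <- as.list(rec)
  if (!identical(rec$kind, "bolus")) stop("`rec` must be a bolus event",
                                          call. = FALSE)
  x <- rec$value
  if (is.na(x) || x < 0) stop("negative or missing bolus dose", call. = FALSE)
  t0 <- rec$t_start
  mode <- rec$mode
  if (x == 0) {
    return(uniform_series(numeric(length(grid$values)), grid$t0, grid$dt,
                          unit = "mU/min"))
  }
  seg <- switch(
    mode,
    normal = data.frame(a = t0, b = t0 + 10, rate = x / 10),
    square = {
      t1 <- rec$t_end
      if (is.na(t1) || t1 <= t0) stop("square bolus needs t_end > t_start",
                                      call. = FALSE)
      data.frame(a = t0, b = t1, rate = x / (t1 - t0))
    },
    normal_dual = ,
    square_dual = {
      t1 <- rec$t_end
      if (is.na(t1) || t1 <= t0) stop("dual bolus needs t_end > t_start",
                                      call. = FALSE)
      mid <- (t0 + t1) / 2
      half <- x / 2
      seg_normal <- function(a, b) {
        if (strict) {
          data.frame(a = a, b = b, rate = half / 10)
        } else {
          d <- min(10, b - a)
          data.frame(a = a, b = a + d, rate = half / d)
        }
      }
      seg_square <- function(a, b) data.frame(a = a, b = b,
                                              rate = half / (b - a))
      if (mode == "normal_dual") {
        rbind(seg_normal(t0, mid), seg_square(mid, t1))
      } else {
        rbind(seg_square(t0, mid), seg_normal(mid, t1))
      }
    },
    stop("unknown bolus mode: ", mode, call. = FALSE)
  )
  rasterize_segments(seg, grid)
}

#' Total insulin infusion rate from pump events
#'
#' Combines basal segments, temp-basal overrides and boluses into the forcing
#' signal `u1(t)`:
#' \deqn{u_1(t) = u_{1,basal}(t) + (1 - \mathbf{1}_{temp}(t))\,u_{1,bolus}(t)
#'   + \mathbf{1}_{temp}(t)\,u_{1,temp}(t),}
#' i.e. the programmed basal rate always runs; while a temp-basal window is
#' active its rate replaces any concurrent bolus contribution.  The temp-basal
#' indicator is evaluated at each grid cell's left edge (half-open cell
#' convention).
#'
#' @param basal basal rate events (`t_start`, `t_end`, rate in `value`);
#'   segments must not overlap.
#' @param temp_basal temp-basal events (may be empty); windows must not
#'   overlap each other.
#' @param boluses bolus events (may be empty).
#' @param grid a [uniform_series()] template.
#' @param strict passed to [bolus_to_rate()].
#' @return A `uniform_series` `u1` in mU/min, non-negative everywhere.
#' @export
total_insulin_rate <- function(basal, temp_basal = NULL, boluses = NULL,
                               grid, strict = FALSE) {
  n <- length(grid$values)
  tt <- series_times(grid)

  basal_rate <- numeric(n)
  if (!is.null(basal) && nrow(basal) > 0L) {
    b <- basal[order(basal$t_start), , drop = FALSE]
    if (any(is.na(b$t_end))) stop("basal segments need t_end", call. = FALSE)
    if (nrow(b) > 1L && any(b$t_start[-1L] < b$t_end[-nrow(b)] - 1e-9)) {
      stop("overlapping basal segments", call. = FALSE)
    }
    basal_rate <- rasterize_segments(
      data.frame(a = b$t_start, b = b$t_end, rate = b$value), grid)$values
  }

  bolus_rate <- numeric(n)
  if (!is.null(boluses) && nrow(boluses) > 0L) {
    for (k in seq_len(nrow(boluses))) {
      bolus_rate <- bolus_rate +
        bolus_to_rate(boluses[k, , drop = FALSE], grid, strict = strict)$values
    }
  }

  temp_rate <- numeric(n)
  in_temp <- rep(FALSE, n)
  if (!is.null(temp_basal) && nrow(temp_basal) > 0L) {
    tb <- temp_basal[order(temp_basal$t_start), , drop = FALSE]
    if (any(is.na(tb$t_end))) stop("temp-basal events need t_end",
                                   call. = FALSE)
    if (nrow(tb) > 1L && any(tb$t_start[-1L] < tb$t_end[-nrow(tb)] - 1e-9)) {
      stop("overlapping temp-basal windows (undefined override order)",
           call. = FALSE)
    }
    for (k in seq_len(nrow(tb))) {
      idx <- tt >= tb$t_start[k] & tt < tb$t_end[k]
      in_temp[idx] <- TRUE
      temp_rate[idx] <- tb$value[k]
    }
  }

  u1 <- basal_rate + ifelse(in_temp, temp_rate, bolus_rate)
  uniform_series(pmax(u1, 0), grid$t0, grid$dt, unit = "mU/min")
}

#' Meal glucose appearance rate
#'
#' Converts logged carbohydrate intakes to the glucose appearance signal
#' \deqn{u_2(t) = 0.0083 \sum_j m_j \exp(0.0083\,(t_j - t)), \quad t \ge t_j,}
#' where meal `j` delivers `m_j` grams at time `t_j`.  Each meal's kernel
#' integrates to `m_j`, so mass is conserved over a long horizon.  The decay
#' constant 0.0083/min (about a two-hour absorption time constant) is exposed
#' as an argument for sensitivity analyses.
#'
#' @param meals meal events (grams of carbohydrate in `value`).
#' @param grid a [uniform_series()] template.
#' @param decay exponential absorption rate in 1/min.
#' @return A `uniform_series` `u2` in g/min.
#' @export
meals_to_u2 <- function(meals, grid, decay = 0.0083) {
  tt <- series_times(grid)
  u2 <- numeric(length(tt))
  if (!is.null(meals) && nrow(meals) > 0L) {
    if (any(meals$value < 0)) stop("negative carbohydrate mass",
                                   call. = FALSE)
    for (k in seq_len(nrow(meals))) {
      tj <- meals$t_start[k]; mj <- meals$value[k]
      on <- tt >= tj
      u2[on] <- u2[on] + decay * mj * exp(decay * (tj - tt[on]))
    }
  }
  uniform_series(u2, grid$t0, grid$dt, unit = "g/min")
}

#' Exercise intensity from heart rate
#'
#' Maps heart rate to the percentage of maximal oxygen uptake by the
#' empirical linear relation `PVO2max = 0.888 HR - 71.91`, and to the
#' above-basal exercise intensity `u3 = max(PVO2max - 8, 0)`, where 8 is the
#' average PVO2max of a person at rest.
#'
#' @param hr heart rate as a [uniform_series()] (bpm, imputed, no gaps).
#' @return A list with `pvo2max` and `u3` uniform series on the same grid.
#' @export
heart_rate_to_u3 <- function(hr) {
  stopifnot(inherits(hr, "uniform_series"))
  pv <- 0.888 * hr$values - 71.91
  u3 <- pmax(pv - 8, 0)
  list(pvo2max = uniform_series(pv, hr$t0, hr$dt, unit = "PVO2max"),
       u3 = uniform_series(u3, hr$t0, hr$dt, unit = "PVO2max"))
}

#' Align several signals onto a common uniform grid
#'
#' Takes a named list of signals — each either a [uniform_series()] or an
#' irregular sample table `data.frame(t, value)` — and returns them linearly
#' interpolated onto one shared grid: the common span is
#' `[max(start times), min(end times)]` and the spacing is `target_dt`.
#' Optional centered rolling-mean smoothing can be applied per channel.
#'
#' Interior gaps are filled by linear interpolation between the adjacent
#' available samples.  For channels listed in `flag_gaps`, output samples
#' whose bracketing observations are further apart than `gap_threshold`
#' minutes are additionally flagged in a logical `gap` attribute rather than
#' silently trusted — downstream fitting can then exclude those spans instead
#' of fitting invented values.
#'
#' @param signals named list of `uniform_series` or `data.frame(t, value)`.
#' @param target_dt output grid spacing in minutes.
#' @param smooth_window odd integer width (in samples) of a centered
#'   rolling-mean; `NULL` for none.  (A 30-point window is the conventional
#'   choice when smoothing model inputs.)
#' @param flag_gaps character vector of channel names to gap-flag.
#' @param gap_threshold minutes; observation gaps longer than this are
#'   flagged instead of interpolated-and-trusted.
#' @return Named list of aligned `uniform_series` (with `gap` attributes
#'   where requested).
#' @export
impute_and_align <- function(signals, target_dt = 5, smooth_window = NULL,
                             flag_gaps = "cgm", gap_threshold = 60) {
  stopifnot(is.list(signals), length(signals) >= 1L)
  as_tv <- function(x) {
    if (inherits(x, "uniform_series")) {
      data.frame(t = series_times(x), value = x$values)
    } else {
      stopifnot(is.data.frame(x), all(c("t", "value") %in% names(x)))
      x <- x[order(x$t), c("t", "value")]
      x[!is.na(x$value), , drop = FALSE]
    }
  }
  tv <- lapply(signals, as_tv)
  if (any(vapply(tv, nrow, 1L) < 1L)) stop("each signal needs >= 1 sample",
                                           call. = FALSE)
  t0 <- max(vapply(tv, function(d) d$t[1L], 1))
  t1 <- min(vapply(tv, function(d) d$t[nrow(d)], 1))
  if (t1 <= t0) stop("signals have no common time span", call. = FALSE)
  tt <- seq(t0, t1, by = target_dt)

  out <- lapply(names(tv), function(nm) {
    d <- tv[[nm]]
    v <- if (nrow(d) == 1L) rep(d$value, length(tt)) else {
      approx(d$t, d$value, xout = tt, method = "linear", rule = 2)$y
    }
    v <- roll_mean(v, smooth_window)
    s <- uniform_series(v, t0 = t0, dt = target_dt, unit = "")
    if (nm %in% flag_gaps && nrow(d) > 1L) {
      # width of the observation interval bracketing each output sample
      idx <- findInterval(tt, d$t, rightmost.closed = TRUE)
      idx <- pmin(pmax(idx, 1L), nrow(d) - 1L)
      width <- d$t[idx + 1L] - d$t[idx]
      attr(s, "gap") <- width > gap_threshold
    }
    s
  })
  names(out) <- names(tv)
  out
}
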