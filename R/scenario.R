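#' Default configuration blocks for the synthetic scenario generator
#'
#' The generator emulates the structure of pump/sensor records from a person
#' with type 1 diabetes on sensor-augmented pump therapy: 2-4 sparse meals a
#' day with lognormal carbohydrate mass, a mode-labelled bolus at each meal,
#' a piecewise-constant basal rate, 0-1 episodic exercise bouts per day
#' raising heart rate to a plateau, and CGM sampling with optional noise and
#' gaps.
#'
#' @param meals_per_day integer range (min, max) of meals per day.
#' @param carb_meanlog,carb_sdlog lognormal parameters of the carbohydrate
#'   mass in grams (default centred on 50 g).
#' @param carb_range truncation bounds for the meal mass (g).
#' @param carb_ratio insulin-to-carbohydrate ratio in g per insulin unit used
#'   for bolus sizing.
#' @param dose_fraction fraction of the nominally required bolus actually
#'   delivered (1 = adequate dosing; 0.5 emulates systematic underdosing).
#' @param mode_probs probabilities of the four bolus modes
#'   (normal, square, normal_dual, square_dual).
#' @param square_minutes duration range of square-family boluses (min).
#' @param basal_step_hours hours between piecewise-constant basal segments.
#' @param basal_jitter relative amplitude of basal-rate steps around `u1b`.
#' @param exercise_prob probability of one exercise bout on a given day.
#' @param exercise_minutes bout duration range (min).
#' @param exercise_hr plateau heart-rate range (bpm).
#' @param rest_hr resting heart rate (bpm).
#' @param hr_noise_sd bpm noise on the heart-rate samples.
#' @param cgm_noise_sd mg/dl noise added to the CGM channel.
#' @param cgm_gap_per_day expected number of CGM gaps per day.
#' @param cgm_gap_minutes gap duration range (min).
#' @return A named list of generator settings.
#' @export
scenario_config <- function(meals_per_day = c(2L, 4L),
                            carb_meanlog = log(50), carb_sdlog = 0.35,
                            carb_range = c(15, 150),
                            carb_ratio = 10, dose_fraction = 1,
                            mode_probs = c(normal = 0.7, square = 0.1,
                                           normal_dual = 0.1,
                                           square_dual = 0.1),
                            square_minutes = c(30, 60),
                            basal_step_hours = 8, basal_jitter = 0.1,
                            exercise_prob = 0.5,
                            exercise_minutes = c(30, 60),
                            exercise_hr = c(110, 140), rest_hr = 70,
                            hr_noise_sd = 1.5,
                            cgm_noise_sd = 0, cgm_gap_per_day = 0.25,
                            cgm_gap_minutes = c(20, 90)) {
  cfg <- as.list(environment())
  if (cfg$carb_meanlog <= 0 || any(cfg$carb_range <= 0) ||
      cfg$dose_fraction < 0 || cfg$carb_ratio <= 0) {
    stop("infeasible scenario configuration", call. = FALSE)
  }
  stopifnot(abs(sum(cfg$mode_probs) - 1) < 1e-9)
  cfg
}

#' Generate a reproducible synthetic patient scenario
#'
#' Draws a random daily schedule of meals, boluses, basal segments and
#' exercise bouts (see [scenario_config()]), and rasterizes it into the three
#' forcing signals `u1`, `u2`, `u3` on a regular grid.  All randomness flows
#' from `seed`; the same seed always yields the identical scenario.
#'
#' Meal windows follow common habits (breakfast 06:30-09:00, lunch
#' 11:30-14:00, dinner 17:30-20:30, optional afternoon snack); each meal is
#' covered by a bolus sized as `grams / carb_ratio` insulin units (1000 mU
#' per unit) scaled by `dose_fraction`.
#'
#' @param seed integer seed.
#' @param duration_days number of simulated days.
#' @param params a [patient_params()] supplying the basal rate `u1b`.
#' @param cfg a [scenario_config()].
#' @param dt grid spacing of the rasterized forcings (min).
#' @return A list with `events` (the raw [event_records()]), `forcing`
#'   (a [forcing_set()]), `hr` (heart-rate `uniform_series`), `grid`, `cfg`
#'   and `seed`.
#' @export
make_scenario <- function(seed, duration_days = 7, params = patient_params(),
                          cfg = scenario_config(), dt = 5) {
  stopifnot(duration_days >= 1)
  withr_seed <- function(code) { # local RNG scope, reproducible
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    t_end <- duration_days * 1440
    grid <- time_grid(0, t_end, dt = dt)

    meal_windows <- list(c(6.5, 9), c(11.5, 14), c(17.5, 20.5), c(15, 16.5))
    meals <- list(); boluses <- list()
    for (d in seq_len(duration_days)) {
      n_meal <- sample(seq(cfg$meals_per_day[1], cfg$meals_per_day[2]), 1L)
      for (j in seq_len(n_meal)) {
        w <- meal_windows[[j]]
        tj <- (d - 1) * 1440 + 60 * runif(1, w[1], w[2])
        mj <- min(max(rlnorm(1, cfg$carb_meanlog, cfg$carb_sdlog),
                      cfg$carb_range[1]), cfg$carb_range[2])
        meals[[length(meals) + 1L]] <-
          data.frame(kind = "meal", t_start = tj, t_end = NA_real_,
                     value = mj, mode = NA_character_)
        dose <- mj / cfg$carb_ratio * 1000 * cfg$dose_fraction
        mode <- sample(names(cfg$mode_probs), 1L, prob = cfg$mode_probs)
        tend <- if (mode == "normal") NA_real_ else
          tj + runif(1, cfg$square_minutes[1], cfg$square_minutes[2])
        boluses[[length(boluses) + 1L]] <-
          data.frame(kind = "bolus", t_start = tj, t_end = tend,
                     value = dose, mode = mode)
      }
    }
    meals <- do.call(rbind, meals)
    boluses <- do.call(rbind, boluses)

    step_min <- cfg$basal_step_hours * 60
    starts <- seq(0, t_end - 1e-9, by = step_min)
    basal <- data.frame(kind = "basal", t_start = starts,
                        t_end = pmin(starts + step_min, t_end),
                        value = params$u1b *
                          (1 + runif(length(starts), -cfg$basal_jitter,
                                     cfg$basal_jitter)),
                        mode = NA_character_)

    tt <- series_times(grid)
    hr <- rep(cfg$rest_hr, length(tt))
    bouts <- list()
    for (d in seq_len(duration_days)) {
      if (runif(1) < cfg$exercise_prob) {
        start <- (d - 1) * 1440 + 60 * runif(1, 16, 19)
        dur <- runif(1, cfg$exercise_minutes[1], cfg$exercise_minutes[2])
        peak <- runif(1, cfg$exercise_hr[1], cfg$exercise_hr[2])
        ramp <- 5
        rel <- tt - start
        up <- rel >= 0 & rel < ramp
        hold <- rel >= ramp & rel < dur - ramp
        down <- rel >= dur - ramp & rel < dur
        hr[up] <- pmax(hr[up], cfg$rest_hr + (peak - cfg$rest_hr) *
                         rel[up] / ramp)
        hr[hold] <- peak
        hr[down] <- pmax(hr[down], cfg$rest_hr + (peak - cfg$rest_hr) *
                           (dur - rel[down]) / ramp)
        bouts[[length(bouts) + 1L]] <- c(start = start, duration = dur,
                                         peak_hr = peak)
      }
    }
    hr <- pmax(hr + rnorm(length(hr), 0, cfg$hr_noise_sd), 40)
    hr_series <- uniform_series(hr, grid$t0, grid$dt, unit = "bpm")

    events <- validate_events(rbind(basal, boluses, meals,
                                    data.frame(kind = "heart_rate",
                                               t_start = tt,
                                               t_end = NA_real_, value = hr,
                                               mode = NA_character_)))
    u1 <- total_insulin_rate(basal = events_of_kind(events, "basal"),
                             temp_basal = NULL,
                             boluses = events_of_kind(events, "bolus"),
                             grid = grid)
    u2 <- meals_to_u2(events_of_kind(events, "meal"), grid)
    u3 <- heart_rate_to_u3(hr_series)$u3
    list(events = events, forcing = forcing_set(u1, u2, u3),
         hr = hr_series, grid = grid, cfg = cfg, seed = seed,
         n_exercise_bouts = length(bouts))
  })
}

#' Simulate CGM data for a synthetic scenario
#'
#' Runs the digital twin over a scenario's forcings and returns the aligned
#' `(t, u1, u2, u3, G)` table plus a CGM channel with optional sensor noise
#' and sampling gaps (points dropped), for use as SBINN training data or as
#' the source of an offline replay buffer.
#'
#' @param scenario output of [make_scenario()].
#' @param params the [patient_params()] used as ground truth.
#' @param noise_seed seed for CGM noise/gaps (defaults to `scenario$seed + 1`).
#' @param ... passed to [twin_simulate()].
#' @return A list with `table` (data.frame `t, u1, u2, u3, G`), `cgm`
#'   (data.frame `t, value` with gaps/noise applied), and `trajectory`
#'   (the full state trajectory).
#' @export
simulate_patient <- function(scenario, params, noise_seed = NULL, ...) {
  traj <- twin_simulate(params, scenario$forcing, ...)
  grid_n <- length(scenario$grid$values)
  traj <- traj[seq_len(grid_n), , drop = FALSE]
  tab <- data.frame(t = traj$t_min, u1 = traj$u1, u2 = traj$u2,
                    u3 = traj$u3, G = traj$G)
  cfg <- scenario$cfg
  if (is.null(noise_seed)) noise_seed <- scenario$seed + 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise_seed)
  g <- tab$G + rnorm(nrow(tab), 0, cfg$cgm_noise_sd)
  keep <- rep(TRUE, nrow(tab))
  n_gaps <- stats::rpois(1, cfg$cgm_gap_per_day * max(tab$t) / 1440)
  if (n_gaps > 0) {
    for (k in seq_len(n_gaps)) {
      gap_start <- runif(1, 0, max(tab$t))
      gap_len <- runif(1, cfg$cgm_gap_minutes[1], cfg$cgm_gap_minutes[2])
      keep[tab$t >= gap_start & tab$t < gap_start + gap_len] <- FALSE
    }
    keep[c(1L, length(keep))] <- TRUE   # preserve the span
  }
  list(table = tab,
       cgm = data.frame(t = tab$t[keep], value = g[keep]),
       trajectory = traj)
}

#' Coarse-grain an aligned table to the reinforcement-learning time step
#'
#' Averages the forcing channels and subsamples glucose onto a coarser grid
#' (1 h by default), the decision interval of the dosing agent.
#'
#' @param tab data.frame `t, u1, u2, u3, G` on a fine regular grid.
#' @param dt_coarse coarse spacing in minutes.
#' @return A data.frame with the same columns on the coarse grid.
#' @export
coarse_grain <- function(tab, dt_coarse = 60) {
  dt_fine <- tab$t[2L] - tab$t[1L]
  k <- round(dt_coarse / dt_fine)
  stopifnot(k >= 1)
  n <- floor(nrow(tab) / k)
  idx <- (seq_len(n) - 1L) * k + 1L
  agg <- function(v) {
    m <- matrix(v[seq_len(n * k)], nrow = k)
    colMeans(m)
  }
  data.frame(t = tab$t[idx], u1 = agg(tab$u1), u2 = agg(tab$u2),
             u3 = agg(tab$u3), G = tab$G[idx])
}
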