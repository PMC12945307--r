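#' Read pump/sensor events from an OhioT1DM-style XML file
#'
#' Parses the element vocabulary of the OhioT1DM records — `glucose_level`,
#' `basal`, `temp_basal`, `bolus` (with `ts_begin`, `ts_end`, `type`,
#' `dose`), `meal` (with `carbs`) and `basis_heart_rate` — into
#' [event_records()].  Timestamps are parsed with a configurable format
#' (default `"%d-%m-%Y %H:%M:%S"`) and converted to minutes since the
#' earliest timestamp in the file; the absolute dates carry no calendar
#' semantics (they are shifted for privacy in the source data).  Unknown
#' elements are skipped with a warning; records with malformed timestamps
#' are dropped and summarized in a warning.
#'
#' Bolus doses are given in insulin units in the source records and are
#' converted to mU (`* 1000`).  Basal/temp-basal rates (units/hr) are
#' converted to mU/min (`* 1000 / 60`).  Basal rate-change events become
#' segments ending at the next change.
#'
#' @param path XML file path.
#' @param ts_format timestamp format string.
#' @return A list with `events` (an [event_records()] data.frame) and
#'   `epoch` (the earliest timestamp string found).
#' @export
read_ohio_xml <- function(path, ts_format = "%d-%m-%Y %H:%M:%S") {
  doc <- xml2::read_xml(path)
  known <- c("glucose_level", "basal", "temp_basal", "bolus", "meal",
             "basis_heart_rate")
  kids <- xml2::xml_children(doc)
  extra <- setdiff(unique(xml2::xml_name(kids)), known)
  if (length(extra)) {
    warning("skipping unknown element(s): ", paste(extra, collapse = ", "))
  }
  parse_ts <- function(s) as.POSIXct(s, format = ts_format, tz = "UTC")

  events <- list()
  n_bad <- 0L
  grab <- function(section, fn) {
    nodes <- xml2::xml_find_all(doc, paste0("./", section, "/event"))
    for (nd in nodes) {
      rec <- tryCatch(fn(nd), error = function(e) NULL)
      if (is.null(rec) || is.na(rec$ts) || !nzchar(rec$ts) ||
          is.na(rec$value)) {
        n_bad <<- n_bad + 1L
      } else {
        events[[length(events) + 1L]] <<- rec
      }
    }
  }
  att <- xml2::xml_attr
  grab("glucose_level", function(nd) {
    data.frame(kind = "cgm", ts = att(nd, "ts"), t_start = NA_real_,
               t_end = NA_real_, value = as.numeric(att(nd, "value")),
               mode = NA_character_)
  })
  grab("basal", function(nd) {
    data.frame(kind = "basal", ts = att(nd, "ts"), t_start = NA_real_,
               t_end = NA_real_,
               value = as.numeric(att(nd, "value")) * 1000 / 60,
               mode = NA_character_)
  })
  grab("temp_basal", function(nd) {
    data.frame(kind = "temp_basal", ts = att(nd, "ts_begin"),
               ts_end = att(nd, "ts_end"), t_start = NA_real_,
               t_end = NA_real_,
               value = as.numeric(att(nd, "value")) * 1000 / 60,
               mode = NA_character_)
  })
  grab("bolus", function(nd) {
    mode <- gsub(" ", "_", att(nd, "type"))
    data.frame(kind = "bolus", ts = att(nd, "ts_begin"),
               ts_end = att(nd, "ts_end"), t_start = NA_real_,
               t_end = NA_real_,
               value = as.numeric(att(nd, "dose")) * 1000, mode = mode)
  })
  grab("meal", function(nd) {
    data.frame(kind = "meal", ts = att(nd, "ts"), t_start = NA_real_,
               t_end = NA_real_, value = as.numeric(att(nd, "carbs")),
               mode = NA_character_)
  })
  grab("basis_heart_rate", function(nd) {
    data.frame(kind = "heart_rate", ts = att(nd, "ts"), t_start = NA_real_,
               t_end = NA_real_, value = as.numeric(att(nd, "value")),
               mode = NA_character_)
  })
  if (n_bad > 0L) warning(n_bad, " record(s) dropped (malformed)")
  if (!length(events)) {
    return(list(events = event_records(character(0), numeric(0), numeric(0)),
                epoch = NA_character_))
  }
  df <- do.call(rbind, lapply(events, function(e) {
    if (is.null(e$ts_end)) e$ts_end <- NA_character_
    e[c("kind", "ts", "ts_end", "t_start", "t_end", "value", "mode")]
  }))
  t_abs <- parse_ts(df$ts)
  bad_ts <- is.na(t_abs)
  if (any(bad_ts)) {
    warning(sum(bad_ts), " record(s) dropped (unparseable timestamp)")
    df <- df[!bad_ts, , drop = FALSE]; t_abs <- t_abs[!bad_ts]
  }
  epoch <- min(t_abs)
  df$t_start <- as.numeric(difftime(t_abs, epoch, units = "mins"))
  has_end <- !is.na(df$ts_end)
  df$t_end[has_end] <- as.numeric(difftime(parse_ts(df$ts_end[has_end]),
                                           epoch, units = "mins"))
  # basal rate changes -> segments ending at the next change
  ib <- which(df$kind == "basal")
  if (length(ib) > 1L) {
    ord <- ib[order(df$t_start[ib])]
    df$t_end[ord] <- c(df$t_start[ord][-1L],
                       max(df$t_start, df$t_end, na.rm = TRUE))
  } else if (length(ib) == 1L) {
    df$t_end[ib] <- max(df$t_start, df$t_end, na.rm = TRUE)
  }
  # square-family boluses missing an end time: treat as normal-mode
  sq <- df$kind == "bolus" & df$mode != "normal" &
    (is.na(df$t_end) | df$t_end <= df$t_start)
  if (any(sq)) df$t_end[sq] <- df$t_start[sq] + 30
  out <- validate_events(df[c("kind", "t_start", "t_end", "value", "mode")])
  list(events = out, epoch = format(epoch, "%d-%m-%Y %H:%M:%S"))
}

#' Preprocess raw events into the aligned forcing table
#'
#' Full preprocessing chain: rasterize insulin events to `u1`, meals to
#' `u2`, heart rate to `u3` (via PVO2max), align all channels and the CGM
#' onto one grid, and return the `(t, u1, u2, u3, G)` table.
#'
#' @param events an [event_records()] data.frame (kinds `basal`,
#'   `temp_basal`, `bolus`, `meal`, `heart_rate`, `cgm`).
#' @param dt output grid spacing (minutes).
#' @param smooth_window optional rolling-mean width for the model inputs.
#' @param gap_threshold CGM gap flagging threshold (minutes).
#' @param strict passed to [bolus_to_rate()].
#' @return A list with `table` (data.frame), `forcing` (a [forcing_set()]),
#'   `cgm` (a gap-flagged [uniform_series()]).
#' @export
preprocess_events <- function(events, dt = 5, smooth_window = NULL,
                              gap_threshold = 60, strict = FALSE) {
  cgm <- events_of_kind(events, "cgm")
  hr <- events_of_kind(events, "heart_rate")
  if (nrow(cgm) == 0L) stop("no CGM events", call. = FALSE)
  if (nrow(hr) == 0L) {
    hr <- data.frame(kind = "heart_rate", t_start = range(cgm$t_start),
                     t_end = NA_real_, value = 70, mode = NA_character_)
  }
  aligned <- impute_and_align(
    list(cgm = data.frame(t = cgm$t_start, value = cgm$value),
         hr = data.frame(t = hr$t_start, value = hr$value)),
    target_dt = dt, flag_gaps = "cgm", gap_threshold = gap_threshold)
  grid <- aligned$cgm
  u1 <- total_insulin_rate(events_of_kind(events, "basal"),
                           events_of_kind(events, "temp_basal"),
                           events_of_kind(events, "bolus"),
                           grid = grid, strict = strict)
  u2 <- meals_to_u2(events_of_kind(events, "meal"), grid)
  hru <- aligned$hr
  if (!is.null(smooth_window) && smooth_window > 1L) {
    sm <- function(s) uniform_series(roll_mean(s$values, smooth_window),
                                     s$t0, s$dt, s$unit)
    u1 <- sm(u1); u2 <- sm(u2); hru <- sm(hru)
  }
  u3 <- heart_rate_to_u3(hru)$u3
  list(table = data.frame(t = series_times(grid), u1 = u1$values,
                          u2 = u2$values, u3 = u3$values,
                          G = grid$values),
       forcing = forcing_set(u1, u2, u3),
       cgm = grid)
}

#' Write / read an aligned forcing table as CSV
#'
#' Full-precision plain-text round trip of the `(t, u1, u2, u3, G)` table.
#'
#' @param tab the table.
#' @param path CSV path.
#' @return `path` / the table.
#' @export
write_aligned_csv <- function(tab, path) {
  out <- tab
  out[] <- lapply(out, function(v) sprintf("%.17g", v))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_aligned_csv
#' @export
read_aligned_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  df[] <- lapply(df, as.numeric)
  df
}

# Deterministic digest of any R object (used in run manifests).
obj_hash <- function(x) rlang::hash(x)

#' Run the full pipeline on a synthetic patient
#'
#' Wires every stage end to end: synthetic scenario -> twin simulation ->
#' aligned table -> SBINN parameter inference -> replay buffer -> two
#' offline agents (TD3+BC, BCQ) -> closed-loop evaluation and a
#' [glycemic_report()] comparing behavior against both agents.  Every source
#' of randomness derives from `seed`, and the returned manifest contains
#' digests of each artifact, so identical seeds yield identical manifests.
#'
#' @param seed master seed.
#' @param duration_days length of the synthetic record.
#' @param params ground-truth [patient_params()].
#' @param scenario_cfg a [scenario_config()].
#' @param sbinn_cfg an [sbinn_config()]; `NULL` skips inference and uses the
#'   ground-truth parameters for the evaluation twin.
#' @param rl_hyper shared hyperparameter overrides for both agents (notably
#'   `iters`).
#' @param reward_cfg a [reward_config()].
#' @param episode_steps steps per evaluation episode.
#' @param out_dir optional directory for artifact files (aligned table,
#'   buffer, report JSON).
#' @return A list with `manifest`, `table`, `model` (or `NULL`), `buffer`,
#'   `agents`, `evals`, `report`.
#' @export
end_to_end <- function(seed, duration_days = 3, params = patient_params(),
                       scenario_cfg = scenario_config(dose_fraction = 0.5),
                       sbinn_cfg = sbinn_config(n_outer = 2, maxit = 20),
                       rl_hyper = list(iters = 200L),
                       reward_cfg = reward_config(), episode_steps = 24L,
                       out_dir = NULL) {
  stage <- "scenario"
  res <- tryCatch({
    scenario <- make_scenario(seed, duration_days, params, scenario_cfg)
    sim <- simulate_patient(scenario, params)

    stage <- "sbinn"
    model <- NULL
    twin_params <- params
    if (!is.null(sbinn_cfg)) {
      sbinn_cfg$seed <- seed
      aligned <- impute_and_align(
        list(cgm = sim$cgm), target_dt = 5, flag_gaps = "cgm")
      model <- sbinn_train(aligned$cgm, scenario$forcing, W = params$W,
                           u1b = params$u1b, Gb = params$Gb, cfg = sbinn_cfg)
      twin_params <- model$params
    }

    stage <- "buffer"
    coarse <- coarse_grain(sim$table)
    buffer <- build_buffer(coarse, reward_cfg)

    stage <- "rl"
    env <- twin_env(twin_params, scenario$forcing, reward_cfg,
                    w = buffer$w, a_max = buffer$a_max,
                    episode_steps = episode_steps)
    agents <- list(
      td3bc = train_td3bc(buffer, rl_hyper, seed = seed, env = env,
                          eval_every = max(50L, rl_hyper$iters %/% 4L)),
      bcq = train_bcq(buffer, rl_hyper, seed = seed, env = env,
                      eval_every = max(50L, rl_hyper$iters %/% 4L)))

    stage <- "evaluate"
    behavior <- function(window, step) {
      i <- min(step, nrow(coarse)); coarse$u1[i]
    }
    evals <- list(
      behavior = evaluate_policy(behavior, env, seed = seed),
      td3bc = evaluate_policy(agents$td3bc, env, seed = seed),
      bcq = evaluate_policy(agents$bcq, env, seed = seed))

    stage <- "report"
    recon_G <- if (!is.null(model)) {
      sbinn_reconstruct(model, scenario$forcing)$G[seq_len(nrow(sim$table))]
    } else sim$table$G
    report <- list(
      reconstruction = glycemic_report(sim$table$G, recon_G),
      policies = lapply(evals, function(e)
        glycemic_report(e$trajectory$G, returns = e$returns)),
      tests = list(
        td3bc_vs_behavior = compare_returns(evals$td3bc$returns,
                                            evals$behavior$returns),
        bcq_vs_behavior = compare_returns(evals$bcq$returns,
                                          evals$behavior$returns)))
    list(scenario = scenario, sim = sim, model = model, buffer = buffer,
         agents = agents, evals = evals, report = report, coarse = coarse)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    seed = seed,
    duration_days = duration_days,
    config_hash = obj_hash(list(unclass(scenario_cfg),
                                if (!is.null(sbinn_cfg)) unclass(sbinn_cfg),
                                rl_hyper, unclass(reward_cfg))),
    artifacts = list(
      events = obj_hash(res$scenario$events),
      aligned_table = obj_hash(res$sim$table),
      inferred_params = if (!is.null(res$model))
        obj_hash(res$model$param_fn(series_times(res$scenario$grid))) else NA,
      buffer = obj_hash(res$buffer[c("states", "actions", "rewards",
                                     "next_states", "dones")]),
      td3bc = obj_hash(res$agents$td3bc[c("actor", "critic1", "critic2")]),
      bcq = obj_hash(res$agents$bcq[c("decoder", "perturb", "critic1",
                                      "critic2")]),
      returns = obj_hash(lapply(res$evals, `[[`, "returns"))
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_aligned_csv(res$sim$table, file.path(out_dir, "aligned.csv"))
    save_buffer(res$buffer, file.path(out_dir, "buffer"))
    jsonlite::write_json(
      list(manifest = manifest,
           report = rapply(res$report, unclass, how = "replace")),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  c(list(manifest = manifest), res)
}
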