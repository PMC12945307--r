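EVENT_KINDS <- c("basal", "temp_basal", "bolus", "meal", "heart_rate", "cgm")
BOLUS_MODES <- c("normal", "square", "normal_dual", "square_dual")

#' Create a table of pump/sensor event records
#'
#' Event records are the raw, irregular observations from an insulin pump, a
#' meal log, a fitness band and a CGM sensor.  They are stored as a plain
#' data frame with one row per event and columns `kind`, `t_start`, `t_end`,
#' `value`, `mode`:
#'
#' * `basal` / `temp_basal`: `value` is an infusion rate (mU/min) over
#'   `[t_start, t_end)`; basal segments must tile time without overlap,
#'   temp-basal windows override concurrent boluses while active.
#' * `bolus`: `value` is the total dose (mU); `mode` is one of
#'   `"normal"`, `"square"`, `"normal_dual"`, `"square_dual"`; square-family
#'   modes carry `t_end`.
#' * `meal`: `value` is grams of carbohydrate at `t_start`.
#' * `heart_rate`: `value` is bpm at `t_start`.
#' * `cgm`: `value` is glucose (mg/dl) at `t_start`.
#'
#' @param kind character vector of event kinds.
#' @param t_start,t_end event times in minutes (`t_end` is `NA` unless the
#'   event spans an interval).
#' @param value event value (units depend on `kind`).
#' @param mode bolus release mode, `NA` for non-bolus events.
#' @return A validated `data.frame` of event records.
#' @export
event_records <- function(kind, t_start, value, t_end = NA_real_,
                          mode = NA_character_) {
  if (length(kind) == 0L) {
    return(data.frame(kind = character(0), t_start = numeric(0),
                      t_end = numeric(0), value = numeric(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(kind = as.character(kind),
                   t_start = as.numeric(t_start),
                   t_end = as.numeric(t_end),
                   value = as.numeric(value),
                   mode = as.character(mode),
                   stringsAsFactors = FALSE)
  validate_events(df)
}

validate_events <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("kind", "t_start", "t_end", "value", "mode")
  miss <- setdiff(need, names(df))
  for (m in miss) df[[m]] <- if (m == "mode") NA_character_ else NA_real_
  df <- df[need]
  bad <- !df$kind %in% EVENT_KINDS
  if (any(bad)) stop("unknown event kind(s): ",
                     paste(unique(df$kind[bad]), collapse = ", "), call. = FALSE)
  if (any(df$value < 0, na.rm = TRUE)) {
    stop("event values must be non-negative", call. = FALSE)
  }
  has_end <- !is.na(df$t_end)
  if (any(has_end & df$t_end < df$t_start)) {
    stop("t_end must be >= t_start", call. = FALSE)
  }
  is_bolus <- df$kind == "bolus"
  if (any(is_bolus & (is.na(df$mode) | !df$mode %in% BOLUS_MODES))) {
    stop("bolus events need a mode in {", paste(BOLUS_MODES, collapse = ", "),
         "}", call. = FALSE)
  }
  if (any(!is_bolus & !is.na(df$mode))) {
    stop("`mode` is only meaningful for bolus events", call. = FALSE)
  }
  df
}

events_of_kind <- function(events, kind) {
  if (is.null(events) || nrow(events) == 0L) {
    return(events[0L, , drop = FALSE])
  }
  events[events$kind == kind, , drop = FALSE]
}
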