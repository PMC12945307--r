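KINETIC_PARAMS <- c("n", "VolG", "p1", "p2", "p3", "p4",
                    "a1", "a2", "a3", "a4", "a5", "a6")

#' Reference Roy-Parker parameter values
#'
#' Population reference values `xref` for the twelve kinetic parameters of
#' the modified Roy-Parker model, loaded from the versioned configuration
#' file shipped with the package.  Patient-specific parameters are
#' constrained to the box `[0.2 xref, 1.8 xref]`.
#'
#' @param path optional path to an alternative YAML reference file.
#' @return Named numeric vector of the twelve reference values.
#' @export
reference_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "roy_parker_reference.yaml",
                        package = "aptwin")
  }
  ref <- yaml::read_yaml(path)
  unlist(ref[KINETIC_PARAMS])
}

#' Patient parameter set for the digital twin
#'
#' Bundles the twelve kinetic parameters of the modified Roy-Parker model
#' (`n, VolG, p1..p4, a1..a6`; each a positive constant or a time-varying
#' [uniform_series()]/function of time) with the anthropometric and basal
#' constants: body weight `W` (kg), basal insulin infusion `u1b` (mU/min)
#' and basal glucose `Gb` (mg/dl).  The basal plasma insulin is defined by
#' consistency with the insulin balance at rest, `Ib = (p4 / n) u1b`
#' (evaluated at the start of the record when parameters vary in time).
#'
#' Constant or series-valued parameters are validated against the admissible
#' box `[0.2 xref, 1.8 xref]`.
#'
#' @param ... kinetic parameter overrides (constants, `uniform_series`, or
#'   functions of time in minutes); unspecified parameters default to `xref`.
#' @param W body weight in kg.
#' @param u1b basal insulin infusion rate in mU/min.
#' @param Gb basal glucose in mg/dl.
#' @param xref named vector of reference values (see [reference_params()]).
#' @param box lower/upper box multipliers on `xref`.
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(..., W = 60, u1b = 10, Gb = 120,
                           xref = reference_params(), box = c(0.2, 1.8)) {
  over <- list(...)
  bad <- setdiff(names(over), KINETIC_PARAMS)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stopifnot(W > 0, u1b > 0, Gb > 0, length(box) == 2L, box[1] > 0,
            box[1] < box[2])
  pars <- as.list(xref[KINETIC_PARAMS])
  for (nm in names(over)) pars[[nm]] <- over[[nm]]
  for (nm in KINETIC_PARAMS) {
    p <- pars[[nm]]
    lo <- box[1] * xref[[nm]]; hi <- box[2] * xref[[nm]]
    vals <- if (inherits(p, "uniform_series")) p$values
            else if (is.function(p)) NULL
            else as.numeric(p)
    if (!is.null(vals)) {
      if (any(!is.finite(vals)) || any(vals <= 0)) {
        stop(nm, " must be strictly positive", call. = FALSE)
      }
      if (any(vals < lo - 1e-12) || any(vals > hi + 1e-12)) {
        stop(nm, " outside the admissible box [",
             signif(lo, 4), ", ", signif(hi, 4), "]", call. = FALSE)
      }
    }
  }
  obj <- structure(
    list(kinetic = pars, W = W, u1b = u1b, Gb = Gb, xref = xref, box = box),
    class = "patient_params"
  )
  obj$Ib <- param_value(obj, "p4", t = NULL) / param_value(obj, "n", t = NULL) * u1b
  obj
}

# Evaluate a kinetic parameter; t = NULL means "at the start of the record"
# (first value of a series / f(0) of a function).
param_value <- function(params, name, t = NULL) {
  p <- params$kinetic[[name]]
  if (inherits(p, "uniform_series")) {
    if (is.null(t)) p$values[1L] else series_fun(p)(t)
  } else if (is.function(p)) {
    if (is.null(t)) p(0) else p(t)
  } else {
    if (is.null(t)) p else rep(p, length(t))
  }
}

# Build a fast lookup function for each kinetic parameter.
param_funs <- function(params) {
  lapply(setNames(KINETIC_PARAMS, KINETIC_PARAMS), function(nm) {
    p <- params$kinetic[[nm]]
    if (inherits(p, "uniform_series")) series_fun(p)
    else if (is.function(p)) p
    else local({ v <- p; function(t) rep(v, length(t)) })
  })
}

#' @export
print.patient_params <- function(x, ...) {
  cat("<patient_params>\n")
  for (nm in KINETIC_PARAMS) {
    p <- x$kinetic[[nm]]
    if (is.numeric(p) && length(p) == 1L) {
      cat(sprintf("  %-5s %.6g\n", nm, p))
    } else {
      cat(sprintf("  %-5s <time-varying>\n", nm))
    }
  }
  cat(sprintf("  W = %g kg, u1b = %g mU/min, Gb = %g mg/dl, Ib = %.4g uU/ml\n",
              x$W, x$u1b, x$Gb, x$Ib))
  invisible(x)
}

#' Serialize patient parameters to a plain-text table
#'
#' Writes the parameter set to a long-format CSV (`param, t, value`) at full
#' double precision so that a read back reproduces the values exactly.
#' Time-varying parameters get one row per sample; constants have `t = NA`.
#'
#' @param params a [patient_params()] object (functions must be sampled into
#'   a `uniform_series` before serialization).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(params, path) {
  rows <- list()
  for (nm in KINETIC_PARAMS) {
    p <- params$kinetic[[nm]]
    if (inherits(p, "uniform_series")) {
      rows[[nm]] <- data.frame(param = nm, t = series_times(p),
                               value = p$values, dt = p$dt)
    } else if (is.function(p)) {
      stop("sample function-valued parameters onto a uniform_series before ",
           "serialization", call. = FALSE)
    } else {
      rows[[nm]] <- data.frame(param = nm, t = NA_real_, value = p,
                               dt = NA_real_)
    }
  }
  for (nm in c("W", "u1b", "Gb")) {
    rows[[nm]] <- data.frame(param = nm, t = NA_real_, value = params[[nm]],
                             dt = NA_real_)
  }
  df <- do.call(rbind, rows)
  df$value <- sprintf("%.17g", df$value)
  df$t <- ifelse(is.na(df$t), "", sprintf("%.17g", df$t))
  df$dt <- ifelse(is.na(df$dt), "", sprintf("%.17g", df$dt))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a serialized parameter table
#'
#' @param path CSV written by [write_ground_truth()].
#' @param xref,box passed to [patient_params()].
#' @return A [patient_params()] object.
#' @export
read_ground_truth <- function(path, xref = reference_params(),
                              box = c(0.2, 1.8)) {
  df <- read.csv(path, colClasses = c("character", "character", "character",
                                      "character"))
  val <- as.numeric(df$value)
  tt <- suppressWarnings(as.numeric(df$t))
  dt <- suppressWarnings(as.numeric(df$dt))
  kin <- list()
  for (nm in KINETIC_PARAMS) {
    i <- which(df$param == nm)
    if (length(i) == 1L && is.na(tt[i[1L]])) {
      kin[[nm]] <- val[i]
    } else {
      kin[[nm]] <- uniform_series(val[i], t0 = tt[i[1L]], dt = dt[i[1L]])
    }
  }
  scal <- function(nm) val[df$param == nm][1L]
  do.call(patient_params,
          c(kin, list(W = scal("W"), u1b = scal("u1b"), Gb = scal("Gb"),
                      xref = xref, box = box)))
}
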