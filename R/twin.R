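TWIN_STATES <- c("I", "X", "G", "Gprod", "Gup", "Ie")

#' Bundle the three forcing signals of the twin
#'
#' @param u1 insulin infusion rate (mU/min) as a [uniform_series()].
#' @param u2 meal glucose appearance (g/min) on the same grid.
#' @param u3 above-basal exercise intensity (PVO2max units) on the same grid.
#' @return An object of class `forcing_set`.
#' @export
forcing_set <- function(u1, u2, u3) {
  for (s in list(u1, u2, u3)) stopifnot(inherits(s, "uniform_series"))
  same <- function(a, b) isTRUE(all.equal(c(a$t0, a$dt, length(a$values)),
                                          c(b$t0, b$dt, length(b$values))))
  if (!same(u1, u2) || !same(u1, u3)) {
    stop("u1, u2, u3 must share one grid", call. = FALSE)
  }
  if (min(u1$values) < 0 || min(u2$values) < 0 || min(u3$values) < 0) {
    stop("forcing signals must be non-negative", call. = FALSE)
  }
  structure(list(u1 = u1, u2 = u2, u3 = u3), class = "forcing_set")
}

#' Basal steady state of the twin
#'
#' @param params a [patient_params()] object.
#' @return Named state vector `(I, X, G, Gprod, Gup, Ie) = (Ib, 0, Gb, 0, 0, 0)`.
#' @export
basal_state <- function(params) {
  c(I = params$Ib, X = 0, G = params$Gb, Gprod = 0, Gup = 0, Ie = 0)
}

#' Time derivative of the modified Roy-Parker model
#'
#' The six-state glucose-insulin model with exercise:
#' \deqn{dI/dt = -n I + p_4 u_1 - I_e}
#' \deqn{dX/dt = -p_2 X + p_3 (I - I_b)}
#' \deqn{dG/dt = -p_1 (G - G_b) - X G + (W/Vol_G)(G_{prod} - G_{up}) + u_2/Vol_G}
#' \deqn{dG_{prod}/dt = a_1 E - a_2 G_{prod}}
#' \deqn{dG_{up}/dt  = a_3 E - a_4 G_{up}}
#' \deqn{dI_e/dt     = a_5 E - a_6 I_e}
#' where the exercise drive `E` is, by default, the above-basal intensity
#' `u3` so that rest is an exact fixed point of the exercise states; setting
#' `exercise_input = "absolute"` instead feeds the absolute PVO2max
#' (`u3 + 8`).  The term describing declining glycogenolysis under prolonged
#' exercise is deliberately absent: the model targets sporadic, light
#' activity.  `u2` is supplied in g/min and converted to mg/min internally.
#'
#' @param state named numeric vector `(I, X, G, Gprod, Gup, Ie)`.
#' @param t time in minutes.
#' @param params a [patient_params()].
#' @param forcing a [forcing_set()].
#' @param exercise_input `"above_basal"` (default) or `"absolute"`.
#' @return Named vector of the six time derivatives.
#' @export
twin_derivative <- function(state, t, params, forcing,
                            exercise_input = c("above_basal", "absolute")) {
  exercise_input <- match.arg(exercise_input)
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  pf <- param_funs(params)
  u1 <- series_fun(forcing$u1)(t)
  u2 <- series_fun_lin(forcing$u2)(t) * CARB_MG_PER_G
  u3 <- series_fun_lin(forcing$u3)(t)
  E <- if (exercise_input == "absolute") u3 + 8 else u3
  with(as.list(state), {
    n <- pf$n(t); p1 <- pf$p1(t); p2 <- pf$p2(t); p3 <- pf$p3(t)
    p4 <- pf$p4(t); VolG <- pf$VolG(t)
    c(I = -n * I + p4 * u1 - Ie,
      X = -p2 * X + p3 * (I - params$Ib),
      G = -p1 * (G - params$Gb) - X * G +
        (params$W / VolG) * (Gprod - Gup) + u2 / VolG,
      Gprod = pf$a1(t) * E - pf$a2(t) * Gprod,
      Gup = pf$a3(t) * E - pf$a4(t) * Gup,
      Ie = pf$a5(t) * E - pf$a6(t) * Ie)
  })
}

#' Simulate the digital twin forward in time
#'
#' Integrates the modified Roy-Parker model over the span of the forcing
#' grid with a stiff-capable adaptive solver (`deSolve::lsoda`).  Forcing
#' lookup follows the physics of each channel: the pump rate `u1` is a
#' zero-order-hold step function, while `u2` and `u3` (samples of
#' continuous processes) are interpolated linearly — the same conventions
#' the SBINN residual uses.
#'
#' @param params a [patient_params()].
#' @param forcing a [forcing_set()].
#' @param s0 initial state; default is the basal state `(Ib, 0, Gb, 0, 0, 0)`.
#' @param times output times (minutes); default the forcing grid.
#' @param exercise_input see [twin_derivative()].
#' @param rtol,atol solver tolerances.
#' @param method a `deSolve` method name.
#' @return A data.frame with columns `t_min`, the six states, and `u1, u2, u3`.
#' @export
twin_simulate <- function(params, forcing, s0 = NULL, times = NULL,
                          exercise_input = c("above_basal", "absolute"),
                          rtol = 1e-8, atol = 1e-8, method = "lsoda") {
  exercise_input <- match.arg(exercise_input)
  if (is.null(s0)) s0 <- basal_state(params)
  stopifnot(length(s0) == 6L)
  names(s0) <- TWIN_STATES
  if (is.null(times)) times <- c(series_times(forcing$u1),
                                 series_end(forcing$u1))
  pf <- param_funs(params)
  f_u1 <- series_fun(forcing$u1); f_u2 <- series_fun_lin(forcing$u2)
  f_u3 <- series_fun_lin(forcing$u3)
  absE <- exercise_input == "absolute"
  W <- params$W; Gb <- params$Gb; Ib <- params$Ib
  rhs <- function(t, y, parms) {
    E <- f_u3(t) + if (absE) 8 else 0
    VolG <- pf$VolG(t)
    dI <- -pf$n(t) * y[1L] + pf$p4(t) * f_u1(t) - y[6L]
    dX <- -pf$p2(t) * y[2L] + pf$p3(t) * (y[1L] - Ib)
    dG <- -pf$p1(t) * (y[3L] - Gb) - y[2L] * y[3L] +
      (W / VolG) * (y[4L] - y[5L]) + f_u2(t) * CARB_MG_PER_G / VolG
    dP <- pf$a1(t) * E - pf$a2(t) * y[4L]
    dU <- pf$a3(t) * E - pf$a4(t) * y[5L]
    dE <- pf$a5(t) * E - pf$a6(t) * y[6L]
    list(c(dI, dX, dG, dP, dU, dE))
  }
  sol <- deSolve::ode(y = s0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (any(!is.finite(sol))) {
    bad <- which(apply(sol, 1L, function(r) any(!is.finite(r))))[1L]
    stop(sprintf("twin integration produced non-finite state near t = %g min",
                 sol[max(bad - 1L, 1L), "time"]), call. = FALSE)
  }
  out <- as.data.frame(sol)
  names(out) <- c("t_min", TWIN_STATES)
  out$u1 <- f_u1(out$t_min); out$u2 <- f_u2(out$t_min)
  out$u3 <- f_u3(out$t_min)
  out
}
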