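#' Length and velocity errors of the central controller
#'
#' The serial cascade of the threshold-control scheme: the length error is
#' `e_l = g_l * (l - lambda)`; the velocity error compares the contraction
#' velocity against it, `e_v = g_v * (v + e_l)`. The muscle stimulation is
#' the positive part of `e_v`, so a muscle shorter than its target length is
#' never driven.
#'
#' @param l muscle lengths (m), length 11.
#' @param v contraction velocities (m/s), negative while shortening.
#' @param lambda target (equilibrium) lengths (m).
#' @param g_l,g_v gain factors (defaults 2 and 1).
#' @return list with `e_l` and `e_v`, both length 11.
#' @export
length_velocity_errors <- function(l, v, lambda, g_l = 2, g_v = 1) {
  stopifnot(length(l) == length(lambda), length(v) == length(l))
  e_l <- g_l * (l - lambda)
  e_v <- g_v * (v + e_l)
  list(e_l = e_l, e_v = e_v)
}

#' Controller state
#'
#' Holds the low-pass filter and integral accumulator of the central
#' controller's output stage.
#'
#' @param n number of muscles.
#' @return a `controller_state` list.
#' @export
controller_state <- function(n = 11) {
  structure(list(filter = rep(0, n), integral = rep(0, n)),
            class = "controller_state")
}

#' Output stage of the central controller
#'
#' The positive part of the velocity error is low-pass filtered
#' (first-order, time constant `tau_filter`) to promote stability, and a
#' small integral component proportional to the accumulated filtered output
#' is added so the arm is not stuck in equilibria away from the target. The
#' result is clipped at zero.
#'
#' @param e_v velocity errors, length 11.
#' @param state a [controller_state()].
#' @param dt control step (s).
#' @param tau_filter filter time constant (s).
#' @param k_integral integral gain (1/s).
#' @return list with `u` (the muscle command) and the updated `state`.
#' @export
controller_output <- function(e_v, state, dt, tau_filter = 0.05,
                              k_integral = 0.05) {
  stopifnot(dt > 0)
  u_raw <- pmax(e_v, 0)
  state$filter <- state$filter + (dt / tau_filter) * (u_raw - state$filter)
  state$integral <- state$integral + state$filter * dt
  u <- pmax(state$filter + k_integral * state$integral, 0)
  list(u = u, state = state)
}

#' Delay line
#'
#' Fixed-delay signal routing: `ds_read` at time `t` returns the sample
#' recorded at `t - delay`, or the initial sample before the delay has
#' elapsed. Samples are stored at the resolution they are written;
#' lookups take the nearest recorded sample at or before the requested time.
#'
#' @param delay delay (s).
#' @param init initial sample, returned for `t < delay`.
#' @return a `delayed_signal` object.
#' @export
delayed_signal <- function(delay, init) {
  stopifnot(delay >= 0)
  structure(list(delay = delay, t = numeric(0), x = list(), init = init),
            class = "delayed_signal")
}

#' @rdname delayed_signal
#' @param ds a `delayed_signal`.
#' @param t time (s).
#' @param x sample value.
#' @export
ds_write <- function(ds, t, x) {
  ds$t <- c(ds$t, t)
  ds$x <- c(ds$x, list(x))
  ds
}

#' @rdname delayed_signal
#' @export
ds_read <- function(ds, t) {
  tq <- t - ds$delay
  idx <- which(ds$t <= tq + 1e-12)
  if (length(idx) == 0) return(ds$init)
  ds$x[[max(idx)]]
}
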