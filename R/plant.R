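#' Arm state
#'
#' Bundles the joint pose, joint rates and the derived muscle kinematics.
#'
#' @param pose an `arm_pose` or numeric c(alpha, beta, gamma, delta).
#' @param rates joint angular velocities (rad/s), length 4.
#' @param geometry an [arm_geometry()].
#' @param activations muscle activation states (dimensionless, >= 0).
#' @return an `arm_state`: pose, rates, muscle lengths `l` (m), contraction
#'   velocities `v` (m/s, negative while shortening) and activations.
#' @export
arm_state <- function(pose, rates = rep(0, 4), geometry,
                      activations = rep(0, 11)) {
  q <- as_q4(pose)
  J <- cpp_length_jacobian(q, geometry$cpp)
  structure(list(q = q, qd = as.numeric(rates),
                 l = as.numeric(cpp_muscle_lengths(q, geometry$cpp)),
                 v = as.numeric(J %*% rates),
                 activations = as.numeric(activations)),
            class = "arm_state")
}

#' Hill-type muscle tension
#'
#' Tension developed by each muscle for stimulation `u`, length `l` and
#' contraction velocity `v` (negative while shortening), with activation at
#' its steady-state value `u`. The active term is `F_max * u * fv(v)` with a
#' Hill force-velocity hyperbola while shortening and a capped eccentric
#' rise; a passive viscoelastic term `[k_p (l - l_rest) + b_p v]+` engages
#' when the muscle is stretched beyond its rest length. Tension is always
#' nonnegative, nondecreasing in `u`, and decreases with shortening speed.
#'
#' @param u stimulations (>= 0), length 11.
#' @param l lengths (m).
#' @param v contraction velocities (m/s).
#' @param geometry an [arm_geometry()] carrying the Hill parameters.
#' @return tensions (N), length 11.
#' @export
muscle_force <- function(u, l, v, geometry) {
  if (any(!is.finite(u)) || any(!is.finite(l)) || any(!is.finite(v)))
    stop("non-finite muscle state")
  if (any(u < 0)) stop("stimulations must be nonnegative")
  as.numeric(cpp_muscle_force(u, l, v, geometry$cpp))
}

#' Joint torques from muscle tensions
#'
#' Maps tensions to generalized torques by the principle of virtual work:
#' `tau = -t(J) %*% f`, with `J` the Jacobian of muscle path lengths with
#' respect to (alpha, beta, gamma, delta). A contracting muscle therefore
#' drives the joints in the direction that shortens it.
#'
#' @param tensions muscle tensions (N), length 11.
#' @param pose an `arm_pose` or numeric length-4 joint vector.
#' @param geometry an [arm_geometry()].
#' @return generalized torques (N m), length 4.
#' @export
joint_torques <- function(tensions, pose, geometry) {
  as.numeric(cpp_joint_torques(as_q4(pose), tensions, geometry$cpp))
}

#' Advance the rigid-body dynamics
#'
#' Integrates `M(q) qdd + c(q, qd) = tau` (plus gravity when enabled and the
#' soft elbow-limit torque) with semi-implicit Euler under a constant
#' generalized torque. Joint speeds exceeding `qd_max` are clamped and the
#' step is flagged unstable rather than failing: a diverging arm is
#' reportable behavior, not an error.
#'
#' @param state an [arm_state()].
#' @param torques generalized torques (N m), length 4.
#' @param dt integration step (s).
#' @param geometry an [arm_geometry()].
#' @param n_steps number of steps to take.
#' @param gravity logical; include gravity forces.
#' @param qd_max instability bound on joint speeds (rad/s).
#' @return an [arm_state()] with attribute `unstable`.
#' @export
step_dynamics <- function(state, torques, dt, geometry, n_steps = 1L,
                          gravity = FALSE, qd_max = 50) {
  stopifnot(dt > 0)
  res <- cpp_step_dynamics(state$q, state$qd, torques, dt, n_steps,
                           geometry$cpp, gravity, qd_max)
  out <- arm_state(as.numeric(res$q), as.numeric(res$qd), geometry,
                   state$activations)
  attr(out, "unstable") <- res$unstable
  out
}

#' Mechanical energy of the arm
#'
#' Kinetic plus (when `gravity`) gravitational potential energy; used for
#' conservation audits of the integrator.
#'
#' @inheritParams step_dynamics
#' @return energy (J).
#' @export
arm_energy <- function(state, geometry, gravity = FALSE) {
  cpp_energy(state$q, state$qd, geometry$cpp, gravity)
}
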