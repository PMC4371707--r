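#' Parameters of the idealized cerebellum
#'
#' The point-mass cerebellum is characterized by three numbers: a speed
#' threshold on the rate of error increase, a distance threshold below which
#' no corrections are created (and inside which the reach counts as
#' complete), and a gain multiplying the integrated central-controller
#' force.
#'
#' @param speed_threshold radial-speed threshold (m/s).
#' @param distance_threshold distance threshold (m).
#' @param gain impulse gain (dimensionless).
#' @param ball_radius radius (scaled state-space units) of the region around
#'   a stored state within which re-entry triggers the stored impulse.
#' @param reentry_refractory minimum time (s) between applications of the
#'   same stored impulse.
#' @return an `ideal_params` list.
#' @export
ideal_params <- function(speed_threshold = 0.05, distance_threshold = 0.1,
                         gain = 2, ball_radius = 0.02,
                         reentry_refractory = 0.5) {
  stopifnot(speed_threshold >= 0, distance_threshold >= 0, gain >= 0)
  structure(list(speed_threshold = speed_threshold,
                 distance_threshold = distance_threshold, gain = gain,
                 ball_radius = ball_radius,
                 reentry_refractory = reentry_refractory),
            class = "ideal_params")
}

#' Central force toward the target
#'
#' The idealized central controller: a force that always points at the
#' target (the origin) with magnitude depending only on the distance. The
#' default law is a linear spring, `F = -k r`, whose orbits are closed
#' ellipses.
#'
#' @param r position (xyz, m).
#' @param k spring constant (N/m).
#' @param law `"linear"` (spring) or `"inverse_square"`.
#' @return force vector (N); zero at the origin.
#' @export
central_force <- function(r, k = 1, law = c("linear", "inverse_square")) {
  law <- match.arg(law)
  d <- sqrt(sum(r^2))
  if (d == 0) return(c(0, 0, 0))
  if (law == "linear") -k * r else -k * r / d^3
}

#' Detect the onset of an error-increase event
#'
#' Scans a sampled trajectory for the first time the radial speed exceeds
#' the speed threshold while the distance to the origin exceeds the
#' distance threshold.
#'
#' @param times sample times (s).
#' @param pos matrix of positions, one row per sample.
#' @param vel matrix of velocities.
#' @param params an [ideal_params()].
#' @return list with `index` and `t_onset`, or `NULL` if no event occurs.
#' @export
detect_event <- function(times, pos, vel, params) {
  rad <- sqrt(rowSums(pos^2))
  raddot <- rowSums(pos * vel) / pmax(rad, 1e-12)
  hit <- which(raddot > params$speed_threshold &
                 rad > params$distance_threshold)
  if (length(hit) == 0) return(NULL)
  list(index = hit[1], t_onset = times[hit[1]])
}

#' Corrective impulse from a force history
#'
#' Integrates the central force from the event onset until the stop time:
#' the largest time at which (1) the error is still increasing faster than
#' the speed threshold, (2) the mass has not rotated more than pi/2 radians
#' around the origin since onset, and (3) the accumulated impulse (times the
#' gain) is not strong enough to reverse the radial velocity. The result is
#' multiplied by the gain; an empty window yields a zero impulse.
#'
#' @param times sample times from onset (s).
#' @param pos,vel position and velocity samples from onset (rows).
#' @param params an [ideal_params()].
#' @param k spring constant of the linear force law.
#' @param mass point mass (kg).
#' @return list with the `impulse` vector (N s) and `t_stop` (s).
#' @export
corrective_impulse <- function(times, pos, vel, params, k = 1, mass = 1) {
  n <- length(times)
  if (n < 2) return(list(impulse = c(0, 0, 0), t_stop = times[1]))
  J <- c(0, 0, 0); theta <- 0
  t_stop <- times[1]
  for (i in 2:n) {
    r <- pos[i - 1, ]; rn <- pos[i, ]
    rad <- sqrt(sum(rn^2))
    raddot <- sum(rn * vel[i, ]) / max(rad, 1e-12)
    if (raddot <= params$speed_threshold) break
    cr <- sqrt(sum(vcross(r, rn)^2))
    theta <- theta + asin(min(1, cr / max(sqrt(sum(r^2)) * rad, 1e-300)))
    if (theta > pi / 2) break
    dt <- times[i] - times[i - 1]
    Jnew <- J + central_force(r, k) * dt
    rv_after <- sum((vel[i, ] + params$gain * Jnew / mass) * rn) / max(rad, 1e-12)
    if (rv_after < 0) break
    J <- Jnew
    t_stop <- times[i]
  }
  list(impulse = params$gain * J, t_stop = t_stop)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Simulate the idealized point-mass model
#'
#' Runs the central-force dynamics (velocity Verlet) with event detection,
#' storage of corrective impulses, and impulse application on re-entry of
#' stored state-space regions. The simulation terminates when the mass comes
#' within the distance threshold of the origin ("reached"), when the orbit
#' becomes near-circular (radial-speed amplitude below the speed threshold
#' over a full period, "circular"), or at `T_max`.
#'
#' @param r0,v0 initial position (m) and velocity (m/s).
#' @param params an [ideal_params()].
#' @param T_max maximum simulated time (s).
#' @param k spring constant (N/m).
#' @param mass point mass (kg).
#' @param dt integration step (s).
#' @param record_stride store every n-th sample of the trajectory (0 = none).
#' @return an `ideal_run`: termination reason and time, correction log
#'   (`t`, `radius`, `L_before`, `L_after`, `impulse`), per-segment relative
#'   deviation of the angular momentum between impulses, entry count, and
#'   the sampled trajectory.
#' @export
simulate_ideal <- function(r0, v0, params = ideal_params(), T_max = 200,
                           k = 1, mass = 1, dt = 1e-4, record_stride = 100) {
  stopifnot(T_max > 0, dt > 0, mass > 0)
  res <- cpp_sim_ideal(r0, v0, k, mass, dt, T_max,
                       params$speed_threshold, params$distance_threshold,
                       params$gain, params$ball_radius,
                       params$reentry_refractory, record_stride)
  structure(list(
    termination = res$termination, t_end = res$t_end,
    r_final = as.numeric(res$r_final), v_final = as.numeric(res$v_final),
    n_entries = res$n_entries,
    corrections = data.frame(t = unlist(res$cor_t),
                             radius = unlist(res$cor_r),
                             L_before = unlist(res$cor_L_before),
                             L_after = unlist(res$cor_L_after),
                             impulse = unlist(res$cor_impulse)),
    segment_L_reldev = unlist(res$segment_L_reldev),
    trajectory = data.frame(t = unlist(res$rec_t), x = unlist(res$rec_x),
                            y = unlist(res$rec_y), z = unlist(res$rec_z),
                            radius = unlist(res$rec_rad),
                            L = unlist(res$rec_L))),
    class = "ideal_run")
}

#' @export
print.ideal_run <- function(x, ...) {
  cat("ideal_run:", x$termination, "at t =", signif(x$t_end, 4), "s,",
      nrow(x$corrections), "corrections,", x$n_entries, "stored entries\n")
  invisible(x)
}

#' Event log of an idealized run as CSV
#'
#' @param run an `ideal_run`.
#' @param path output file.
#' @export
write_ideal_log <- function(run, path) {
  utils::write.csv(run$corrections, path, row.names = FALSE)
  invisible(path)
}
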