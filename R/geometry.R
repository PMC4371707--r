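#' Arm geometry
#'
#' Builds the fixed physical description of the arm: two cylindrical segments
#' (upper arm; forearm plus hand) joined by a 3-DOF shoulder at the origin and
#' a 1-DOF elbow, actuated by 11 composite muscles. All muscle attachment
#' points are given in *rest coordinates*: the arm hanging along the negative
#' z axis, shoulder at the origin, x lateral, y anterior, z up. Points
#' attached to the upper arm or forearm move with their segment; some muscles
#' wrap over "bending lines", finite segments that model the curvature of a
#' muscle path over bone.
#'
#' @param L_arm upper-arm length (m).
#' @param L_farm forearm-plus-hand length (m).
#' @param m_arm,m_farm segment masses (kg).
#' @param r_arm,r_farm segment cylinder radii (m), used for the inertia
#'   tensors.
#' @param muscles data frame describing the muscle paths and Hill parameters;
#'   see [default_muscles()] for the column layout.
#' @param eps_inertia small articulation inertia (kg m^2) added to the mass
#'   matrix diagonal; keeps the ZXZ Euler chart well conditioned at the
#'   gimbal singularity of the hanging arm.
#' @param delta_min,delta_max soft elbow joint limits (rad).
#' @param K_limit,b_limit stiffness (N m/rad) and damping (N m s/rad) of the
#'   elbow limit torque.
#' @param gravity_g gravitational acceleration (m/s^2) used when gravity is
#'   enabled.
#' @return an object of class `arm_geometry`.
#' @export
arm_geometry <- function(L_arm = 0.30, L_farm = 0.35,
                         m_arm = 2.1, m_farm = 1.65,
                         r_arm = 0.04, r_farm = 0.03,
                         muscles = default_muscles(),
                         eps_inertia = 5e-5,
                         delta_min = 0, delta_max = 2.9,
                         K_limit = 30, b_limit = 2,
                         gravity_g = 9.81) {
  stopifnot(L_arm > 0, L_farm > 0)
  if (nrow(muscles) != 11L)
    stop("the arm model uses exactly 11 muscles, got ", nrow(muscles))
  if (any(muscles$F_max <= 0) || any(muscles$tau_act <= 0) ||
      any(muscles$v_max <= 0))
    stop("Hill parameters must be strictly positive")
  orig <- t(as.matrix(muscles[, c("ox", "oy", "oz")]))
  ins <- t(as.matrix(muscles[, c("ix", "iy", "iz")]))
  if (any(colSums((orig - ins)^2) == 0))
    stop("muscle origin and insertion must differ")
  bendA <- t(as.matrix(muscles[, c("bax", "bay", "baz")]))
  bendB <- t(as.matrix(muscles[, c("bbx", "bby", "bbz")]))
  if (any(muscles$bend & colSums((bendA - bendB)^2) < 1e-18))
    stop("bending lines must have two distinct endpoints")
  bendN <- t(as.matrix(muscles[, c("bnx", "bny", "bnz")]))
  cpp <- list(
    L_arm = L_arm, L_farm = L_farm, m_arm = m_arm, m_farm = m_farm,
    r_arm = r_arm, r_farm = r_farm, eps_inertia = eps_inertia,
    orig = orig, ins = ins,
    orig_frame = as.integer(muscles$oframe),
    ins_frame = as.integer(muscles$iframe),
    has_bend = as.integer(muscles$bend),
    bend_frame = as.integer(muscles$bframe),
    bendA = bendA, bendB = bendB, bendN = bendN,
    F_max = muscles$F_max, tau_act = muscles$tau_act,
    k_passive = muscles$k_passive, b_passive = muscles$b_passive,
    v_max = muscles$v_max, l_rest = rep(0, 11),
    delta_min = delta_min, delta_max = delta_max,
    K_limit = K_limit, b_limit = b_limit, gravity_g = gravity_g)
  # muscle rest lengths: lengths at the resting pose (arm along -z)
  cpp$l_rest <- as.numeric(cpp_muscle_lengths(rep(0, 4), cpp))
  structure(list(L_arm = L_arm, L_farm = L_farm, m_arm = m_arm,
                 m_farm = m_farm, r_arm = r_arm, r_farm = r_farm,
                 muscles = muscles, cpp = cpp),
            class = "arm_geometry")
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat("arm_geometry: L_arm =", x$L_arm, "m, L_farm =", x$L_farm,
      "m,", nrow(x$muscles), "muscles,",
      sum(x$muscles$bend), "with bending lines\n")
  invisible(x)
}

#' Default 11-muscle layout
#'
#' A documented composite-muscle layout covering all four degrees of freedom:
#' shoulder flexor/extensor, deltoid-like abductor, adductor, two axial
#' rotators, biceps-like and triceps-like biarticulars, a brachialis-like
#' monoarticular elbow flexor, and two oblique shoulder stabilizers. The
#' elbow muscles wrap over bending lines at the joint so they keep a useful
#' moment arm near full extension. Coordinates are rest-pose metres; the
#' layout is a geometric idealization, not an anatomical reconstruction.
#'
#' Columns: `name`; origin `ox,oy,oz` with frame `oframe`; insertion
#' `ix,iy,iz` with frame `iframe` (frames: 0 torso, 1 upper arm, 2 forearm);
#' `bend` plus bending-segment endpoints `ba*`, `bb*`, crossing-plane normal
#' `bn*` and frame `bframe`; Hill parameters `F_max` (N), `tau_act` (s),
#' `k_passive` (N/m), `b_passive` (N s/m), `v_max` (m/s).
#'
#' @return a data frame with 11 rows.
#' @export
default_muscles <- function() {
  m <- function(name, o, ofr, i, ifr, Fm,
                bend = FALSE, ba = c(0, 0, 0), bb = c(0, 0, 0),
                bn = c(0, 0, 1), bfr = 1L) {
    data.frame(name = name, ox = o[1], oy = o[2], oz = o[3], oframe = ofr,
               ix = i[1], iy = i[2], iz = i[3], iframe = ifr,
               bend = bend, bax = ba[1], bay = ba[2], baz = ba[3],
               bbx = bb[1], bby = bb[2], bbz = bb[3],
               bnx = bn[1], bny = bn[2], bnz = bn[3], bframe = bfr,
               F_max = Fm, tau_act = 0.020, k_passive = 50,
               b_passive = 20, v_max = 0.6)
  }
  rbind(
    m("shoulder_flexor",   c(0.02, 0.09, 0.01), 0L, c(0, 0.035, -0.12), 1L, 600),
    m("shoulder_extensor", c(-0.02, -0.09, 0.01), 0L, c(0, -0.035, -0.12), 1L, 600),
    m("abductor",          c(0.10, 0.00, 0.04), 0L, c(0.035, 0, -0.13), 1L, 600),
    m("adductor",          c(-0.09, 0.02, -0.04), 0L, c(-0.035, 0, -0.11), 1L, 600),
    m("internal_rotator",  c(-0.05, 0.07, 0.00), 0L, c(0.04, 0.01, -0.06), 1L, 250),
    m("external_rotator",  c(-0.05, -0.07, 0.00), 0L, c(0.04, -0.01, -0.06), 1L, 250),
    m("biceps",            c(0.00, 0.04, 0.02), 0L, c(0, 0.03, -0.335), 2L, 450,
      bend = TRUE, ba = c(-0.04, 0.05, -0.295), bb = c(0.04, 0.05, -0.295),
      bn = c(0, 0, 1), bfr = 1L),
    m("triceps",           c(0.00, -0.05, 0.02), 0L, c(0, -0.04, -0.31), 2L, 450,
      bend = TRUE, ba = c(-0.04, -0.05, -0.29), bb = c(0.04, -0.05, -0.29),
      bn = c(0, 0, 1), bfr = 1L),
    m("brachialis",        c(0.00, 0.035, -0.17), 1L, c(0, 0.035, -0.34), 2L, 400,
      bend = TRUE, ba = c(-0.04, 0.045, -0.30), bb = c(0.04, 0.045, -0.30),
      bn = c(0, 0, 1), bfr = 1L),
    m("stabilizer_ant",    c(0.06, 0.06, 0.03), 0L, c(0.025, 0.025, -0.09), 1L, 300),
    m("stabilizer_post",   c(0.06, -0.06, 0.03), 0L, c(0.025, -0.025, -0.09), 1L, 300))
}

#' Shoulder rotation matrix (intrinsic ZXZ)
#'
#' The rotation taking rest-pose upper-arm coordinates to the pose given by
#' the shoulder Euler angles, i.e. `Rz(alpha) %*% Rx(beta) %*% Rz(gamma)`.
#'
#' @param alpha,beta,gamma Euler angles (rad).
#' @return a 3x3 rotation matrix.
#' @export
shoulder_rotation_matrix <- function(alpha, beta, gamma) {
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta);  sb <- sin(beta)
  cg <- cos(gamma); sg <- sin(gamma)
  matrix(c(ca * cg - sa * cb * sg, -ca * sg - sa * cb * cg,  sa * sb,
           sa * cg + ca * cb * sg, -sa * sg + ca * cb * cg, -ca * sb,
           sb * sg,                 sb * cg,                 cb),
         nrow = 3, byrow = TRUE)
}

#' Inverse kinematics of the 4-DOF arm
#'
#' Maps a reachable hand target to the unique arm pose with no axial
#' upper-arm rotation (`gamma = 0`). The shoulder angles use the closed-form
#' two-link solution; `alpha` is computed with `atan2(-x, y)`, which agrees
#' with the arcsine form on its domain and extends it to targets behind the
#' frontal plane. On the vertical axis (x = y = 0) `alpha` is undefined and
#' set to 0.
#'
#' @param target numeric xyz (m), shoulder at the origin.
#' @param geometry an [arm_geometry()].
#' @return an `arm_pose`: list with `alpha`, `beta`, `gamma`, `delta`, the
#'   shoulder quaternion `q_s` (w, x, y, z) and elbow angle `theta_e`.
#' @export
ik_angles <- function(target, geometry) {
  stopifnot(length(target) == 3)
  La <- geometry$L_arm; Lf <- geometry$L_farm
  d <- sqrt(sum(target^2))
  if (d < abs(La - Lf) - 1e-12 || d > La + Lf + 1e-12)
    stop("target at distance ", signif(d, 4), " m is outside the reachable ",
         "annulus [", abs(La - Lf), ", ", La + Lf, "] m")
  d <- min(max(d, abs(La - Lf)), La + Lf)
  x <- target[1]; y <- target[2]; z <- target[3]
  alpha <- if (x == 0 && y == 0) 0 else atan2(-x, y)
  cospsi <- (d^2 + La^2 - Lf^2) / (2 * d * La)
  beta <- acos(max(-1, min(1, -z / d))) - acos(max(-1, min(1, cospsi)))
  cosd <- (La^2 + Lf^2 - d^2) / (2 * La * Lf)
  delta <- pi - acos(max(-1, min(1, cosd)))
  arm_pose(alpha, beta, 0, delta)
}

#' Construct an arm pose
#'
#' @param alpha,beta,gamma shoulder intrinsic ZXZ Euler angles (rad).
#' @param delta elbow flexion (rad, 0 = extended).
#' @return an `arm_pose` object.
#' @export
arm_pose <- function(alpha, beta, gamma = 0, delta = 0) {
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 q_s = zxz_quaternion(alpha, beta, gamma),
                 theta_e = delta),
            class = "arm_pose")
}

#' ZXZ Euler angles to unit quaternion
#'
#' @param alpha,beta,gamma Euler angles (rad).
#' @return quaternion as c(w, x, y, z), canonicalized to w >= 0.
#' @export
zxz_quaternion <- function(alpha, beta, gamma) {
  cb <- cos(beta / 2); sb <- sin(beta / 2)
  q <- c(cb * cos((alpha + gamma) / 2),
         sb * cos((alpha - gamma) / 2),
         sb * sin((alpha - gamma) / 2),
         cb * sin((alpha + gamma) / 2))
  if (q[1] < 0) q <- -q
  q
}

as_q4 <- function(pose) {
  if (inherits(pose, "arm_pose"))
    c(pose$alpha, pose$beta, pose$gamma, pose$delta)
  else as.numeric(pose)
}

#' Forward kinematics: hand position
#'
#' Rest coordinates are rotated first about the elbow (by `delta`, about the
#' local x axis) and then by the shoulder rotation, mirroring how insertion
#' points are placed. Exact inverse of [ik_angles()] on the `gamma = 0`
#' slice.
#'
#' @param pose an `arm_pose` or numeric c(alpha, beta, gamma, delta).
#' @param geometry an [arm_geometry()].
#' @return hand xyz (m).
#' @export
forward_hand_position <- function(pose, geometry) {
  as.numeric(cpp_hand_position(as_q4(pose), geometry$cpp))
}

#' Elbow position for a pose
#' @inheritParams forward_hand_position
#' @return elbow xyz (m).
#' @export
forward_elbow_position <- function(pose, geometry) {
  q <- as_q4(pose)
  as.numeric(shoulder_rotation_matrix(q[1], q[2], q[3]) %*%
               c(0, 0, -geometry$L_arm))
}

#' Muscle path length with an optional bending line
#'
#' Without a bending line (or when the straight path stays on one side of
#' the line's crossing plane) the path is the Euclidean segment. Otherwise
#' the path goes through the point of the bending segment that minimizes the
#' total length, computed in closed form from the mirror construction.
#'
#' @param p1,p2 endpoints (xyz, m).
#' @param bending optional list with elements `a`, `b` (segment endpoints)
#'   and `normal` (crossing-plane normal).
#' @return list with `length` (m) and `via` (xyz or NULL).
#' @export
muscle_path_length <- function(p1, p2, bending = NULL) {
  if (sum((p1 - p2)^2) == 0) stop("degenerate muscle: p1 == p2")
  if (is.null(bending))
    return(list(length = sqrt(sum((p1 - p2)^2)), via = NULL))
  if (sum((bending$a - bending$b)^2) < 1e-18)
    stop("degenerate bending line")
  res <- cpp_path_length(p1, p2, bending$a, bending$b, bending$normal, TRUE)
  list(length = res$length,
       via = if (is.null(res$via)) NULL else as.numeric(res$via))
}

#' Muscle lengths at a pose
#'
#' @inheritParams forward_hand_position
#' @return numeric vector of 11 path lengths (m).
#' @export
muscle_lengths <- function(pose, geometry) {
  as.numeric(cpp_muscle_lengths(as_q4(pose), geometry$cpp))
}

#' Target (equilibrium) muscle lengths for a reach target
#'
#' The central controller's command: the muscle lengths the arm would have
#' with the hand at `target`, obtained from the inverse kinematics.
#'
#' @param target hand xyz (m).
#' @param geometry an [arm_geometry()].
#' @return numeric vector of 11 lengths (m).
#' @export
target_lengths <- function(target, geometry) {
  muscle_lengths(ik_angles(target, geometry), geometry)
}

#' Standard test-reach targets
#'
#' The eight target locations used in the reaching experiments, stored as
#' printed (cm) and returned in metres.
#'
#' @return data frame with columns `target` (id) and `x`, `y`, `z` in m.
#' @export
reach_targets <- function() {
  path <- system.file("extdata", "targets.csv", package = "cbreach")
  tb <- utils::read.csv(path)
  data.frame(target = tb$target,
             x = tb$x_cm / 100, y = tb$y_cm / 100, z = tb$z_cm / 100)
}

#' Read / write arm geometry configuration
#'
#' The geometry is serialized as nested YAML: scalar segment parameters plus
#' one block per muscle.
#'
#' @param path file path.
#' @param geometry an [arm_geometry()].
#' @return `read_arm_config` returns an [arm_geometry()].
#' @export
read_arm_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mus <- do.call(rbind, lapply(cfg$muscles, function(m)
    data.frame(name = m$name, ox = m$origin[1], oy = m$origin[2],
               oz = m$origin[3], oframe = m$origin_frame,
               ix = m$insertion[1], iy = m$insertion[2], iz = m$insertion[3],
               iframe = m$insertion_frame,
               bend = isTRUE(m$bend$enabled),
               bax = m$bend$a[1], bay = m$bend$a[2], baz = m$bend$a[3],
               bbx = m$bend$b[1], bby = m$bend$b[2], bbz = m$bend$b[3],
               bnx = m$bend$normal[1], bny = m$bend$normal[2],
               bnz = m$bend$normal[3], bframe = m$bend$frame,
               F_max = m$F_max, tau_act = m$tau_act,
               k_passive = m$k_passive, b_passive = m$b_passive,
               v_max = m$v_max)))
  arm_geometry(L_arm = cfg$L_arm, L_farm = cfg$L_farm, m_arm = cfg$m_arm,
               m_farm = cfg$m_farm, r_arm = cfg$r_arm, r_farm = cfg$r_farm,
               muscles = mus, eps_inertia = cfg$eps_inertia,
               delta_min = cfg$delta_min, delta_max = cfg$delta_max,
               K_limit = cfg$K_limit, b_limit = cfg$b_limit,
               gravity_g = cfg$gravity_g)
}

#' @rdname read_arm_config
#' @export
write_arm_config <- function(geometry, path) {
  mus <- geometry$muscles
  cfg <- list(
    L_arm = geometry$L_arm, L_farm = geometry$L_farm,
    m_arm = geometry$m_arm, m_farm = geometry$m_farm,
    r_arm = geometry$r_arm, r_farm = geometry$r_farm,
    eps_inertia = geometry$cpp$eps_inertia,
    delta_min = geometry$cpp$delta_min, delta_max = geometry$cpp$delta_max,
    K_limit = geometry$cpp$K_limit, b_limit = geometry$cpp$b_limit,
    gravity_g = geometry$cpp$gravity_g,
    muscles = lapply(seq_len(nrow(mus)), function(i) {
      m <- mus[i, ]
      list(name = m$name,
           origin = c(m$ox, m$oy, m$oz), origin_frame = m$oframe,
           insertion = c(m$ix, m$iy, m$iz), insertion_frame = m$iframe,
           bend = list(enabled = m$bend, a = c(m$bax, m$bay, m$baz),
                       b = c(m$bbx, m$bby, m$bbz),
                       normal = c(m$bnx, m$bny, m$bnz), frame = m$bframe),
           F_max = m$F_max, tau_act = m$tau_act, k_passive = m$k_passive,
           b_passive = m$b_passive, v_max = m$v_max)
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
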