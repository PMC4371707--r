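# Independent oracles used to check the implementation; deliberately written
# from the definitions, not from the package's code paths.

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)
rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), -sin(a),
                              0, sin(a), cos(a)), 3, 3, byrow = TRUE)

# intrinsic Z-X-Z as an explicit product of elementary rotations
oracle_rotation <- function(alpha, beta, gamma) {
  rot_z(alpha) %*% rot_x(beta) %*% rot_z(gamma)
}

# hand position from a homogeneous-transform chain:
# shoulder rotation -> translate to elbow -> elbow flexion about x ->
# translate along the forearm
oracle_fk <- function(q, L_arm, L_farm) {
  hom <- function(R, p) rbind(cbind(R, p), c(0, 0, 0, 1))
  T1 <- hom(rot_z(q[1]) %*% rot_x(q[2]) %*% rot_z(q[3]), c(0, 0, 0))
  T2 <- hom(diag(3), c(0, 0, -L_arm))
  T3 <- hom(rot_x(q[4]), c(0, 0, 0))
  T4 <- hom(diag(3), c(0, 0, -L_farm))
  as.numeric((T1 %*% T2 %*% T3 %*% T4 %*% c(0, 0, 0, 1))[1:3])
}

# literal transcription of the olivary spike-probability formula
oracle_spike_prob <- function(E, Edot_pos, freq, phase, t, p) {
  w <- 2 * pi * freq
  num <- p * cos(w * (t - phase)) + 1
  den <- (1 + exp(5 - E)) * (1 + exp(30 - 15 * Edot_pos))
  min(1, max(0, num / den))
}

# literal transcription of the recall formulas: D(i) = ||f(i) - v||^2 on the
# scaled context, D_N = (M_F/||D||) D, output = sum_i w(i) exp(gamma D_N(i))
oracle_recall <- function(F, W, v, scales, gamma, M_F) {
  n <- nrow(F)
  if (n == 0) return(rep(0, ncol(W)))
  D <- vapply(seq_len(n), function(i)
    sum((scales * (F[i, ] - v))^2), numeric(1))
  nD <- sqrt(sum(D^2))
  DN <- if (nD > 0) (M_F / nD) * D else rep(0, n)
  out <- rep(0, ncol(W))
  for (i in seq_len(n)) out <- out + W[i, ] * exp(gamma * DN[i])
  out
}

# dense 1-D grid search for the shortest path via a point on segment a-b
oracle_path_grid <- function(p1, p2, a, b, n = 200001) {
  ts <- seq(0, 1, length.out = n)
  best <- Inf
  for (t in ts) {
    v <- a + t * (b - a)
    len <- sqrt(sum((p1 - v)^2)) + sqrt(sum((v - p2)^2))
    if (len < best) best <- len
  }
  best
}

# random targets inside the reachable annulus, away from its boundary
random_targets <- function(n, L_arm = 0.30, L_farm = 0.35,
                           margin = 0.02) {
  lo <- abs(L_arm - L_farm) + margin
  hi <- L_arm + L_farm - margin
  out <- matrix(0, n, 3)
  i <- 0
  while (i < n) {
    t <- stats::runif(3, -hi, hi)
    d <- sqrt(sum(t^2))
    if (d > lo && d < hi) {
      i <- i + 1
      out[i, ] <- t
    }
  }
  out
}
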