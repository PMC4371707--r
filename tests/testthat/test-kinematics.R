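g <- arm_geometry()

test_that("inverse kinematics hits the closed-form elbow angles", {
  # fully extended arm: delta = 0
  d <- g$L_arm + g$L_farm
  p <- ik_angles(c(0, d / sqrt(2), -d / sqrt(2)), g)
  expect_equal(p$delta, 0, tolerance = 1e-7)
  # right elbow: |target|^2 = L_arm^2 + L_farm^2
  d <- sqrt(g$L_arm^2 + g$L_farm^2)
  p <- ik_angles(c(0, d, 0), g)
  expect_equal(p$delta, pi / 2, tolerance = 1e-10)
  expect_identical(p$gamma, 0)
})

test_that("forward kinematics inverts the inverse kinematics", {
  set.seed(11)
  tg <- random_targets(300)
  for (i in seq_len(nrow(tg))) {
    h <- forward_hand_position(ik_angles(tg[i, ], g), g)
    expect_lt(sqrt(sum((h - tg[i, ])^2)), 1e-6)
  }
})

test_that("unreachable targets and the vertical-axis singularity are handled", {
  expect_error(ik_angles(c(0, 0, -0.9), g), "reachable")
  expect_error(ik_angles(c(0.01, 0, 0.01), g), "reachable")
  p <- ik_angles(c(0, 0, -0.5), g)   # x = y = 0: alpha defined as 0
  expect_identical(p$alpha, 0)
  expect_equal(forward_hand_position(p, g), c(0, 0, -0.5), tolerance = 1e-9)
})

test_that("shoulder rotation matrix is the intrinsic ZXZ rotation", {
  expect_equal(shoulder_rotation_matrix(0, 0, 0), diag(3))
  set.seed(21)
  for (k in 1:50) {
    ang <- runif(3, -pi, pi)
    R <- shoulder_rotation_matrix(ang[1], ang[2], ang[3])
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(R, oracle_rotation(ang[1], ang[2], ang[3]),
                 tolerance = 1e-12)
  }
})

test_that("hand position matches an independent homogeneous-transform chain", {
  # round-trip through the printed first test target
  t1 <- c(-0.10, 0.20, -0.30)
  expect_equal(forward_hand_position(ik_angles(t1, g), g), t1,
               tolerance = 1e-9)
  # extended arm reaches the full arm length
  p <- arm_pose(0.3, 0.8, 0.2, 0)
  expect_equal(sqrt(sum(forward_hand_position(p, g)^2)),
               g$L_arm + g$L_farm, tolerance = 1e-12)
  set.seed(31)
  for (k in 1:50) {
    q <- c(runif(3, -pi, pi), runif(1, 0, 2.8))
    expect_equal(forward_hand_position(q, g),
                 oracle_fk(q, g$L_arm, g$L_farm), tolerance = 1e-12)
  }
})

test_that("muscle path length handles bending lines like a grid search", {
  p1 <- c(0, 0.05, 0); p2 <- c(0, 0.04, -0.4)
  expect_equal(muscle_path_length(p1, p2)$length, sqrt(sum((p1 - p2)^2)))
  # collinear via point: triangle equality, no extra length
  bend <- list(a = c(-0.1, 0.045, -0.2), b = c(0.1, 0.045, -0.2),
               normal = c(0, 1, 0))
  p1c <- c(0, 0.05, 0); p2c <- c(0, 0.04, -0.4)
  mid <- (p1c + p2c) / 2
  bend_thru <- list(a = mid + c(-0.1, 0, 0), b = mid + c(0.1, 0, 0),
                    normal = c(0, 1, 0))
  res <- muscle_path_length(p1c, p2c, bend_thru)
  expect_equal(res$length, sqrt(sum((p1c - p2c)^2)), tolerance = 1e-12)
  # random wrapping instances against dense grid search
  set.seed(41)
  for (k in 1:20) {
    p1 <- c(runif(1, -0.1, 0.1), runif(1, 0.02, 0.1), runif(1, -0.05, 0.05))
    p2 <- c(runif(1, -0.1, 0.1), runif(1, -0.1, -0.02), runif(1, -0.45, -0.3))
    a <- c(-0.15, 0, runif(1, -0.3, -0.1)); b <- c(0.15, 0, a[3])
    res <- muscle_path_length(p1, p2, list(a = a, b = b, normal = c(0, 1, 0)))
    expect_equal(res$length, oracle_path_grid(p1, p2, a, b),
                 tolerance = 1e-8)
    expect_gte(res$length, sqrt(sum((p1 - p2)^2)) - 1e-12)
  }
  expect_error(muscle_path_length(p1, p2,
    list(a = c(0, 0, 0), b = c(0, 0, 0), normal = c(0, 1, 0))), "degenerate")
})

test_that("target lengths are consistent, positive, and continuous", {
  tg <- reach_targets()
  expect_equal(nrow(tg), 8L)
  for (i in 1:8) {
    lam <- target_lengths(as.numeric(tg[i, c("x", "y", "z")]), g)
    expect_length(lam, 11)
    expect_true(all(is.finite(lam) & lam > 0))
  }
  # self-consistency: lengths at the IK pose equal the target lengths
  set.seed(51)
  rt <- random_targets(20)
  for (i in seq_len(nrow(rt))) {
    pose <- ik_angles(rt[i, ], g)
    expect_equal(target_lengths(forward_hand_position(pose, g), g),
                 muscle_lengths(pose, g), tolerance = 1e-9)
    # continuity in the target
    eps <- 1e-4
    dl <- target_lengths(rt[i, ] + c(eps, 0, 0), g) -
      target_lengths(rt[i, ], g)
    expect_lt(max(abs(dl)), 100 * eps)
  }
})

test_that("geometry configuration files round-trip", {
  path <- tempfile(fileext = ".yaml")
  write_arm_config(g, path)
  g2 <- read_arm_config(path)
  expect_equal(g2$cpp$l_rest, g$cpp$l_rest, tolerance = 1e-12)
  expect_equal(g2$muscles$F_max, g$muscles$F_max)
  q <- c(0.3, 0.7, 0.1, 1.1)
  expect_equal(muscle_lengths(q, g2), muscle_lengths(q, g), tolerance = 1e-12)
  # the shipped default-geometry fixture parses to the same arm
  shipped <- read_arm_config(system.file("extdata", "arm_default.yaml",
                                         package = "cbreach"))
  expect_equal(muscle_lengths(q, shipped), muscle_lengths(q, g),
               tolerance = 1e-12)
})

test_that("geometry constructor validates its invariants", {
  mus <- default_muscles()
  expect_error(arm_geometry(muscles = mus[1:10, ]), "11")
  mus2 <- default_muscles(); mus2$F_max[3] <- -1
  expect_error(arm_geometry(muscles = mus2), "positive")
  mus3 <- default_muscles()
  mus3[1, c("ix", "iy", "iz")] <- mus3[1, c("ox", "oy", "oz")]
  expect_error(arm_geometry(muscles = mus3), "differ")
})
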