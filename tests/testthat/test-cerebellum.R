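test_that("context lookback follows the delay-compensation formula", {
  # visual delay 150 ms, proprioceptive 25 ms, 50 ms since spike -> 150 ms
  expect_equal(context_lookback_time(1.0, 1.05), 0.150)
  # at the spike itself: tau_v - tau_p
  expect_equal(context_lookback_time(2, 2), 0.125)
  # at the storage-window cap
  expect_equal(context_lookback_time(0.5, 0.75), 0.250)
  expect_error(context_lookback_time(1, 0.9))
})

test_that("efference-copy corrections average over the shifted window", {
  times <- seq(0, 1, by = 1e-3)
  eff <- matrix(0.3, length(times), 11)
  w <- correction_from_efference(times, eff, t_cs = 0.4, t = 0.6, gain = 2)
  expect_equal(w, rep(0.6, 11), tolerance = 1e-12)
  # linear ramp: the discrete mean approaches (a + b)/2
  ramp <- matrix(seq(0, 1, length.out = length(times)), length(times), 11)
  w <- correction_from_efference(times, ramp, t_cs = 0.3, t = 0.5, gain = 1)
  a <- ramp[which.min(abs(times - (0.3 - 0.125))), 1]
  b <- ramp[which.min(abs(times - (0.5 - 0.125))), 1]
  expect_equal(w[1], (a + b) / 2, tolerance = 1e-3)
  # zero efference stores a correction that corrects nothing
  w <- correction_from_efference(times, eff * 0, 0.4, 0.6, gain = 2)
  expect_equal(w, rep(0, 11))
  # empty window: the single sample at the window start
  w <- correction_from_efference(times, ramp, t_cs = 0.5, t = 0.5, gain = 1)
  expect_equal(w[1], ramp[which.min(abs(times - 0.375)), 1], tolerance = 1e-3)
})

test_that("single-muscle and proprioceptive-product corrections", {
  w <- correction_from_muscle(4, 0.02)
  expect_equal(w, c(0, 0, 0, 0.02, rep(0, 7)))
  expect_equal(correction_from_muscle(2, 0), rep(0, 11))
  expect_error(correction_from_muscle(12, 0.1))
  # product rule: positive parts of the length excess and elongation rate
  lam <- rep(0.2, 11)
  expect_equal(correction_model4(rep(0.19, 11), lam, rep(0.5, 11), 1),
               rep(0, 11))
  expect_equal(correction_model4(rep(0.22, 11), lam, rep(-0.1, 11), 1),
               rep(0, 11))
  w <- correction_model4(lam + 0.02, lam, rep(0.5, 11), gain = 1)
  expect_equal(w, rep(0.01, 11), tolerance = 1e-12)
})

test_that("recall matches a literal transcription of the formulas", {
  set.seed(101)
  st <- cb_store(M_F = 32, gamma = -2)
  # empty store: zero output
  expect_equal(cb_recall(st, rnorm(28)), rep(0, 11))
  for (k in 1:100) {
    n <- sample(1:8, 1)
    F <- matrix(rnorm(n * 28), n, 28)
    W <- matrix(rnorm(n * 11, sd = 0.1), n, 11)
    st$F <- F; st$W <- W
    v <- rnorm(28)
    expect_equal(cb_recall(st, v),
                 oracle_recall(F, W, v, st$scales, st$gamma, st$M_F),
                 tolerance = 1e-10)
  }
})

test_that("recall edge cases and bounds", {
  st <- cb_store(M_F = 32, gamma = -2)
  f <- rnorm(28); w <- rnorm(11)
  st <- cb_add(st, f, w)
  # exact hit on the only entry: D = 0 edge case yields the full correction
  expect_equal(cb_recall(st, f), w, tolerance = 1e-12)
  # two entries equidistant from v contribute with equal kernel weights
  st2 <- cb_store(M_F = 32, gamma = -1, fuse_threshold = 0)
  v <- rep(0, 28)
  f1 <- c(1, rep(0, 27)); f2 <- c(-1, rep(0, 27))
  st2 <- cb_add(st2, f1, rep(1, 11))
  st2 <- cb_add(st2, f2, rep(1, 11))
  D <- sum((st2$scales * f1)^2)
  DN <- st2$M_F * D / sqrt(2 * D^2)
  expect_equal(cb_recall(st2, v), rep(2 * exp(-DN), 11), tolerance = 1e-12)
  # bounded by the summed correction norms
  set.seed(111)
  for (k in 1:20) {
    st3 <- cb_store(gamma = -0.5, fuse_threshold = 0)
    for (i in 1:5) st3 <- cb_add(st3, rnorm(28), rnorm(11))
    out <- cb_recall(st3, rnorm(28))
    expect_lte(sqrt(sum(out^2)), sum(sqrt(rowSums(st3$W^2))))
  }
  # recall is continuous in the context
  v <- rnorm(28)
  o1 <- cb_recall(st, v)
  o2 <- cb_recall(st, v + 1e-8)
  expect_lt(max(abs(o1 - o2)), 1e-5)
  # a nonnegative kernel exponent is a configuration error
  expect_error(cb_store(gamma = 0.5), "negative")
})

test_that("fusion keeps the store bounded and on the parent segment", {
  # identical parents fuse into themselves
  st <- cb_store(M_F = 4, fuse_threshold = 0.5)
  f <- rnorm(28); w <- rnorm(11)
  st <- cb_add(st, f, w)
  st <- cb_add(st, f, w)
  expect_equal(nrow(st$F), 1L)
  expect_equal(st$F[1, ], f)
  expect_equal(st$W[1, ], w)
  # a full store fuses with the nearest neighbor and stays at M_F
  set.seed(121)
  st <- cb_store(M_F = 4, fuse_threshold = 0)
  for (i in 1:4) st <- cb_add(st, rnorm(28, sd = 5), rnorm(11))
  F_before <- st$F
  f_new <- rnorm(28, sd = 5)
  d <- sqrt(colSums((t(F_before) - f_new)^2 * st$scales^2))
  nearest <- which.min(d)
  st <- cb_add(st, f_new, rnorm(11))
  expect_equal(nrow(st$F), 4L)
  # the child lies at the midpoint of the segment joining the parents
  expect_equal(st$F[nearest, ], (F_before[nearest, ] + f_new) / 2,
               tolerance = 1e-12)
  # random operation sequences never exceed M_F
  st <- cb_store(M_F = 8, fuse_threshold = 0.3)
  for (i in 1:100) st <- cb_add(st, rnorm(28), rnorm(11))
  expect_lte(nrow(st$F), 8L)
})

test_that("stores serialize to JSON and restore exactly", {
  set.seed(131)
  st <- cb_store(M_F = 16, gamma = -1.5, fuse_threshold = 0)
  for (i in 1:5)
    st <- cb_add(st, rnorm(28), rnorm(11), t_cs = i * 0.1, t_store = i * 0.1 + 0.05,
                 source = -1)
  path <- tempfile(fileext = ".json")
  cb_save(st, path)
  st2 <- cb_load(path)
  expect_equal(st2$F, st$F)
  expect_equal(st2$W, st$W)
  expect_equal(st2$gamma, st$gamma)
  v <- rnorm(28)
  expect_equal(cb_recall(st2, v), cb_recall(st, v))
})

test_that("stored entries are causally valid and learning precedes recall", {
  g <- test_geometry()
  tg <- as.numeric(reach_targets()[7, c("x", "y", "z")])
  r <- run_reach(1, tg, g, seed = 5)
  expect_gt(r$n_storages, 0)
  # every storage happened within the handling window after its spike
  expect_true(all(r$storages$t >= r$storages$t_cs))
  expect_true(all(r$storages$t - r$storages$t_cs <= 0.250 + 1e-9))
  # record-only mode: with the output disconnected, the first stored entry
  # is identical (the store is empty until then, so no recall can differ)
  r2 <- run_reach(1, tg, g, seed = 5, record_only = TRUE)
  expect_equal(r2$store$F[1, ], r$store$F[1, ], tolerance = 1e-12)
  expect_equal(r2$store$W[1, ], r$store$W[1, ], tolerance = 1e-12)
})

test_that("context scales mask components out of the metric", {
  sc <- context_scales(error = 0, error_rate = 0)
  expect_equal(sc[1:2], c(0, 0))
  st <- cb_store(scales = sc, fuse_threshold = 0)
  f <- rep(0, 28); w <- rep(1, 11)
  st <- cb_add(st, f, w)
  v <- rep(0, 28); v[1] <- 100  # huge error difference, masked out
  expect_equal(cb_recall(st, v), w, tolerance = 1e-12)
})
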