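test_that("spike probability reproduces the printed gate constants", {
  p <- 0.1
  # error gate: at E = 5 the magnitude factor is exactly 2 (1 + e^0);
  # saturate the derivative gate so only that factor remains
  P <- visual_spike_probability(E = 5, Edot_pos = 50, freq = 3, phase = 0,
                                t = 0, p = p)
  expect_equal(P, (p * cos(0) + 1) / 2, tolerance = 1e-12)
  # derivative gate: at [E']+ = 2 the factor is exactly 2 (30 - 15*2 = 0)
  P <- visual_spike_probability(E = 50, Edot_pos = 2, freq = 3, phase = 0,
                                t = 0, p = p)
  expect_equal(P, (p * cos(0) + 1) / 2, tolerance = 1e-12)
  # both gates nearly closed at zero error: essentially no spiking
  P0 <- visual_spike_probability(E = 0, Edot_pos = 0, freq = 7, phase = 0,
                                 t = 0.05, p = p)
  expect_lt(P0, 0.02)
})

test_that("spike probability matches a literal transcription", {
  set.seed(71)
  for (k in 1:200) {
    E <- runif(1, 0, 40); Ed <- runif(1, 0, 5)
    fr <- sample(c(3, 7), 1); ph <- runif(1, 0, 1 / fr)
    t <- runif(1, 0, 4); p <- runif(1, 0, 0.5)
    expect_equal(visual_spike_probability(E, Ed, fr, ph, t, p),
                 oracle_spike_prob(E, Ed, fr, ph, t, p), tolerance = 1e-12)
  }
})

test_that("spike probability gates open monotonically with the error", {
  grid <- seq(0, 30, by = 0.5)
  P_E <- vapply(grid, function(E)
    visual_spike_probability(E, 1, 3, 0, 0, 0.1), numeric(1))
  expect_true(all(diff(P_E) >= -1e-12))
  P_Ed <- vapply(seq(0, 4, by = 0.1), function(Ed)
    visual_spike_probability(10, Ed, 3, 0, 0, 0.1), numeric(1))
  expect_true(all(diff(P_Ed) >= -1e-12))
})

test_that("cells with distinct phases peak at distinct times", {
  cells <- olive_cells(N3 = 5, N7 = 0, p = 0.3)
  ts <- seq(0, 1 / 3, by = 1e-4)
  peaks <- vapply(seq_len(nrow(cells)), function(i) {
    P <- vapply(ts, function(t)
      visual_spike_probability(6, 1.8, cells$freq[i], cells$phase[i], t, 0.3),
      numeric(1))
    ts[which.max(P)]
  }, numeric(1))
  expect_equal(sort(peaks), peaks)           # evenly spaced phases in order
  expect_equal(length(unique(round(peaks, 6))), 5)
  expect_equal(peaks, cells$phase, tolerance = 1e-3)
})

test_that("population spike counts grow with the error derivative", {
  count_spikes <- function(Edot) {
    set.seed(81)
    cells <- olive_cells()
    n <- 0
    for (t in seq(0, 2, by = 1e-3)) {
      out <- generate_visual_spikes(E = 10, Edot = Edot, cells, t)
      cells <- out$cells
      n <- n + nrow(out$spikes)
    }
    n
  }
  n_low <- count_spikes(0.5)
  n_high <- count_spikes(2.5)
  expect_gt(n_high, n_low)
})

test_that("the 200 ms refractory period is never violated", {
  # forced probability, recent spike: silent
  cells <- olive_cells()
  cells$last_spike <- rep(-0.1, nrow(cells))  # spiked 100 ms before t = 0
  out <- generate_visual_spikes(E = 50, Edot = 50, cells, t = 0)
  expect_equal(nrow(out$spikes), 0)
  # long stochastic run under strong drive: per-cell ISI >= 200 ms
  set.seed(91)
  cells <- olive_cells()
  trains <- vector("list", nrow(cells))
  for (t in seq(0, 60, by = 1e-3)) {
    out <- generate_visual_spikes(E = runif(1, 5, 30),
                                  Edot = runif(1, 0, 4), cells, t)
    cells <- out$cells
    if (nrow(out$spikes) > 0)
      for (i in out$spikes$cell)
        trains[[i]] <- c(trains[[i]], t)
  }
  expect_gt(sum(lengths(trains)), 100)
  for (tr in trains)
    if (length(tr) > 1) expect_gte(min(diff(tr)), 0.200 - 1e-9)
})

test_that("spike trains are reproducible under a fixed seed", {
  run_train <- function() {
    set.seed(123)
    cells <- olive_cells()
    log <- NULL
    for (t in seq(0, 3, by = 1e-3)) {
      out <- generate_visual_spikes(E = 12, Edot = 1.5, cells, t)
      cells <- out$cells
      if (nrow(out$spikes)) log <- rbind(log, out$spikes)
    }
    log
  }
  expect_identical(run_train(), run_train())
})

test_that("proprioceptive spikes require all printed conditions", {
  lam <- rep(0.2, 11)
  last <- rep(-Inf, 11)
  # condition 2 fails: shorter than target
  l <- rep(0.19, 11); ld <- rep(0.1, 11)
  out <- proprioceptive_spikes(l, ld, lam, last, t = 1)
  expect_equal(nrow(out$spikes), 0)
  # all three hold, last spike 250 ms ago: spike
  l <- rep(0.21, 11); last2 <- rep(0.75, 11)
  out <- proprioceptive_spikes(l, ld, lam, last2, t = 1)
  expect_equal(out$spikes$muscle, 1:11)
  # refractory: last spike 100 ms ago blocks
  last3 <- rep(0.9, 11)
  out <- proprioceptive_spikes(l, ld, lam, last3, t = 1)
  expect_equal(nrow(out$spikes), 0)
  # condition 1 fails for shortening muscles
  out <- proprioceptive_spikes(l, rep(-0.1, 11), lam, last, t = 1)
  expect_equal(nrow(out$spikes), 0)
  # visual-error constraint blocks when the error is not increasing
  out <- proprioceptive_spikes(l, ld, lam, last, t = 1,
                               require_visual = TRUE, Edot = -0.01)
  expect_equal(nrow(out$spikes), 0)
  out <- proprioceptive_spikes(l, ld, lam, last, t = 1,
                               require_visual = TRUE, Edot = 0.02)
  expect_equal(nrow(out$spikes), 11)
})

test_that("the olive population covers the oscillation cycle", {
  cells <- olive_cells(N3 = 10, N7 = 10)
  expect_equal(sum(cells$freq == 3), 10)
  expect_equal(sum(cells$freq == 7), 10)
  ph3 <- cells$phase[cells$freq == 3]
  expect_equal(ph3, seq(0, 1 / 3, length.out = 11)[1:10], tolerance = 1e-12)
  expect_error(olive_cells(p = 1.5))
})
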