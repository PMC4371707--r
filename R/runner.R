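#' Integrated hand-target error
#'
#' The reach performance measure: the time integral (trapezoidal rule) of
#' the distance between hand and target over the simulation horizon.
#' Smaller values indicate a faster, more accurate reach.
#'
#' @param times sample times (s) covering `[0, T]`.
#' @param hand matrix of hand positions, one row per sample.
#' @param target target xyz (m).
#' @param T expected horizon (s); the trajectory must cover it.
#' @return integrated error (m s).
#' @export
integrated_error <- function(times, hand, target, T = NULL) {
  d <- sqrt(colSums((t(hand) - target)^2))
  if (!is.null(T) && (max(times) < T - 1e-6))
    stop("trajectory is truncated: covers ", max(times), " of ", T, " s")
  n <- length(times)
  sum(diff(times) * (d[-1] + d[-n]) / 2)
}

model_code <- function(model) {
  if (is.character(model) && model == "none") return(0L)
  m <- as.integer(model)
  if (is.na(m) || m < 0 || m > 4)
    stop("model must be 'none' or 1, 2, 3, 4")
  m
}

#' Simulate one reach
#'
#' Runs the full closed loop for one reach: the central controller drives
#' the 11 muscles toward the target lengths of `target`; depending on the
#' model variant, complex spikes (visual Eq.-gated olivary spikes for models
#' 1 and 4, per-muscle proprioceptive rules for models 2 and 3) trigger the
#' storage of context-correction pairs, and the cerebellar store adds its
#' recalled corrections at the muscle input. The arm starts at the resting
#' pose; pass the returned `store` back in to chain successive reaches to
#' the same target.
#'
#' @param model `"none"` or 1, 2, 3, 4.
#' @param target hand target xyz (m).
#' @param geometry an [arm_geometry()].
#' @param config see [default_config()].
#' @param store a [cb_store()] carried over from previous reaches, or NULL
#'   for a fresh store.
#' @param seed integer seed for the olivary spike draws.
#' @param record_only logical; run the cerebellum in record-only mode (the
#'   store learns but its output is disconnected from the muscles).
#' @return a `reach_result`: trajectory matrix (`t`, hand xyz, joint
#'   angles, `E`, muscle lengths, muscle inputs), integrated error,
#'   instability flag, spike and storage logs, the per-step norm of the
#'   recalled correction (`recall_norm`), and the updated store.
#' @export
run_reach <- function(model, target, geometry, config = default_config(),
                      store = NULL, seed = 1L, record_only = FALSE) {
  mcode <- model_code(model)
  cb_cfg <- config$cerebellum
  if (mcode > 0) {
    per <- cb_cfg[[paste0("model", mcode)]]
    gamma <- per$gamma; gain <- per$gain
  } else {
    gamma <- -2; gain <- 0
  }
  if (is.null(store))
    store <- cb_store(M_F = cb_cfg$M_F, gamma = gamma,
                      scales = cb_cfg$scales,
                      fuse_threshold = cb_cfg$fuse_threshold)
  pose <- ik_angles(target, geometry)
  lambda <- muscle_lengths(pose, geometry)
  olv <- olive_cells(config$olive$N3, config$olive$N7, config$olive$p,
                     config$olive$product_parse)
  res <- cpp_sim_reach(
    q0 = rep(0, 4), qd0 = rep(0, 4), target = target, geom = geometry$cpp,
    lambda = lambda, qdes = pose$q_s, delta_des = pose$delta,
    ctl = config$controller,
    olive = list(freq = olv$freq, phase = olv$phase, p = attr(olv, "p"),
                 product_parse = attr(olv, "product_parse")),
    cb = list(scales = store$scales, gamma = store$gamma, M_F = store$M_F,
              fuse_thresh = store$fuse_threshold, gain = gain,
              output_enabled = isTRUE(cb_cfg$output_enabled) && !record_only),
    sim = config$sim, model = mcode,
    store_F = store$F, store_W = store$W, seed = as.integer(seed))
  traj <- res$traj
  colnames(traj) <- c("t", "hand_x", "hand_y", "hand_z",
                      "alpha", "beta", "gamma", "delta", "E",
                      paste0("l", 1:11), paste0("u", 1:11))
  store$F <- res$store_F
  store$W <- res$store_W
  structure(list(
    model = model, target = target, seed = seed,
    trajectory = traj,
    integrated_error = integrated_error(traj[, "t"], traj[, 2:4], target),
    unstable = res$unstable,
    spikes = data.frame(time = unlist(res$spike_t),
                        source = unlist(res$spike_source)),
    storages = data.frame(t_cs = unlist(res$storage_tcs),
                          t = unlist(res$storage_t),
                          source = unlist(res$storage_source)),
    n_spikes = length(res$spike_t), n_storages = length(res$storage_tcs),
    recall_norm = as.numeric(res$recall_norm),
    store = store), class = "reach_result")
}

#' @export
print.reach_result <- function(x, ...) {
  cat("reach_result: model", x$model, "- integrated error",
      signif(x$integrated_error, 4), "m s,",
      x$n_spikes, "spikes,", x$n_storages, "storages",
      if (x$unstable) "(UNSTABLE)" else "", "\n")
  invisible(x)
}

#' Run a learning experiment
#'
#' The full protocol: for each target, a fresh cerebellar store and
#' `reaches` successive reaches with the store carried over (the arm state
#' is reset between reaches). Performance is the integrated error per
#' reach; per-reach means across targets are normalized by the first
#' reach's mean, with standard errors `SD/sqrt(n_targets)`.
#'
#' @param model `"none"` or 1, 2, 3, 4.
#' @param targets data frame with columns `x`, `y`, `z` in m (default: the
#'   eight standard test targets).
#' @param reaches number of successive reaches per target.
#' @param geometry an [arm_geometry()].
#' @param config see [default_config()].
#' @param seed master seed; per-reach olivary seeds are drawn from it.
#' @return an `experiment_table`: `errors` (targets x reaches, m s),
#'   `unstable` (logical matrix), `mean_error`, `norm_mean`, `norm_se`.
#' @export
run_experiment <- function(model, targets = reach_targets(), reaches = 8,
                           geometry = arm_geometry(),
                           config = default_config(), seed = 1L) {
  nt <- nrow(targets)
  set.seed(seed)
  reach_seeds <- matrix(sample.int(.Machine$integer.max - 1, nt * reaches),
                        nt, reaches)
  errors <- matrix(NA_real_, nt, reaches)
  unstable <- matrix(NA, nt, reaches)
  n_storages <- matrix(NA_integer_, nt, reaches)
  for (i in seq_len(nt)) {
    tgt <- as.numeric(targets[i, c("x", "y", "z")])
    store <- NULL
    for (r in seq_len(reaches)) {
      res <- run_reach(model, tgt, geometry, config, store = store,
                       seed = reach_seeds[i, r])
      errors[i, r] <- res$integrated_error
      unstable[i, r] <- res$unstable
      n_storages[i, r] <- res$n_storages
      store <- res$store
    }
  }
  mean_error <- colMeans(errors)
  norm_mean <- mean_error / mean_error[1]
  norm_se <- apply(errors / mean_error[1], 2, stats::sd) / sqrt(nt)
  structure(list(model = model, errors = errors, unstable = unstable,
                 n_storages = n_storages, mean_error = mean_error,
                 norm_mean = norm_mean, norm_se = norm_se, seed = seed),
            class = "experiment_table")
}

#' @export
print.experiment_table <- function(x, ...) {
  cat("experiment_table: model", x$model, "-", nrow(x$errors), "targets x",
      ncol(x$errors), "reaches\n")
  cat("normalized mean integrated error by reach:\n")
  print(round(x$norm_mean, 3))
  if (any(x$unstable))
    cat(sum(x$unstable), "reach(es) flagged unstable\n")
  invisible(x)
}

#' Write a reach trajectory as CSV
#'
#' Columns: `t`, hand xyz, the four joint angles, the 11 muscle lengths and
#' the 11 muscle inputs; one file per reach.
#'
#' @param result a `reach_result`.
#' @param path output file.
#' @export
write_trajectory <- function(result, path) {
  utils::write.csv(as.data.frame(result$trajectory), path, row.names = FALSE)
  invisible(path)
}
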