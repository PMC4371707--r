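#' Context component scales
#'
#' Per-component normalization constants applied before the recall distance
#' `||f - v||^2` is computed. The context concatenates heterogeneous units,
#' so without scaling, metres and radians would weigh arbitrarily. Defaults:
#' lengths (the error E) x10, rates x1, quaternion components x1, efferent
#' commands x5. Setting a scale to 0 masks that component out of the
#' distance.
#'
#' @param error,error_rate scales of E and its derivative.
#' @param quat,quat_rate scales of the shoulder quaternion and its rate.
#' @param elbow,elbow_rate scales of the elbow angle and rate.
#' @param command scale of the 11 efferent commands.
#' @param desired_quat,desired_elbow scales of the desired pose.
#' @return numeric vector of 28 scales in context order.
#' @export
context_scales <- function(error = 10, error_rate = 1, quat = 1,
                           quat_rate = 1, elbow = 1, elbow_rate = 1,
                           command = 5, desired_quat = 1,
                           desired_elbow = 1) {
  c(error, error_rate, rep(quat, 4), rep(quat_rate, 4), elbow, elbow_rate,
    rep(command, 11), rep(desired_quat, 4), desired_elbow)
}

#' Cerebellar feature store
#'
#' The microcomplex memory: a set of "error-prone areas", each a feature
#' vector (a 28-component sensorimotor context), a corrective 11-vector of
#' muscle commands, and one shared kernel radius. The kernel exponent
#' `gamma` must be negative: the printed recall kernel `exp(gamma * D_N)`
#' only decays with distance for `gamma < 0`.
#'
#' @param M_F maximum number of stored feature vectors.
#' @param gamma kernel exponent (< 0); larger magnitude means a smaller
#'   kernel radius.
#' @param scales see [context_scales()].
#' @param fuse_threshold closeness threshold (scaled units) below which a
#'   new entry fuses with its nearest stored neighbor.
#' @param n_context,n_muscles dimensions of the feature and correction
#'   vectors.
#' @return a `cb_store` object.
#' @export
cb_store <- function(M_F = 32, gamma = -2, scales = context_scales(),
                     fuse_threshold = 0.5, n_context = 28, n_muscles = 11) {
  if (gamma >= 0)
    stop("gamma must be negative: a nonnegative kernel exponent makes the ",
         "recall kernel grow with distance")
  stopifnot(M_F >= 1, fuse_threshold >= 0)
  structure(list(F = matrix(numeric(0), 0, n_context),
                 W = matrix(numeric(0), 0, n_muscles),
                 M_F = as.integer(M_F), gamma = gamma, scales = scales,
                 fuse_threshold = fuse_threshold,
                 meta = data.frame(t_cs = numeric(0), t_store = numeric(0),
                                   source = numeric(0))),
            class = "cb_store")
}

#' @export
print.cb_store <- function(x, ...) {
  cat("cb_store:", nrow(x$F), "/", x$M_F, "entries, gamma =", x$gamma, "\n")
  invisible(x)
}

#' Context lookback before a complex spike
#'
#' The stored feature vector is the context as it was
#' `tau_v - tau_p + (t - t_cs)/2` before the complex spike: the visual delay
#' minus the proprioceptive delay, plus half the time the error kept
#' increasing after the spike.
#'
#' @param t_cs spike time (s).
#' @param t current time (s), `t >= t_cs`.
#' @param tau_v visual delay (s).
#' @param tau_p proprioceptive delay (s).
#' @return lookback (s) measured backwards from the spike.
#' @export
context_lookback_time <- function(t_cs, t, tau_v = 0.150, tau_p = 0.025) {
  stopifnot(t >= t_cs)
  tau_v - tau_p + (t - t_cs) / 2
}

#' Correction from efferent copies (model 1)
#'
#' The corrective command stored with a feature vector is the time-average
#' of the central controller's muscle commands over the error-increase
#' episode, shifted back by `tau_v - tau_p` so the window covers the
#' commands issued while the error was actually increasing, and scaled by
#' `gain`.
#'
#' @param times sample times (s) of the efference history.
#' @param efference matrix, one row per sample, 11 columns.
#' @param t_cs,t spike time and storage time (s).
#' @param tau_v,tau_p visual and proprioceptive delays (s).
#' @param gain correction gain.
#' @return corrective 11-vector.
#' @export
correction_from_efference <- function(times, efference, t_cs, t,
                                      tau_v = 0.150, tau_p = 0.025,
                                      gain = 1) {
  a <- t_cs - (tau_v - tau_p)
  b <- t - (tau_v - tau_p)
  sel <- which(times >= a - 1e-9 & times <= b + 1e-9)
  if (length(sel) == 0)
    sel <- max(1, which.min(abs(times - a)))
  gain * colMeans(efference[sel, , drop = FALSE])
}

#' Correction as a single-muscle contraction (models 2 and 3)
#'
#' @param muscle spiking muscle index (1-based).
#' @param amplitude contraction amplitude.
#' @param n number of muscles.
#' @return corrective vector, zero except `amplitude` at `muscle`.
#' @export
correction_from_muscle <- function(muscle, amplitude, n = 11) {
  stopifnot(muscle >= 1, muscle <= n)
  w <- rep(0, n)
  w[muscle] <- amplitude
  w
}

#' Correction from proprioceptive signals (model 4)
#'
#' Per muscle, the correction is proportional to the product of how much
#' longer than its target the muscle is and how fast it is elongating:
#' `w_i = gain * [l_avg_i - lambda_i]+ * [ldot_i]+`.
#'
#' @param l_avg average muscle lengths over a brief window before the error
#'   stopped increasing (m).
#' @param lambda target lengths (m).
#' @param ldot length derivatives (m/s).
#' @param gain correction gain.
#' @return corrective 11-vector.
#' @export
correction_model4 <- function(l_avg, lambda, ldot, gain = 1) {
  stopifnot(length(l_avg) == length(lambda), length(ldot) == length(lambda))
  gain * pmax(l_avg - lambda, 0) * pmax(ldot, 0)
}

#' Add an entry to the store (with fusion)
#'
#' When the new feature vector lies within `fuse_threshold` (scaled units)
#' of its nearest stored neighbor, or the store already holds `M_F`
#' entries, the newcomer fuses with that neighbor: both are replaced by the
#' midpoint of their feature vectors and of their correction vectors.
#' Otherwise the entry is appended. The store never exceeds `M_F` entries.
#'
#' @param store a [cb_store()].
#' @param f feature vector (28 components).
#' @param w correction vector (11 components).
#' @param t_cs,t_store,source optional bookkeeping recorded in `store$meta`.
#' @return the updated store.
#' @export
cb_add <- function(store, f, w, t_cs = NA_real_, t_store = NA_real_,
                   source = NA_real_) {
  stopifnot(length(f) == ncol(store$F), length(w) == ncol(store$W))
  n0 <- nrow(store$F)
  res <- cpp_store_add(store$F, store$W, f, w, store$scales, store$M_F,
                       store$fuse_threshold)
  store$F <- res$F
  store$W <- res$W
  if (nrow(store$F) > n0)
    store$meta <- rbind(store$meta,
                        data.frame(t_cs = t_cs, t_store = t_store,
                                   source = source))
  store
}

#' Radial-basis-function recall
#'
#' For the current context `v`, squared scaled distances
#' `D(i) = ||f(i) - v||^2` to every stored feature vector are normalized as
#' `D_N = (M_F / ||D||) D` and each correction enters the output weighted by
#' `exp(gamma * D_N(i))`. An empty store returns zero; `||D|| = 0` (exact
#' hit on every entry) yields full corrections.
#'
#' @param store a [cb_store()].
#' @param v current context (28 components).
#' @return summed corrective 11-vector.
#' @export
cb_recall <- function(store, v) {
  stopifnot(length(v) == ncol(store$F))
  as.numeric(cpp_recall(store$F, store$W, v, store$scales, store$gamma,
                        store$M_F))
}

#' Serialize / restore a cerebellar store
#'
#' JSON round-trip for inspection and warm restarts.
#'
#' @param store a [cb_store()].
#' @param path file path.
#' @return `cb_load` returns the restored store.
#' @export
cb_save <- function(store, path) {
  obj <- list(F = store$F, W = store$W, M_F = store$M_F,
              gamma = store$gamma, scales = store$scales,
              fuse_threshold = store$fuse_threshold, meta = store$meta)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname cb_save
#' @export
cb_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- cb_store(M_F = obj$M_F, gamma = obj$gamma, scales = obj$scales,
                 fuse_threshold = obj$fuse_threshold)
  if (length(obj$F) > 0) {
    st$F <- matrix(obj$F, ncol = ncol(st$F))
    st$W <- matrix(obj$W, ncol = ncol(st$W))
  }
  if (!is.null(obj$meta) && length(obj$meta) > 0)
    st$meta <- as.data.frame(obj$meta)
  st
}
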