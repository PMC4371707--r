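#' Inferior olivary cell population
#'
#' A population of olivary cells with subthreshold membrane oscillations:
#' `N3` cells at 3 Hz and `N7` at 7 Hz. Phases within each subpopulation are
#' evenly spaced so the whole oscillation cycle is covered. A cell's
#' probability of emitting a complex spike depends on the phase of its
#' oscillation and on sigmoidal gates driven by the visual error and the
#' positive part of its derivative; a 200 ms refractory period limits each
#' cell's rate.
#'
#' @param N3,N7 number of 3 Hz and 7 Hz cells.
#' @param p oscillation modulation amplitude (dimensionless).
#' @param product_parse logical; with `TRUE` (default) the oscillation term
#'   `p cos + 1` multiplies the product of the two sigmoidal gates. The
#'   alternative reading adds the gated term to the raw oscillation.
#' @return an `olive_cells` object: data frame of `freq` (Hz), `phase` (s),
#'   `last_spike` (s), plus parameters as attributes.
#' @export
olive_cells <- function(N3 = 10, N7 = 10, p = 0.1, product_parse = TRUE) {
  stopifnot(p >= 0, p <= 1)
  phase3 <- if (N3 > 0) (seq_len(N3) - 1) / N3 * (1 / 3) else numeric(0)
  phase7 <- if (N7 > 0) (seq_len(N7) - 1) / N7 * (1 / 7) else numeric(0)
  cells <- data.frame(freq = c(rep(3, N3), rep(7, N7)),
                      phase = c(phase3, phase7),
                      last_spike = rep(-Inf, N3 + N7))
  structure(cells, p = p, product_parse = product_parse,
            class = c("olive_cells", "data.frame"))
}

#' Complex-spike probability from the visual error
#'
#' For a cell with angular frequency `2*pi*freq` and phase `phase` the
#' per-step spike probability is
#' `(p cos(w (t - phase)) + 1) / ((1 + exp(5 - E)) (1 + exp(30 - 15 [E']+)))`,
#' clipped to `[0, 1]`. `E` and `[E']+` are expressed in gating units (cm
#' and cm/s at reach scale) so that the printed thresholds 5 and 30 fall
#' inside the operating range. Probabilities are per evaluation step; spike
#' generation evaluates them every millisecond.
#'
#' @param E visual error in gating units (cm).
#' @param Edot_pos positive part of its derivative (cm/s); must be >= 0.
#' @param freq cell oscillation frequency (Hz).
#' @param phase cell phase offset (s).
#' @param t time (s).
#' @param p oscillation modulation amplitude in \[0, 1\].
#' @param product_parse see [olive_cells()].
#' @return spike probability in \[0, 1\].
#' @export
visual_spike_probability <- function(E, Edot_pos, freq, phase, t, p = 0.1,
                                     product_parse = TRUE) {
  stopifnot(Edot_pos >= 0, p >= 0, p <= 1)
  cpp_spike_probability(E, Edot_pos, freq, phase, t, p, product_parse)
}

#' Generate visual-error complex spikes
#'
#' One Bernoulli draw per cell against [visual_spike_probability()]; a cell
#' spikes only if the draw succeeds and it has not spiked in the last
#' 200 ms. Uses R's RNG: seed with `set.seed()` for reproducible trains.
#'
#' @param E,Edot visual error and derivative in gating units (cm, cm/s).
#' @param cells an [olive_cells()] population.
#' @param t time (s).
#' @return list with `spikes` (data frame: `time`, `cell`) and the updated
#'   `cells`.
#' @export
generate_visual_spikes <- function(E, Edot, cells, t) {
  p <- attr(cells, "p"); parse <- attr(cells, "product_parse")
  Edp <- max(Edot, 0)
  P <- vapply(seq_len(nrow(cells)), function(i)
    cpp_spike_probability(E, Edp, cells$freq[i], cells$phase[i], t, p, parse),
    numeric(1))
  draws <- stats::runif(nrow(cells))
  fire <- draws < P & (t - cells$last_spike) >= 0.200
  cells$last_spike[fire] <- t
  list(spikes = data.frame(time = rep(t, sum(fire)), cell = which(fire)),
       cells = cells)
}

#' Proprioceptive complex spikes
#'
#' Per-muscle rule-based spikes: muscle `i` spikes iff (1) its length is
#' increasing, (2) its length exceeds its target length, and (3) it has not
#' spiked in the last 200 ms. With `require_visual` (the visual-error
#' constraint) a fourth condition is added: the visual error must be
#' increasing.
#'
#' @param l muscle lengths (m), length 11.
#' @param ldot length derivatives (m/s).
#' @param lambda target lengths (m).
#' @param last_spike_times per-muscle time of last spike (s).
#' @param t time (s).
#' @param require_visual logical; add the visual-error condition.
#' @param Edot visual error derivative (m/s), needed when `require_visual`.
#' @return list with `spikes` (data frame: `time`, `muscle`) and updated
#'   `last_spike_times`.
#' @export
proprioceptive_spikes <- function(l, ldot, lambda, last_spike_times, t,
                                  require_visual = FALSE, Edot = NULL) {
  stopifnot(length(l) == length(lambda), length(ldot) == length(l))
  fire <- ldot > 0 & l > lambda & (t - last_spike_times) >= 0.200
  if (require_visual) {
    stopifnot(!is.null(Edot))
    fire <- fire & Edot > 0
  }
  last_spike_times[fire] <- t
  list(spikes = data.frame(time = rep(t, sum(fire)), muscle = which(fire)),
       last_spike_times = last_spike_times)
}
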