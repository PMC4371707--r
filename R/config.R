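#' Default simulation configuration
#'
#' Nested list of all tunable parameters outside the arm geometry:
#' `controller` (Eq.-style gain cascade, output filter, integral gain,
#' proprioceptive and visual delays), `olive` (population sizes, oscillation
#' modulation `p`, formula parse), `cerebellum` (store size, kernel
#' exponent, correction gain and fusion threshold per model variant), and
#' `sim` (horizon, control and physics steps, gravity flag, instability
#' bound). Models 2 and 3 ship with smaller kernel radii (larger `|gamma|`)
#' and smaller correction amplitudes than models 1 and 4, which individual
#' muscle corrections require for stability.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    controller = list(g_l = 2, g_v = 1, tau_filter = 0.05,
                      k_integral = 0.25, tau_p = 0.025, tau_v = 0.150),
    olive = list(N3 = 10, N7 = 10, p = 0.1, product_parse = TRUE),
    cerebellum = list(
      M_F = 32, fuse_threshold = 0.2, scales = context_scales(),
      output_enabled = TRUE,
      model1 = list(gamma = -0.35, gain = 1.5),
      model2 = list(gamma = -3, gain = 0.002),
      model3 = list(gamma = -0.7, gain = 0.05),
      model4 = list(gamma = -0.5, gain = 250)),
    sim = list(T = 4, dt_ctrl = 1e-3, dt_phys = 5e-4, gravity = FALSE,
               qd_max = 20))
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it (recursively) over
#' [default_config()], so partial files only need the keys they change.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}
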