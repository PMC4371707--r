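# Shared simulation results, computed once per test run. The learning
# experiments and baseline reaches are used by several test files.

sim_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = sim_cache)) assign(key, expr, envir = sim_cache)
  get(key, envir = sim_cache)
}

test_geometry <- function() cache_get("geom", arm_geometry())

test_experiment <- function(model) {
  cache_get(paste0("exp_", model),
            run_experiment(model, geometry = test_geometry(),
                           config = default_config(), seed = 42))
}

baseline_reaches <- function() {
  cache_get("baseline", {
    g <- test_geometry()
    tg <- reach_targets()
    lapply(seq_len(nrow(tg)), function(i)
      run_reach("none", as.numeric(tg[i, c("x", "y", "z")]), g))
  })
}
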