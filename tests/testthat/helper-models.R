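## Shared, lazily built model fixtures. Equilibrated models and the common
## stimulus amplitude are cached for the whole test session because several
## files (and the acceptance suite) reuse them.

.fixture_cache <- new.env(parent = emptyenv())

get_model <- function(variant) {
  key <- paste0("model_", variant)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- init_steady_state(build_model(variant))
  .fixture_cache[[key]]
}

## common stimulus intensity: 1.5x the control model's threshold (the train
## protocol emulates drug application at fixed stimulation intensity)
get_common_amp <- function() {
  if (is.null(.fixture_cache$amp))
    .fixture_cache$amp <- 1.5 * find_stim_threshold(get_model("control"))
  .fixture_cache$amp
}

get_velocity <- function(variant) {
  key <- paste0("vel_", variant)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- measure_velocity(get_model(variant))$velocity
  .fixture_cache[[key]]
}

## single-bouton model (one segment, no axial coupling) for integrator
## oracle comparisons; sliced out of the full model so that all membrane
## parameters are identical
single_bouton_model <- function(variant = "control") {
  m <- build_model(variant)
  i <- m$bouton_center[1]
  for (f in c("area", "pos", "cm_pF", "g_nav", "g_kv", "g_leak_na",
              "g_leak_k", "g_hcn_na", "g_hcn_k", "seg_type", "seg_sec",
              "chain_mask", "v"))
    m[[f]] <- m[[f]][i]
  m$gates <- m$gates[i, , drop = FALSE]
  m$g_axial <- numeric(0)
  m$n_seg <- 1L
  m$bouton_center <- 1L
  init_steady_state(m)
}
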