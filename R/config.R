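#' Load a model/protocol configuration
#'
#' Reads a YAML configuration whose defaults reproduce the published model
#' constants exactly (see `inst/extdata/default_config.yaml`; physical
#' constants carry their unit in the key name). Keys present in `path`
#' override the defaults; unknown keys are an error listing them.
#'
#' @param path optional YAML file with overrides; `NULL` for the defaults.
#' @return named list of class `run_config`, with attribute `overridden`
#'   naming any overridden keys.
#' @export
load_config <- function(path = NULL) {
  default_path <- system.file("extdata", "default_config.yaml",
                              package = "hcnax", mustWork = TRUE)
  cfg <- yaml::read_yaml(default_path)
  overridden <- character(0)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    for (k in names(user)) cfg[[k]] <- user[[k]]
    overridden <- names(user)
  }
  structure(cfg, class = "run_config", overridden = overridden)
}

#' Build an axon model from a configuration
#'
#' @param variant model variant, see [build_model()].
#' @param config a [load_config()] result.
#' @return an [axon_model].
#' @export
build_model_from_config <- function(variant = "control",
                                    config = load_config()) {
  geo <- axon_geometry(
    n_units = config$n_units,
    bouton_len = config$bouton_len_um, bouton_diam = config$bouton_diam_um,
    internode_len = config$internode_len_um,
    internode_diam = config$internode_diam_um,
    wm_len = config$wm_len_um, wm_diam = config$wm_diam_um,
    nseg_bouton = config$nseg_bouton,
    nseg_internode = config$nseg_internode, nseg_wm = config$nseg_wm)
  mem <- membrane_spec(
    cm = config$cm_uF_per_cm2, ri = config$ri_ohm_cm,
    e_na = config$e_na_mV, e_k = config$e_k_mV, e_hcn = config$e_hcn_mV,
    myelin_factor = config$myelin_factor,
    wm_myelinated = config$wm_myelinated)
  den <- channel_densities(
    g_nav = config$g_nav_pS_per_um2, g_kv = config$g_kv_pS_per_um2,
    g_leak_na = config$g_leak_na_pS_per_um2,
    g_leak_k = config$g_leak_k_pS_per_um2,
    g_hcn = config$g_hcn_pS_per_um2,
    g_hcn_axon = config$g_hcn_axon_pS_per_um2)
  hcn <- rate_params(config$hcn_A, config$hcn_v_half_mV,
                     config$hcn_v_alpha_mV, config$hcn_v_beta_mV,
                     label = "config", rate_unit = config$hcn_rate_unit)
  build_model(variant, geometry = geo, membrane = mem, densities = den,
              hcn = if (variant == "camp_1mM") NULL else hcn)
}
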