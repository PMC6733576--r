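#' Immunogold particle density
#'
#' @param n particle count, >= 0.
#' @param area_um2 membrane area (µm²), > 0.
#' @return density (particles/µm²).
#' @export
particle_density <- function(n, area_um2) {
  if (any(n < 0)) stop("count must be >= 0")
  if (any(area_um2 <= 0)) stop("area must be > 0")
  n / area_um2
}

#' Background labeling as a percentage of specific labeling
#'
#' @param bg_density background (non-specific) density (particles/µm²).
#' @param specific_density specific labeling density (particles/µm²), > 0.
#' @return percent, `100 * bg / specific`.
#' @export
background_fraction <- function(bg_density, specific_density) {
  if (any(specific_density <= 0)) stop("specific density must be > 0")
  100 * bg_density / specific_density
}

#' Channel density implied by a conductance density
#'
#' @param g_density conductance density (pS/µm²).
#' @param unitary_g single-channel conductance (pS), > 0 (1.7 pS for HCN2).
#' @return channels/µm².
#' @export
channels_per_area <- function(g_density, unitary_g = 1.7) {
  if (any(unitary_g <= 0)) stop("unitary conductance must be > 0")
  g_density / unitary_g
}

#' Quantify immunogold counts from a CSV table
#'
#' Reads a table with columns `label`, `n`, `area_um2`, computes densities,
#' and (optionally) writes a JSON report. Display rounding follows the
#' field's convention (1 decimal for densities); raw values are retained.
#'
#' @param path input CSV.
#' @param json_path optional output JSON.
#' @return data.frame with `label`, `n`, `area_um2`, `density`,
#'   `density_display`.
#' @export
quantify_particles <- function(path, json_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "n", "area_um2")
  if (!all(need %in% names(df)))
    stop("particle CSV must have columns: ", paste(need, collapse = ", "))
  df$density <- particle_density(df$n, df$area_um2)
  df$density_display <- round(df$density, 1)
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, auto_unbox = TRUE, digits = NA)
  df
}
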