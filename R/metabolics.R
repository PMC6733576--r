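ELEMENTARY_CHARGE <- 1.602176634e-19   # C
NA_PER_ATP <- 3                        # Na+/K+-ATPase stoichiometry

#' Na+ charge influx by pathway
#'
#' Time-integrated inward Na+ current per membrane pathway (voltage-gated
#' NaV, Na+ leak, HCN Na+ branch), summed over segments (segment
#' conductances already carry the membrane area). Requires a simulation run
#' with `record_pathways = TRUE`.
#'
#' @param sim a `sim_result` from [integrate_model()] with recorded
#'   pathway currents.
#' @param window time window (ms, length 2); default the whole run.
#' @param include_wm include the white-matter cylinder (default FALSE: the
#'   bouton/internode chain only).
#' @return named numeric (pC, positive = influx): `nav`, `leak_na`,
#'   `hcn_na`, plus `total`.
#' @export
na_influx <- function(sim, window = NULL, include_wm = FALSE) {
  if (is.null(sim$currents))
    stop("simulation lacks pathway currents; rerun with record_pathways = TRUE")
  cur <- sim$currents$chain
  if (include_wm) cur <- cur + sim$currents$wm
  tm <- sim$t[-1] - sim$dt / 2          # step midpoints
  sel <- if (is.null(window)) rep(TRUE, length(tm))
         else tm >= window[1] & tm <= window[2]
  paths <- c("nav", "leak_na", "hcn_na")
  out <- vapply(paths, function(p)
    -sum(cur[sel, p]) * sim$dt / 1000, 0)   # inward (negative) -> +pC
  c(out, total = sum(out))
}

#' Convert Na+ charge influx to ATP demand
#'
#' The Na+/K+-ATPase extrudes 3 Na+ per ATP hydrolyzed, so
#' `ATP = (charge / e) / 3` with `e` the elementary charge.
#'
#' @param charge_pC Na+ charge (pC), >= 0; vectorized.
#' @return ATP molecule count.
#' @export
atp_from_na <- function(charge_pC) {
  if (any(charge_pC < 0)) stop("charge must be >= 0")
  (charge_pC * 1e-12) / ELEMENTARY_CHARGE / NA_PER_ATP
}

#' Resting metabolic cost of the axon
#'
#' Na+ influx per second at the resting steady state over the
#' bouton/internode chain, normalized by the chain length and converted to
#' ATP molecules per mm of axon per second.
#'
#' @param model equilibrated [axon_model].
#' @param t_window simulated window used for the rate estimate (ms).
#' @param dt integration step (ms); the model is stationary so a coarse
#'   step suffices.
#' @param include_wm include the white-matter cylinder in both influx and
#'   length basis.
#' @return list of class `energy_report`: `atp_rest_per_mm_s`,
#'   `na_charge_by_pathway` (pC over `t_window`), `length_basis_um`,
#'   `window`.
#' @export
resting_cost <- function(model, t_window = 100, dt = 0.1,
                         include_wm = FALSE) {
  if (!model$at_rest) stop("model must be at steady state (init_steady_state)")
  sim <- integrate_model(model, stimuli = list(), dt = dt, t_end = t_window,
                         record = model$bouton_center[1],
                         record_pathways = TRUE)
  chg <- na_influx(sim, include_wm = include_wm)
  geo <- model$geometry
  len_um <- geo$n_units * (geo$bouton_len + geo$internode_len) +
    if (include_wm) geo$wm_len else 0
  influx_per_s <- chg[["total"]] * (1000 / t_window)       # pC/s
  atp <- atp_from_na(influx_per_s) / (len_um / 1000)       # per mm
  structure(list(atp_rest_per_mm_s = atp, na_charge_by_pathway = chg,
                 length_basis_um = len_um, window = c(0, t_window)),
            class = "energy_report")
}

#' Metabolic cost of one propagated action potential
#'
#' Evokes a single action potential, integrates the Na+ influx from
#' stimulus onset to `post_peak` ms after the last bouton's peak, subtracts
#' the resting influx over an equal window, and normalizes per mm of the
#' bouton/internode chain.
#'
#' @param model equilibrated [axon_model].
#' @param stim_amplitude pulse amplitude (pA); `NULL` for 1.5x threshold.
#' @param stim_duration pulse duration (ms).
#' @param post_peak window extension past the last AP peak (ms).
#' @param dt integration step (ms).
#' @param include_wm include the white-matter cylinder.
#' @return list of class `energy_report`: `atp_per_ap_per_mm`,
#'   `na_charge_by_pathway` (AP window, resting-subtracted, pC),
#'   `length_basis_um`, `window`.
#' @export
ap_cost <- function(model, stim_amplitude = NULL, stim_duration = 0.1,
                    post_peak = 10, dt = 0.00125, include_wm = FALSE) {
  if (!model$at_rest) stop("model must be at steady state (init_steady_state)")
  if (is.null(stim_amplitude))
    stim_amplitude <- 1.5 * find_stim_threshold(model, dt = dt)
  rec <- model$bouton_center[length(model$bouton_center)]
  onset <- 0.5
  probe <- integrate_model(model,
    stimuli = list(list(site = 1L, onset = onset, duration = stim_duration,
                        amplitude = stim_amplitude)),
    dt = dt, t_end = 20, record = rec, record_pathways = TRUE)
  pk <- .refine_peak(probe$t, probe$vm[, 1])
  subthreshold <- pk$y <= 0
  t_end <- if (subthreshold) 20 else pk$t + post_peak
  win <- c(onset, min(t_end, max(probe$t)))
  chg_ap <- na_influx(probe, window = win, include_wm = include_wm)
  ## resting influx over an equal window
  rest <- integrate_model(model, stimuli = list(), dt = 0.05,
                          t_end = diff(win), record = rec,
                          record_pathways = TRUE)
  chg_rest <- na_influx(rest, include_wm = include_wm)
  net <- pmax(chg_ap - chg_rest, 0)
  geo <- model$geometry
  len_um <- geo$n_units * (geo$bouton_len + geo$internode_len) +
    if (include_wm) geo$wm_len else 0
  structure(list(atp_per_ap_per_mm = atp_from_na(net[["total"]]) /
                   (len_um / 1000),
                 na_charge_by_pathway = net, length_basis_um = len_um,
                 window = win, subthreshold = subthreshold),
            class = "energy_report")
}

#' HCN share of the axonal energy budget at a firing rate
#'
#' For a model pair with and without the HCN conductance,
#' \deqn{share(f) = \frac{rest_{with} - rest_{without}}
#'   {rest_{without} + f \cdot ap\_cost}}
#' (all terms per mm and per second): the extra resting cost imposed by the
#' HCN conductance relative to the total budget at firing rate `f`.
#' Strictly decreasing in `f`.
#'
#' @param rest_with,rest_without resting costs (ATP/mm/s), e.g. from
#'   [resting_cost()] of the control and no-HCN models.
#' @param ap_cost_per_mm AP cost (ATP/mm), e.g. from [ap_cost()].
#' @param frequency firing rate(s) (Hz), >= 0; vectorized.
#' @return share (dimensionless fraction), same length as `frequency`.
#' @export
cost_share <- function(rest_with, rest_without, ap_cost_per_mm, frequency) {
  if (any(frequency < 0)) stop("'frequency' must be >= 0")
  (rest_with - rest_without) / (rest_without + frequency * ap_cost_per_mm)
}

#' @export
print.energy_report <- function(x, ...) {
  if (!is.null(x$atp_rest_per_mm_s))
    cat(sprintf("Resting cost: %.4g ATP/mm/s\n", x$atp_rest_per_mm_s))
  if (!is.null(x$atp_per_ap_per_mm))
    cat(sprintf("AP cost: %.4g ATP/mm\n", x$atp_per_ap_per_mm))
  cat("Na+ charge by pathway (pC):\n")
  print(round(x$na_charge_by_pathway, 6))
  invisible(x)
}

#' Serialize an energy report to JSON
#'
#' @param report an `energy_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_json <- function(report, path) {
  x <- unclass(report)
  x$na_charge_by_pathway <- as.list(x$na_charge_by_pathway)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
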