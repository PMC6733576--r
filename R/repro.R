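#' Recompute the package's headline quantities from scratch
#'
#' Runs the end-to-end reproduction pipelines and returns the headline
#' numbers of each analysis: the steady-state midpoints of the two HCN
#' gating models, the tail-current pipeline recovery of the population
#' activation midpoint and of the cAMP-induced shift, the Hill EC50
#' recovery, the resting potential of the HCN-blocked compartmental model,
#' and the immunogold/channel-density quantification arithmetic. All
#' stochastic steps derive their RNG streams from `seed`.
#'
#' @param seed integer seed for every stochastic step.
#' @param n_hill_reps replicates for the Hill EC50 recovery (>= 100).
#' @param quiet suppress progress messages.
#' @return named list; each element is a list with `value` (the number, in
#'   the units used throughout the package) and `n` (the problem size
#'   used).
#' @export
repro_targets <- function(seed = 1, n_hill_reps = 100L, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  out <- list()

  ## steady-state midpoints of the two gating models (mV)
  mid <- function(p)
    stats::uniroot(function(V) steady_state(V, p) - 0.5, c(-150, -60),
                   tol = 1e-10)$root
  say("solving HH steady-state midpoints")
  out$t1 <- list(value = mid(hh_params("0mM_cAMP")), n = 1)
  out$t2 <- list(value = mid(hh_params("1mM_cAMP")), n = 1)

  ## tail-current pipeline: population midpoint recovery (0 mM, n = 36
  ## cells, between-cell SD 4.8 mV = 0.8 * sqrt(36)); slope 9 mV
  say("running tail-current population pipeline (0 mM)")
  set.seed(seed)
  r0 <- recover_population_v_half(-103.3, cell_sd = 4.8, n_cells = 36L)
  out$t3 <- list(value = r0$mean, n = 36)

  ## the same pipeline for 1 mM cAMP (n = 16, SEM class 1.2 mV) minus 0 mM
  say("running tail-current population pipeline (1 mM)")
  set.seed(seed + 1L)
  r1 <- recover_population_v_half(-86.6, cell_sd = 1.2 * sqrt(16),
                                  n_cells = 16L)
  out$t4 <- list(value = r1$mean - r0$mean, n = 52)

  ## Hill EC50 recovery: h = 1, s_max anchored to the 17 mV shift at 1 mM
  say("running Hill EC50 recovery (", n_hill_reps, " replicates)")
  set.seed(seed + 2L)
  ec50s <- vapply(seq_len(n_hill_reps), function(r) {
    d <- gen_dose_response(ec50 = 40.4, s_max = anchor_s_max(), h = 1,
                           sem = 1.2)
    fit_hill(d$points, fix_h = 1)$ec50
  }, 0)
  out$t5 <- list(value = stats::median(ec50s), n = n_hill_reps)

  ## resting potential of the compartmental model without HCN (mV)
  say("equilibrating the HCN-blocked compartmental model")
  mn <- init_steady_state(build_model("no_hcn"))
  out$t6 <- list(value = mn$v[mn$bouton_center[8]], n = mn$n_seg)

  ## quantification arithmetic (particles/um2, %, channels/um2)
  out$t7 <- list(value = round(particle_density(1260, 73.65), 1), n = 1260)
  out$t8 <- list(value = round(background_fraction(
    particle_density(40, 60.5), particle_density(1260, 73.65)), 1), n = 40)
  out$t9 <- list(value = round(channels_per_area(0.3, 1.7), 2), n = 1)

  out
}
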