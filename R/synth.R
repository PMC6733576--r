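## Seeded generators for every input class the analysis pipelines consume.
## Each generator returns its data plus a manifest (generator name, full
## parameter set, seed, embedded ground truth) sufficient to regenerate the
## dataset bit-identically and to score downstream recovery.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Generate a synthetic HCN voltage-clamp dataset
#'
#' Simulates ZD7288-sensitive current sweeps from the single-gate HH model:
#' the command steps from a holding potential to each conditioning voltage
#' and back, the gate relaxes exactly along the linear gate ODE, and the
#' current is `g_max * m(t) * (V - e_hcn)` plus additive Gaussian noise.
#'
#' @param p HCN gate parameters ([rate_params()]).
#' @param steps conditioning voltages (mV).
#' @param holding holding (and tail) potential (mV).
#' @param t_cond conditioning-step duration (ms).
#' @param t_pre,t_tail pre-step and tail durations (ms).
#' @param sample_dt sample interval (ms).
#' @param g_max maximal HCN conductance (nS).
#' @param e_hcn HCN reversal potential (mV).
#' @param noise_sd additive current noise SD (pA); the default, `NULL`,
#'   uses 2% of the maximal HCN current amplitude.
#' @param seed RNG seed.
#' @return list: `sweeps` (list of [vc_sweep()]), `manifest`.
#' @export
gen_vclamp_dataset <- function(p, steps = seq(-80, -150, by = -10),
                               holding = -70, t_cond = 500,
                               t_pre = 20, t_tail = 100, sample_dt = 0.5,
                               g_max = 1, e_hcn = -23.3,
                               noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(p, "rate_params"))
  i_max <- abs(g_max * (min(steps) - e_hcn))
  if (is.null(noise_sd)) noise_sd <- 0.02 * i_max
  .with_seed(seed, {
    sweeps <- lapply(steps, function(vs) {
      t <- seq(0, t_pre + t_cond + t_tail, by = sample_dt)
      v <- ifelse(t < t_pre, holding,
           ifelse(t < t_pre + t_cond, vs, holding))
      m <- numeric(length(t))
      m[1] <- steady_state(holding, p)
      for (i in 2:length(t))
        m[i] <- gate_step(m[i - 1], v[i], sample_dt, p)
      i_pA <- g_max * m * (v - e_hcn)
      if (noise_sd > 0) i_pA <- i_pA + stats::rnorm(length(t), 0, noise_sd)
      vc_sweep(t, i_pA, v, meta = list(holding_mV = holding, step_mV = vs,
                                       drug = "ZD7288-subtracted"))
    })
    list(sweeps = sweeps,
         manifest = list(generator = "gen_vclamp_dataset",
                         params = unclass(p), steps = steps,
                         holding = holding, t_cond = t_cond, t_pre = t_pre,
                         t_tail = t_tail, sample_dt = sample_dt,
                         g_max = g_max, e_hcn = e_hcn, noise_sd = noise_sd,
                         seed = seed,
                         truth = list(v_half = p$v_half,
                                      k = 1 / (1 / p$v_alpha + 1 / p$v_beta))))
  })
}

#' Generate a population of cells with scattered activation midpoints
#'
#' Draws per-cell Boltzmann midpoints from
#' `Normal(true_v_half, cell_sd)` and produces one voltage-clamp dataset
#' per cell (slope factor `k`, symmetric HH rates). The between-cell SD is
#' calibrated as `SEM * sqrt(n)` of the printed population statistics.
#'
#' @param true_v_half generating population midpoint (mV).
#' @param cell_sd between-cell midpoint SD (mV).
#' @param n_cells number of cells (>= 2).
#' @param k Boltzmann slope factor (mV) of every cell.
#' @param A gate rate at midpoint (per second).
#' @param seed RNG seed.
#' @param ... passed to [gen_vclamp_dataset()].
#' @return list: `cells` (each a [gen_vclamp_dataset()] result), `manifest`
#'   (with the drawn per-cell midpoints as truth).
#' @export
gen_cell_population <- function(true_v_half, cell_sd, n_cells, k = 9,
                                A = 6.907, seed = NULL, ...) {
  if (n_cells < 2L) stop("need at least 2 cells")
  .with_seed(seed, {
    vh <- stats::rnorm(n_cells, true_v_half, cell_sd)
    cells <- lapply(vh, function(v0) {
      p <- rate_params(A, v0, 2 * k, 2 * k, label = "cell")
      gen_vclamp_dataset(p, seed = NULL, ...)
    })
    list(cells = cells,
         manifest = list(generator = "gen_cell_population",
                         true_v_half = true_v_half, cell_sd = cell_sd,
                         n_cells = n_cells, k = k, A = A, seed = seed,
                         truth = list(cell_v_half = vh)))
  })
}

#' Generate synthetic dose-response data
#'
#' Mean midpoint shifts on a Hill curve plus Gaussian noise of the printed
#' per-point SEM class.
#'
#' @param ec50 half-maximal concentration (µM).
#' @param s_max maximal shift (mV).
#' @param h Hill coefficient.
#' @param concs concentrations (µM).
#' @param sem per-point SEM (mV), recycled; also the noise SD.
#' @param seed RNG seed.
#' @return list: `points` ([dose_response_points()]), `manifest`.
#' @export
gen_dose_response <- function(ec50 = 40.4, s_max = 17.69, h = 1,
                              concs = c(30, 100, 300, 1000, 3000, 10000),
                              sem = 1.2, seed = NULL) {
  .with_seed(seed, {
    sem <- rep_len(sem, length(concs))
    mu <- hill(concs, ec50, s_max, h)
    shift <- mu + stats::rnorm(length(concs), 0, sem)
    list(points = dose_response_points(concs, shift, sem = sem),
         manifest = list(generator = "gen_dose_response", ec50 = ec50,
                         s_max = s_max, h = h, concs = concs, sem = sem,
                         seed = seed, truth = list(mu = mu)))
  })
}

#' Maximal Hill shift anchored to an observed shift at one concentration
#'
#' Inverts the Hill equation for `s_max` given the shift observed at
#' `conc`: with `h = 1`, a 17 mV shift at 1000 µM and EC50 40.4 µM implies
#' `s_max` of about 17.69 mV.
#'
#' @param shift_at_conc observed shift (mV).
#' @param conc concentration of the observation (µM).
#' @param ec50 half-maximal concentration (µM).
#' @param h Hill coefficient.
#' @return `s_max` (mV).
#' @export
anchor_s_max <- function(shift_at_conc = 17, conc = 1000, ec50 = 40.4,
                         h = 1) {
  shift_at_conc * (conc^h + ec50^h) / conc^h
}

#' Generate a synthetic two-electrode CAP experiment
#'
#' Produces compound-action-potential sweep pairs over a series of
#' timestamps. The instantaneous conduction velocity follows
#' `v(t) = baseline * (1 + rundown(t)) * (1 + effect * (1 - e^{-t/tau}))`
#' for `t > 0` (drug onset at 0), with a linear rundown; each electrode
#' records a biphasic difference-of-Gaussians waveform delayed by
#' `distance / v(t)`, plus noise and a brief stimulus marker at time zero.
#'
#' @param baseline_mps baseline velocity (m/s).
#' @param effect_pct programmed plateau drug effect (%; negative = slowing).
#' @param onset_min drug onset (min).
#' @param tau_min effect time constant (min).
#' @param rundown_pct_per_20min linear rundown (% per 20 min).
#' @param distances_um electrode distances from the stimulation site (µm),
#'   length 2 (prox, dist).
#' @param timestamps_min recording times (min).
#' @param trace_ms trace duration (ms).
#' @param sample_dt sample interval (ms).
#' @param width_ms Gaussian width of the CAP waveform (ms).
#' @param noise_sd additive noise SD (waveform units).
#' @param seed RNG seed.
#' @return list: `pairs` (list of [sweep_pair()]), `manifest` (with the
#'   velocity time-course as truth).
#' @export
gen_cap_recording <- function(baseline_mps = 0.30, effect_pct = -8,
                              onset_min = 0, tau_min = 2,
                              rundown_pct_per_20min = 0,
                              distances_um = c(400, 1300),
                              timestamps_min = seq(-5, 20),
                              trace_ms = 15, sample_dt = 0.02,
                              width_ms = 0.5, noise_sd = 0.02,
                              seed = NULL) {
  stopifnot(length(distances_um) == 2L, distances_um[2] > distances_um[1])
  vel_of_t <- function(tm) {
    eff <- ifelse(tm > onset_min,
                  effect_pct / 100 * (1 - exp(-(tm - onset_min) / tau_min)), 0)
    baseline_mps * (1 + rundown_pct_per_20min / 100 * tm / 20) * (1 + eff)
  }
  .with_seed(seed, {
    t <- seq(0, trace_ms, by = sample_dt)
    wave <- function(t0) {
      exp(-(t - t0)^2 / (2 * width_ms^2)) -
        0.6 * exp(-(t - t0 - width_ms)^2 / (2 * (1.4 * width_ms)^2))
    }
    marker <- ifelse(t <= 0.1, 2, 0)     # stimulus artifact marker
    pairs <- lapply(timestamps_min, function(tm) {
      v <- vel_of_t(tm)
      d_prox <- distances_um[1] / (v * 1000)   # µm / (µm/ms)
      d_dist <- distances_um[2] / (v * 1000)
      vp <- -wave(d_prox) + marker
      vd <- -wave(d_dist) + marker
      if (noise_sd > 0) {
        vp <- vp + stats::rnorm(length(t), 0, noise_sd)
        vd <- vd + stats::rnorm(length(t), 0, noise_sd)
      }
      sweep_pair(t, vp, vd,
                 distance_delta_um = diff(distances_um),
                 timestamp_min = tm)
    })
    list(pairs = pairs,
         manifest = list(generator = "gen_cap_recording",
                         baseline_mps = baseline_mps,
                         effect_pct = effect_pct, onset_min = onset_min,
                         tau_min = tau_min,
                         rundown_pct_per_20min = rundown_pct_per_20min,
                         distances_um = distances_um,
                         timestamps_min = timestamps_min,
                         trace_ms = trace_ms, sample_dt = sample_dt,
                         width_ms = width_ms, noise_sd = noise_sd,
                         seed = seed,
                         truth = list(velocity_mps = vel_of_t(timestamps_min))))
  })
}

#' Generate a synthetic current-clamp sag trace
#'
#' A hyperpolarizing step response composed of a fast charging exponential
#' (membrane time constant) and a slower depolarizing relaxation (sag).
#' The manifest stores the noise-free peak/steady-state deflections and
#' the resulting sag ratio as ground truth.
#'
#' @param rest resting potential (mV).
#' @param r_in input resistance (MΩ).
#' @param tau membrane time constant (ms).
#' @param sag_fraction steady-state deflection as a fraction of the early
#'   deflection (the programmed sag-ratio class).
#' @param tau_sag sag relaxation time constant (ms).
#' @param step_pA current step (pA), < 0.
#' @param t_step step duration (ms).
#' @param t_pre,t_post pre- and post-step durations (ms).
#' @param sample_dt sample interval (ms).
#' @param noise_sd additive voltage noise SD (mV).
#' @param seed RNG seed.
#' @return list: `t`, `v`, `manifest`.
#' @export
gen_sag_trace <- function(rest = -80, r_in = 800, tau = 15,
                          sag_fraction = 0.5, tau_sag = 60,
                          step_pA = -10, t_step = 300,
                          t_pre = 50, t_post = 100, sample_dt = 0.1,
                          noise_sd = 0, seed = NULL) {
  if (step_pA >= 0) stop("'step_pA' must be hyperpolarizing (< 0)")
  .with_seed(seed, {
    t <- seq(-t_pre, t_step + t_post, by = sample_dt)
    dv_early <- step_pA * r_in / 1000          # pA * MΩ -> µV -> /1000 mV
    dv_ss <- dv_early * sag_fraction
    defl <- function(tt) {
      d <- dv_early * (1 - exp(-tt / tau)) -
        (dv_early - dv_ss) * (1 - exp(-tt / tau_sag))
      d[tt < 0] <- 0
      d
    }
    v <- rest + defl(t) - defl(t - t_step)
    ## noise-free ground truth as an analysis would see it
    in_step <- t >= 0 & t <= t_step
    v_true <- rest + defl(t)
    v_peak <- min(v_true[in_step])
    v_steady <- mean(v_true[in_step & t >= 0.9 * t_step])
    ## input-resistance truth uses the last 10 ms (the measurement window)
    v_steady_rin <- mean(v_true[in_step & t >= t_step - 10])
    if (noise_sd > 0) v <- v + stats::rnorm(length(t), 0, noise_sd)
    list(t = t, v = v,
         manifest = list(generator = "gen_sag_trace", rest = rest,
                         r_in = r_in, tau = tau,
                         sag_fraction = sag_fraction, tau_sag = tau_sag,
                         step_pA = step_pA, t_step = t_step,
                         sample_dt = sample_dt, noise_sd = noise_sd,
                         seed = seed,
                         truth = list(
                           v_peak = v_peak, v_steady = v_steady,
                           sag_ratio = (v_steady - rest) / (v_peak - rest),
                           r_in = (v_steady_rin - rest) / step_pA * 1000)))
  })
}

#' Run the tail-current activation pipeline on a synthetic population
#'
#' Convenience wrapper: generates a cell population with
#' [gen_cell_population()], extracts tail-current activation points and
#' fits a per-cell Boltzmann, returning the recovered midpoints.
#'
#' @inheritParams gen_cell_population
#' @param ... passed to [gen_cell_population()].
#' @return list: `v_half` (recovered per-cell midpoints, mV), `mean`,
#'   `sem`, `manifest`.
#' @export
recover_population_v_half <- function(true_v_half, cell_sd, n_cells,
                                      seed = NULL, ...) {
  pop <- gen_cell_population(true_v_half, cell_sd, n_cells, seed = seed, ...)
  vh <- vapply(pop$cells, function(cell) {
    pts <- extract_tail_activation(cell$sweeps)
    fit_boltzmann(pts)$v_half
  }, 0)
  list(v_half = vh, mean = mean(vh),
       sem = stats::sd(vh) / sqrt(length(vh)), manifest = pop$manifest)
}
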