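#' Measure apparent input resistance and membrane time constant
#'
#' Injects a small hyperpolarizing current step into a bouton, reads the
#' steady-state voltage at the end of the step
#' (`r_in = (v_steady - v_rest)/i_step`) and fits a mono-exponential to the
#' initial decay of the voltage response for the apparent membrane time
#' constant.
#'
#' @param model an equilibrated [axon_model], or a trace given as
#'   `list(t =, v =)` with the step applied at `t = 0`.
#' @param i_step step amplitude (pA), default −10.
#' @param t_step step duration (ms), default 300.
#' @param site segment index for injection and recording (default: center
#'   bouton).
#' @param fit_window window after step onset used for the tau fit (ms).
#' @param dt integration step (ms) for model runs.
#' @return list of class `input_resistance_result`: `r_in` (MΩ), `tau_m`
#'   (ms), `v_rest`, `v_steady` (mV), `steady` (FALSE with a warning flag
#'   if the last 50 ms still drift).
#' @export
measure_input_resistance <- function(model, i_step = -10, t_step = 300,
                                     site = NULL, fit_window = c(0.5, 150),
                                     dt = 0.05) {
  if (inherits(model, "axon_model")) {
    if (is.null(site))
      site <- model$bouton_center[ceiling(length(model$bouton_center) / 2)]
    sim <- integrate_model(model,
      stimuli = list(list(site = site, onset = 5, duration = t_step,
                          amplitude = i_step)),
      dt = dt, t_end = t_step + 10, record = site)
    t <- sim$t - 5
    v <- sim$vm[, 1]
  } else {
    t <- model$t; v <- model$v
  }
  v_rest <- mean(v[t < 0])
  in_step <- t >= 0 & t <= t_step
  t_in <- t[in_step]; v_in <- v[in_step]
  v_steady <- mean(v_in[t_in >= t_step - 10])
  ## drift check over the last 50 ms of the step
  last <- t_in >= t_step - 50
  slope <- stats::coef(stats::lm(v_in[last] ~ t_in[last]))[2]
  steady <- abs(slope) < 2e-3   # mV/ms
  if (!steady) warning("no steady state reached within the step")
  r_in <- (v_steady - v_rest) / i_step * 1000   # mV/pA -> GΩ -> MΩ: *1e3
  fit <- fit_monoexp(list(t = t_in, i = v_in),
                     window = fit_window)
  structure(list(r_in = r_in, tau_m = fit$tau, v_rest = v_rest,
                 v_steady = v_steady, steady = steady),
            class = "input_resistance_result")
}

#' Measure the voltage sag of a hyperpolarizing response
#'
#' The sag ratio is the steady-state deflection divided by the peak
#' deflection, `(v_steady - v_rest)/(v_peak - v_rest)`; a sag-free
#' (monotonic) response gives a ratio of ~1, a pronounced sag a ratio well
#' below 1. The complementary convention `1 - ratio` is available via
#' `complement`.
#'
#' @param t time base (ms), step onset at `t = 0`.
#' @param v voltage trace (mV).
#' @param t_step step duration (ms).
#' @param complement return `1 - ratio` instead.
#' @return list of class `sag_result`: `v_rest`, `v_peak`, `v_steady`,
#'   `sag_ratio`, `flag` (TRUE when no distinct early peak exists and the
#'   ratio is reported as 1).
#' @export
measure_sag <- function(t, v, t_step, complement = FALSE) {
  v_rest <- mean(v[t < 0])
  in_step <- t >= 0 & t <= t_step
  v_in <- v[in_step]; t_in <- t[in_step]
  ipk <- which.min(v_in)
  v_peak <- v_in[ipk]
  v_steady <- mean(v_in[t_in >= t_step - 0.1 * t_step])
  if (v_peak >= v_rest) stop("response is not hyperpolarizing")
  flag <- FALSE
  if (t_in[ipk] > 0.9 * t_step ||
      abs(v_peak - v_steady) < 1e-9 * abs(v_peak - v_rest)) {
    ratio <- 1; flag <- TRUE
  } else {
    ratio <- (v_steady - v_rest) / (v_peak - v_rest)
  }
  if (complement) ratio <- 1 - ratio
  structure(list(v_rest = v_rest, v_peak = v_peak, v_steady = v_steady,
                 sag_ratio = ratio, flag = flag),
            class = "sag_result")
}

#' Run a current-clamp sag protocol on the model
#'
#' Finds a step amplitude whose peak hyperpolarization reaches
#' `target_peak`, then measures the sag with [measure_sag()].
#'
#' @param model equilibrated [axon_model].
#' @param target_peak desired peak voltage (mV), default −150.
#' @param t_step step duration (ms).
#' @param site injection/recording segment (default: center bouton).
#' @param dt integration step (ms).
#' @return a `sag_result` with additional field `i_step` (pA).
#' @export
run_sag_protocol <- function(model, target_peak = -150, t_step = 300,
                             site = NULL, dt = 0.05) {
  if (is.null(site))
    site <- model$bouton_center[ceiling(length(model$bouton_center) / 2)]
  v_rest <- model$v[site]
  run <- function(amp) {
    sim <- integrate_model(model,
      stimuli = list(list(site = site, onset = 5, duration = t_step,
                          amplitude = amp)),
      dt = dt, t_end = t_step + 20, record = site)
    list(t = sim$t - 5, v = sim$vm[, 1])
  }
  amp <- -50
  for (it in 1:3) {
    tr <- run(amp)
    pk <- min(tr$v)
    if (abs(pk - target_peak) < 1) break
    amp <- amp * (target_peak - v_rest) / (pk - v_rest)
  }
  out <- measure_sag(tr$t, tr$v, t_step)
  out$i_step <- amp
  out
}

## sub-sample peak time by 3-point quadratic interpolation
.refine_peak <- function(t, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(list(t = t[i], y = y[i]))
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(list(t = t[i], y = y2))
  delta <- 0.5 * (y1 - y3) / denom
  dt <- t[i + 1L] - t[i]
  list(t = t[i] + delta * dt, y = y2 - 0.25 * (y1 - y3) * delta)
}

#' Measure conduction velocity between two boutons
#'
#' Evokes a propagating action potential by a brief suprathreshold pulse at
#' the distal end of the white-matter cylinder and measures the peak-time
#' difference between two interior boutons, with quadratic sub-sample
#' refinement of each peak.
#'
#' @param model equilibrated [axon_model].
#' @param site_a,site_b bouton numbers (1 = closest to the white matter);
#'   defaults 5 and 12.
#' @param stim_amplitude pulse amplitude (pA); `NULL` to auto-detect 1.5x
#'   threshold.
#' @param stim_duration pulse duration (ms), default 0.1.
#' @param dt integration step (ms).
#' @param t_end simulated time (ms).
#' @return list of class `velocity_result`: `velocity` (m/s), `site_a`,
#'   `site_b` (segment indices), `t_peak_a`, `t_peak_b` (ms), `distance`
#'   (µm).
#' @export
measure_velocity <- function(model, site_a = 5L, site_b = 12L,
                             stim_amplitude = NULL, stim_duration = 0.1,
                             dt = 0.00125, t_end = 15) {
  seg_a <- model$bouton_center[site_a]
  seg_b <- model$bouton_center[site_b]
  if (is.null(stim_amplitude))
    stim_amplitude <- 1.5 * find_stim_threshold(model, dt = dt)
  sim <- integrate_model(model,
    stimuli = list(list(site = 1L, onset = 0.5, duration = stim_duration,
                        amplitude = stim_amplitude)),
    dt = dt, t_end = t_end, record = c(seg_a, seg_b))
  pa <- .refine_peak(sim$t, sim$vm[, 1])
  pb <- .refine_peak(sim$t, sim$vm[, 2])
  if (pa$y < 0 || pb$y < 0)
    stop("action potential failed at a recording site (peak below 0 mV)")
  distance <- abs(model$pos[seg_b] - model$pos[seg_a])
  delay <- pb$t - pa$t
  if (delay <= 0) stop("non-orthodromic peak order")
  structure(list(velocity = distance / delay / 1000,   # µm/ms -> m/s
                 site_a = seg_a, site_b = seg_b,
                 t_peak_a = pa$t, t_peak_b = pb$t, distance = distance),
            class = "velocity_result")
}

#' Minimal stimulus amplitude that evokes a propagated action potential
#'
#' Bisects the amplitude of a brief pulse at the distal white-matter end
#' until the most distal bouton fires (peak > 0 mV).
#'
#' @param model equilibrated [axon_model].
#' @param stim_duration pulse duration (ms).
#' @param dt integration step (ms).
#' @param lo,hi initial bracket (pA).
#' @param rel_tol relative bisection tolerance.
#' @return threshold amplitude (pA).
#' @export
find_stim_threshold <- function(model, stim_duration = 0.1, dt = 0.0025,
                                lo = 10, hi = 6000, rel_tol = 0.02) {
  rec <- model$bouton_center[length(model$bouton_center)]
  fires <- function(amp) {
    sim <- integrate_model(model,
      stimuli = list(list(site = 1L, onset = 0.5, duration = stim_duration,
                          amplitude = amp)),
      dt = dt, t_end = 12, record = rec)
    max(sim$vm[, 1]) > 0
  }
  if (!fires(hi)) stop("no action potential even at the bracket maximum")
  while (fires(lo)) { hi <- lo; lo <- lo / 4 }
  while ((hi - lo) / hi > rel_tol) {
    mid <- sqrt(lo * hi)
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Run a high-frequency stimulus train
#'
#' Delivers `n` brief pulses at `frequency` to the distal white-matter end
#' and detects per-stimulus action potentials at a distal bouton. A
#' stimulus counts as a failure when the voltage peak in its inter-stimulus
#' window does not exceed `fail_threshold` (−40 mV). Delays are measured
#' stimulus-to-peak; amplitudes peak-to-baseline; half-durations at
#' half-maximal amplitude (non-failures only).
#'
#' @param model equilibrated [axon_model].
#' @param frequency train frequency (Hz), in (0, 2000].
#' @param n number of stimuli (default 20).
#' @param stim_amplitude pulse amplitude (pA); `NULL` for 1.5x threshold.
#' @param stim_duration pulse duration (ms).
#' @param record_bouton bouton number for AP detection (default: last).
#' @param fail_threshold failure threshold (mV), default −40.
#' @param dt integration step (ms).
#' @return list of class `train_result`: `frequency`, `n_stimuli`,
#'   `failures`, `delays`, `amplitudes`, `half_durations` (`NA` at
#'   failures), `peaks`.
#' @export
run_train <- function(model, frequency, n = 20L, stim_amplitude = NULL,
                      stim_duration = 0.1, record_bouton = NULL,
                      fail_threshold = -40, dt = 0.00125) {
  if (frequency <= 0 || frequency > 2000)
    stop("'frequency' must be in (0, 2000] Hz")
  if (is.null(stim_amplitude))
    stim_amplitude <- 1.5 * find_stim_threshold(model, dt = dt)
  if (is.null(record_bouton)) record_bouton <- length(model$bouton_center)
  rec <- model$bouton_center[record_bouton]
  isi <- 1000 / frequency
  onsets <- 0.5 + (seq_len(n) - 1L) * isi
  stimuli <- lapply(onsets, function(o)
    list(site = 1L, onset = o, duration = stim_duration,
         amplitude = stim_amplitude))
  t_end <- onsets[n] + max(isi, 8)
  sim <- integrate_model(model, stimuli = stimuli, dt = dt, t_end = t_end,
                         record = rec)
  v <- sim$vm[, 1]; tt <- sim$t
  baseline <- v[1]
  delays <- amplitudes <- half_durations <- peaks <- rep(NA_real_, n)
  failures <- 0L
  for (k in seq_len(n)) {
    w_end <- if (k < n) onsets[k + 1L] else t_end
    sel <- tt >= onsets[k] & tt < w_end
    pk <- .refine_peak(tt[sel], v[sel])
    peaks[k] <- pk$y
    if (pk$y <= fail_threshold) {
      failures <- failures + 1L
      next
    }
    delays[k] <- pk$t - onsets[k]
    amplitudes[k] <- pk$y - baseline
    hw <- try(peak_halfwidth(tt[sel], v[sel], polarity = "positive",
                             baseline = baseline), silent = TRUE)
    half_durations[k] <- if (inherits(hw, "try-error")) NA_real_
                         else hw$half_duration
  }
  structure(list(frequency = frequency, n_stimuli = n, failures = failures,
                 delays = delays, amplitudes = amplitudes,
                 half_durations = half_durations, peaks = peaks),
            class = "train_result")
}

#' Maximal failure-free train frequency
#'
#' Runs [run_train()] over a frequency ladder and returns the highest
#' frequency with zero failures (assuming the standard experimental ladder).
#'
#' @param model equilibrated [axon_model].
#' @param frequencies ladder (Hz), default the experimental set.
#' @param ... passed to [run_train()].
#' @return list: `max_freq` (Hz; 0 if all frequencies fail), `failures`
#'   (per ladder entry).
#' @export
max_failure_free_frequency <- function(model,
    frequencies = c(100, 200, 333, 500, 750, 1000, 1111, 1666), ...) {
  fails <- vapply(frequencies, function(f)
    run_train(model, frequency = f, ...)$failures, integer(1))
  ok <- frequencies[fails == 0L]
  list(max_freq = if (length(ok)) max(ok) else 0, failures = fails,
       frequencies = frequencies)
}

#' Conduction velocity as a function of resting potential
#'
#' Sets the resting membrane potential by adjusting the K+ leak reversal
#' potential uniformly (so every point is a true steady state), then
#' measures the conduction velocity and NaV availability at each target
#' rest.
#'
#' @param model a [build_model()] result (typically `no_hcn` so the rest is
#'   set purely by the leak mixture).
#' @param rest_targets desired resting potentials (mV).
#' @param dt integration step (ms) for velocity runs.
#' @param ... passed to [measure_velocity()].
#' @return data.frame: `rest_target`, `rest` (achieved), `velocity` (m/s),
#'   `nav_availability`, `reached` (logical; unreachable targets are
#'   flagged and carry NA velocity).
#' @export
velocity_vs_resting <- function(model, rest_targets = seq(-90, -55, by = 5),
                                dt = 0.00125, ...) {
  out <- data.frame(rest_target = rest_targets, rest = NA_real_,
                    velocity = NA_real_, nav_availability = NA_real_,
                    reached = FALSE)
  ## analytic resting potential for a uniform membrane as a function of the
  ## (global) K reversal; NaV/KV window currents are negligible at rest.
  ## Effective conductances are taken from a reference bouton segment so
  ## variant modifications are respected (density ratios are uniform
  ## across regions, hence the rest is spatially uniform).
  ref <- model$bouton_center[1]
  gna <- model$g_leak_na[ref]; gk <- model$g_leak_k[ref]
  gh_na <- model$g_hcn_na[ref]; gh_k <- model$g_hcn_k[ref]
  gnav <- model$g_nav[ref]; gkv <- model$g_kv[ref]
  kin <- model$kinetics
  ## e_k enters the steady-state current balance linearly: solve exactly
  ek_for_rest <- function(vt) {
    mh <- steady_state(vt, model$hcn)
    minf <- 1 / (1 + exp(-(vt - kin$nav_m[["vh"]]) / kin$nav_m[["k"]]))
    hinf <- 1 / (1 + exp((vt - kin$nav_h[["vh"]]) / kin$nav_h[["k"]]))
    ninf <- 1 / (1 + exp(-(vt - kin$kv_n[["vh"]]) / kin$kv_n[["k"]]))
    g_to_ek <- gk + mh * gh_k + gkv * ninf^kin$kv_power
    i_na <- (gna + mh * gh_na + gnav * minf^3 * hinf) * (vt - model$e_na)
    vt + i_na / g_to_ek
  }
  for (i in seq_along(rest_targets)) {
    vt <- rest_targets[i]
    m <- model
    m$e_k <- ek_for_rest(vt)
    m <- try(init_steady_state(m), silent = TRUE)
    if (inherits(m, "try-error")) next
    rest <- m$v[m$bouton_center[8]]
    if (abs(rest - vt) > 2.5) next
    vel <- try(measure_velocity(m, dt = dt, ...), silent = TRUE)
    out$rest[i] <- rest
    out$nav_availability[i] <- nav_availability(rest, m$kinetics)
    if (!inherits(vel, "try-error")) {
      out$velocity[i] <- vel$velocity
      out$reached[i] <- TRUE
    }
  }
  out
}
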