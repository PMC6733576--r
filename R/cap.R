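#' Smooth an extracellular trace with a cubic smoothing spline
#'
#' Cubic smoothing-spline estimate evaluated on the input grid, used to
#' raise the signal-to-noise ratio of compound-action-potential recordings
#' before peak detection. The smoothing parameter is chosen by generalized
#' cross-validation unless given.
#'
#' @param t time base (ms).
#' @param v samples (>= 20).
#' @param spar smoothing parameter passed to [stats::smooth.spline()];
#'   `NULL` for GCV, 0 approaches interpolation through the data.
#' @return smoothed samples on the same grid.
#' @export
smooth_trace <- function(t, v, spar = NULL) {
  if (length(v) < 20L) stop("need at least 20 samples")
  fit <- if (is.null(spar))
    stats::smooth.spline(t, v, cv = FALSE)       # generalized CV
  else
    stats::smooth.spline(t, v, spar = spar)
  stats::predict(fit, t)$y
}

#' Construct a two-electrode sweep pair
#'
#' @param t shared time base (ms).
#' @param v_prox,v_dist voltages at the proximal and distal electrodes.
#' @param distance_delta_um electrode separation along the fiber path (µm),
#'   > 0.
#' @param timestamp_min recording time relative to drug onset (min).
#' @return object of class `sweep_pair`.
#' @export
sweep_pair <- function(t, v_prox, v_dist, distance_delta_um,
                       timestamp_min = NA_real_) {
  stopifnot(length(t) == length(v_prox), length(t) == length(v_dist))
  if (distance_delta_um <= 0) stop("'distance_delta_um' must be > 0")
  structure(list(t = t, v_prox = v_prox, v_dist = v_dist,
                 distance_delta_um = distance_delta_um,
                 timestamp_min = timestamp_min),
            class = "sweep_pair")
}

#' Peak delay and conduction velocity from a sweep pair
#'
#' Finds the dominant peak of each electrode's trace inside the analysis
#' window (excluding the stimulus-artifact window), refines the peak times
#' by 3-point quadratic interpolation, and returns
#' `delay = t_peak(dist) - t_peak(prox)` and
#' `velocity = distance / delay`.
#'
#' @param pair a [sweep_pair()].
#' @param polarity peak direction, `"negative"` (typical extracellular CAP)
#'   or `"positive"`.
#' @param artifact_ms initial window excluded from the peak search (ms).
#' @param smooth smooth both traces with [smooth_trace()] first.
#' @param ambiguity_ratio flag the result when a second local extremum
#'   comes within this fraction of the main peak's amplitude.
#' @return list of class `peak_delay_result`: `delay` (ms), `velocity`
#'   (m/s; negative if the distal peak leads), `t_peak_prox`, `t_peak_dist`,
#'   `ambiguous` (logical per electrode).
#' @export
peak_delay <- function(pair, polarity = c("negative", "positive"),
                       artifact_ms = 0.3, smooth = FALSE,
                       ambiguity_ratio = 0.8) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "negative") -1 else 1
  one <- function(v) {
    if (smooth) v <- smooth_trace(pair$t, v)
    s <- sgn * v
    sel <- pair$t >= pair$t[1] + artifact_ms
    ts <- pair$t[sel]; ss <- s[sel]
    pk <- .refine_peak(ts, ss)
    ## ambiguity: another local max within ambiguity_ratio of the peak
    ## amplitude (above baseline), away from the main peak
    base <- stats::median(ss)
    locmax <- which(diff(sign(diff(ss))) == -2) + 1L
    amb <- any(abs(ts[locmax] - pk$t) > 0.5 &
               (ss[locmax] - base) > ambiguity_ratio * (pk$y - base))
    list(t = pk$t, ambiguous = amb)
  }
  p <- one(pair$v_prox); d <- one(pair$v_dist)
  delay <- d$t - p$t
  structure(list(delay = delay,
                 velocity = pair$distance_delta_um / delay / 1000,
                 t_peak_prox = p$t, t_peak_dist = d$t,
                 ambiguous = c(prox = p$ambiguous, dist = d$ambiguous)),
            class = "peak_delay_result")
}

#' Named analysis-window presets (minutes)
#'
#' `baseline`: −5 to 0 min before drug onset; `effect`: 10 to 15 min after;
#' `fast_effect`: 1 to 6 min after.
#'
#' @param name preset name.
#' @return numeric length-2 window (min).
#' @export
timecourse_window <- function(name = c("baseline", "effect", "fast_effect")) {
  switch(match.arg(name),
         baseline = c(-5, 0), effect = c(10, 15), fast_effect = c(1, 6))
}

#' Normalize a velocity timecourse to its baseline
#'
#' @param times timestamps (min).
#' @param velocity velocities (any consistent unit).
#' @param baseline_window window (min) whose mean defines 1; needs >= 2
#'   points.
#' @return list of class `timecourse_result`: `times`, `velocity_norm`,
#'   `baseline_window`.
#' @export
normalize_timecourse <- function(times, velocity,
                                 baseline_window = timecourse_window("baseline")) {
  stopifnot(length(times) == length(velocity))
  sel <- times >= baseline_window[1] & times <= baseline_window[2]
  if (sum(sel) < 2L) stop("baseline window must contain at least 2 points")
  structure(list(times = times,
                 velocity_norm = velocity / mean(velocity[sel]),
                 baseline_window = baseline_window),
            class = "timecourse_result")
}

#' Relative velocity change over a window
#'
#' `100 * (mean(normalized velocity over window) - 1)`, in percent.
#'
#' @param tc a [normalize_timecourse()] result.
#' @param window window (min), e.g. [timecourse_window()]`("effect")`.
#' @return percent change (negative = slowing).
#' @export
window_change <- function(tc, window = timecourse_window("effect")) {
  sel <- tc$times >= window[1] & tc$times <= window[2]
  if (!any(sel)) stop("empty analysis window")
  100 * (mean(tc$velocity_norm[sel]) - 1)
}

#' Read or write two-electrode sweeps as CSV + JSON sidecar
#'
#' The CSV holds columns `t_ms`, `v_prox`, `v_dist`; the sidecar holds
#' `distance_delta_um` and `timestamp_min`.
#'
#' @param csv_path,json_path file paths.
#' @return `read_sweep_pair`: a [sweep_pair()].
#' @export
read_sweep_pair <- function(csv_path, json_path) {
  df <- utils::read.csv(csv_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  sweep_pair(df$t_ms, df$v_prox, df$v_dist,
             distance_delta_um = meta$distance_delta_um,
             timestamp_min = meta$timestamp_min)
}

#' @param pair a [sweep_pair()].
#' @rdname read_sweep_pair
#' @export
write_sweep_pair <- function(pair, csv_path, json_path) {
  utils::write.csv(data.frame(t_ms = pair$t, v_prox = pair$v_prox,
                              v_dist = pair$v_dist),
                   csv_path, row.names = FALSE)
  jsonlite::write_json(list(distance_delta_um = pair$distance_delta_um,
                            timestamp_min = pair$timestamp_min),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
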