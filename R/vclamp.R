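#' Construct a voltage-clamp sweep
#'
#' A uniformly sampled current trace with its command-voltage trace and
#' condition metadata.
#'
#' @param t time base (ms), uniform step.
#' @param i current samples (pA).
#' @param v_cmd command-voltage trace (mV), same length as `t`.
#' @param meta named list of condition labels (e.g. `holding_mV`,
#'   `step_mV`, `drug`).
#' @return object of class `sweep`.
#' @export
vc_sweep <- function(t, i, v_cmd, meta = list()) {
  stopifnot(length(t) == length(i), length(t) == length(v_cmd))
  dt <- diff(t)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
    stop("sweep time base must be uniformly sampled")
  structure(list(t = t, i = i, v_cmd = v_cmd, meta = meta), class = "sweep")
}

#' Extract a normalized tail-current activation curve
#'
#' For each sweep the tail amplitude is the current at the fixed post-step
#' potential, averaged over `tail_window` (ms, measured from the end of the
#' conditioning pulse; the default skips the first 0.5 ms of capacitive
#' settling). Because the sweeps are blocker-subtracted (leak-free), the
#' default baseline is zero, which keeps the tail amplitude proportional to
#' the channel open fraction even when a fraction of channels is open at
#' the holding potential; `baseline = "pre_step"` subtracts the mean
#' pre-step holding current instead. Amplitudes are normalized to the
#' maximum across sweeps, giving one activation point per conditioning
#' voltage.
#'
#' @param sweeps list of [vc_sweep()] objects sharing holding and tail
#'   potentials.
#' @param tail_window numeric length-2, ms after the end of the conditioning
#'   step over which the tail is averaged (default `c(0.5, 2.5)`).
#' @param baseline `"zero"` (default, for subtracted sweeps) or
#'   `"pre_step"`.
#' @return an [activation_points()] data.frame, one row per sweep.
#' @export
extract_tail_activation <- function(sweeps, tail_window = c(0.5, 2.5),
                                    baseline = c("zero", "pre_step")) {
  baseline <- match.arg(baseline)
  stopifnot(is.list(sweeps), length(sweeps) >= 1L)
  amp <- vstep <- numeric(length(sweeps))
  for (s in seq_along(sweeps)) {
    sw <- sweeps[[s]]
    v <- sw$v_cmd; t <- sw$t
    chg <- which(diff(v) != 0)
    if (length(chg) < 2L)
      stop("sweep ", s, ": cannot locate conditioning step in v_cmd")
    t_on <- t[chg[1] + 1L]          # step onset
    t_off <- t[chg[length(chg)] + 1L]  # return to tail potential
    pre <- t < t_on
    tail <- t >= t_off + tail_window[1] & t <= t_off + tail_window[2]
    if (!any(tail))
      stop("sweep ", s, ": missing tail segment in [",
           tail_window[1], ", ", tail_window[2], "] ms after the step")
    base <- if (baseline == "pre_step") mean(sw$i[pre]) else 0
    amp[s] <- mean(sw$i[tail]) - base
    vstep[s] <- v[chg[1] + 1L + max(1L, (chg[length(chg)] - chg[1]) %/% 2L)]
  }
  mx <- max(abs(amp))
  if (mx == 0) stop("zero maximum tail amplitude: cannot normalize")
  activation_points(vstep, amp / amp[which.max(abs(amp))])
}

#' Fit a mono-exponential decay to a trace segment
#'
#' Least-squares fit of `a * exp(-t/tau) + c` over `window` (time measured
#' from the window start).
#'
#' @param sweep a [vc_sweep()] or any list with `t` and a sample vector `i`
#'   (a voltage trace may be passed with samples in `i`).
#' @param window numeric length-2 time range (ms) inside the sweep.
#' @return list of class `monoexp_fit`: `tau` (ms), `amplitude`, `offset`,
#'   `rss`, `ok` (FALSE for a non-decaying segment, in which case the other
#'   fields are `NA`).
#' @export
fit_monoexp <- function(sweep, window) {
  sel <- sweep$t >= window[1] & sweep$t <= window[2]
  if (sum(sel) < 10L) stop("window must contain at least 10 samples")
  tt <- sweep$t[sel] - window[1]
  y <- sweep$i[sel]
  a0 <- y[1] - y[length(y)]
  c0 <- y[length(y)]
  if (abs(a0) < 1e-12 * max(1, abs(c0)) || stats::sd(y) == 0)
    return(structure(list(tau = NA_real_, amplitude = NA_real_,
                          offset = NA_real_, rss = NA_real_, ok = FALSE),
                     class = "monoexp_fit"))
  tau0 <- diff(range(tt)) / 3
  fit <- minpack.lm::nls.lm(
    par = c(a = a0, ltau = log(tau0), c = c0),
    fn = function(p) y - (p[1] * exp(-tt / exp(p[2])) + p[3]),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  tau <- exp(fit$par[["ltau"]])
  rss <- sum(fit$fvec^2)
  ## flag non-decaying data: fit no better than a constant, or tau pinned
  ## to the window edge
  rss0 <- sum((y - mean(y))^2)
  ok <- is.finite(tau) && tau > 0 && rss < 0.99 * rss0 &&
    tau < 50 * diff(range(tt))
  structure(list(tau = if (ok) tau else NA_real_,
                 amplitude = fit$par[["a"]], offset = fit$par[["c"]],
                 rss = rss, ok = ok),
            class = "monoexp_fit")
}

#' Construct a ramp I-V relationship
#'
#' @param v voltages along the ramp (mV), strictly monotone.
#' @param i leak-subtracted current (pA).
#' @param activation_V conditioning potential preceding the ramp (mV).
#' @return object of class `ramp_iv`.
#' @export
ramp_iv <- function(v, i, activation_V) {
  stopifnot(length(v) == length(i))
  dv <- diff(v)
  if (!(all(dv > 0) || all(dv < 0))) stop("ramp voltages must be strictly monotone")
  structure(list(v = v, i = i, activation_V = activation_V), class = "ramp_iv")
}

#' Reversal potential from three voltage-ramp I-V relationships
#'
#' Fits a line to each I-V relationship, computes the three pairwise
#' intersection voltages of the lines, and returns their mean. The ramps are
#' recorded after conditioning at three different activation potentials, so
#' the lines differ in slope (channel open fraction) but share the reversal
#' potential.
#'
#' @param ramps list of exactly three [ramp_iv()] objects with distinct
#'   activation potentials.
#' @param slope_tol minimum relative slope difference below which a pair of
#'   lines is considered parallel (error).
#' @return list of class `reversal_fit`: `reversal` (mV), `intersections`
#'   (mV, length 3), `slopes`, `intercepts`.
#' @export
reversal_from_ramps <- function(ramps, slope_tol = 1e-6) {
  if (length(ramps) != 3L) stop("exactly three ramps are required")
  av <- vapply(ramps, function(r) r$activation_V, 0)
  if (anyDuplicated(av)) stop("activation potentials must be distinct")
  cf <- vapply(ramps, function(r) stats::coef(stats::lm(r$i ~ r$v)), numeric(2))
  b <- cf[1, ]; m <- cf[2, ]
  pairs <- utils::combn(3L, 2L)
  xs <- numeric(3L)
  for (j in 1:3) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    dm <- m[i1] - m[i2]
    if (abs(dm) <= slope_tol * max(abs(m[i1]), abs(m[i2])))
      stop(sprintf("ramps %d and %d are near-parallel: no intersection",
                   i1, i2))
    xs[j] <- (b[i2] - b[i1]) / dm
  }
  structure(list(reversal = mean(xs), intersections = xs,
                 slopes = m, intercepts = b),
            class = "reversal_fit")
}

#' Construct dose-response points
#'
#' @param conc cAMP concentrations (µM), > 0.
#' @param shift midpoint shifts relative to 0 cAMP (mV).
#' @param sem per-point uncertainty (mV); optional.
#' @param n cells per point; optional.
#' @return data.frame of class `dose_response`.
#' @export
dose_response_points <- function(conc, shift, sem = NA_real_, n = NA_integer_) {
  stopifnot(length(conc) == length(shift))
  if (any(conc <= 0)) stop("concentrations must be > 0")
  structure(data.frame(conc_uM = conc, shift_mV = shift,
                       sem_mV = rep_len(sem, length(conc)),
                       n = rep_len(n, length(conc))),
            class = c("dose_response", "data.frame"))
}

#' Hill equation
#'
#' \eqn{s(c) = s_{max} c^h / (c^h + EC_{50}^h)}.
#'
#' @param conc concentrations (µM).
#' @param ec50 half-maximal concentration (µM).
#' @param s_max maximal effect.
#' @param h Hill coefficient.
#' @return effect values.
#' @export
hill <- function(conc, ec50, s_max, h = 1) {
  s_max * conc^h / (conc^h + ec50^h)
}

#' Fit a Hill equation to dose-response data
#'
#' Least-squares fit of [hill()], weighted by `1/sem^2` when SEMs are
#' present. The Hill coefficient is free by default or can be fixed.
#'
#' @param points a [dose_response_points()] data.frame with at least 3
#'   distinct concentrations (4 if `h` is free).
#' @param fix_h `NULL` (free) or a fixed Hill coefficient (e.g. 1).
#' @return list of class `hill_fit`: `ec50` (µM), `s_max` (mV), `h`,
#'   `covariance` (over the fitted parameters, on the natural scale), `rss`.
#' @export
fit_hill <- function(points, fix_h = NULL) {
  conc <- points$conc_uM; y <- points$shift_mV
  w <- if (all(is.finite(points$sem_mV)) && all(points$sem_mV > 0))
    1 / points$sem_mV^2 else rep(1, length(y))
  n_par <- if (is.null(fix_h)) 3L else 2L
  if (length(unique(conc)) < max(3L, n_par))
    stop("need at least ", max(3L, n_par), " distinct concentrations ",
         "(or fix the Hill coefficient)")
  ec0 <- stats::approx(y, conc, xout = max(y) / 2, ties = mean)$y
  if (is.na(ec0) || ec0 <= 0) ec0 <- exp(mean(log(conc)))
  start <- c(lec50 = log(ec0), s_max = max(y) * 1.1)
  if (is.null(fix_h)) start <- c(start, lh = 0)
  fn <- function(p) {
    h <- if (is.null(fix_h)) exp(p[["lh"]]) else fix_h
    sqrt(w) * (y - hill(conc, exp(p[["lec50"]]), p[["s_max"]], h))
  }
  fit <- minpack.lm::nls.lm(par = start, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                         ptol = 1e-12))
  ec50 <- exp(fit$par[["lec50"]])
  s_max <- fit$par[["s_max"]]
  h <- if (is.null(fix_h)) exp(fit$par[["lh"]]) else fix_h
  rss <- sum(fit$fvec^2)
  nat <- if (is.null(fix_h)) c(ec50 = ec50, s_max = s_max, h = h)
         else c(ec50 = ec50, s_max = s_max)
  J <- .num_jacobian(function(q) {
    hh <- if (is.null(fix_h)) q[["h"]] else fix_h
    sqrt(w) * hill(conc, q[["ec50"]], q[["s_max"]], hh)
  }, nat)
  covar <- .gn_covariance(J, rss, length(y), length(nat))
  dimnames(covar) <- list(names(nat), names(nat))
  structure(list(ec50 = ec50, s_max = s_max, h = h,
                 covariance = covar, rss = rss, h_fixed = !is.null(fix_h)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: EC50 = %.4g uM, s_max = %.4g mV, h = %.3g%s\n",
              x$ec50, x$s_max, x$h, if (x$h_fixed) " (fixed)" else ""))
  invisible(x)
}

#' Estimate the endogenous cAMP concentration from a Hill fit
#'
#' The point estimate solves the mean Hill curve for the observed midpoint
#' shift. The 68% interval is obtained by first-order (delta-method)
#' propagation of the fit covariance onto a log-spaced concentration grid:
#' the bounds are the extreme concentrations at which the fit's 68%
#' confidence band overlaps `shift ± shift_sem`.
#'
#' @param fit a [fit_hill()] result.
#' @param shift observed midpoint shift (mV), in `(0, s_max)`.
#' @param shift_sem uncertainty of the observed shift (mV).
#' @param grid_range concentration grid range (µM), default `c(1e-1, 1e5)`.
#' @param grid_n number of log-spaced grid points (default 400).
#' @return list of class `endogenous_estimate`: `conc_point`, `ci68_low`,
#'   `ci68_high` (µM). Open-ended bounds are reported as the grid edge with
#'   attribute `open` naming the side(s).
#' @export
estimate_endogenous_camp <- function(fit, shift, shift_sem,
                                     grid_range = c(1e-1, 1e5),
                                     grid_n = 400L) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!(shift > 0 && shift < fit$s_max))
    stop("'shift' must lie strictly between 0 and the fitted maximal shift")
  ## invert the mean curve: s = smax c^h/(c^h+ec50^h)
  conc_point <- fit$ec50 * (shift / (fit$s_max - shift))^(1 / fit$h)
  grid <- exp(seq(log(grid_range[1]), log(grid_range[2]), length.out = grid_n))
  mu <- hill(grid, fit$ec50, fit$s_max, fit$h)
  sdv <- rep(0, grid_n)
  if (all(is.finite(fit$covariance))) {
    for (i in seq_len(grid_n)) {
      g <- .num_jacobian(function(q) {
        h <- if (fit$h_fixed) fit$h else q[["h"]]
        hill(grid[i], q[["ec50"]], q[["s_max"]], h)
      }, if (fit$h_fixed) c(ec50 = fit$ec50, s_max = fit$s_max)
         else c(ec50 = fit$ec50, s_max = fit$s_max, h = fit$h))
      sdv[i] <- sqrt(max(0, g %*% fit$covariance %*% t(g)))
    }
  }
  lo_band <- mu - sdv; hi_band <- mu + sdv
  overlap <- (lo_band <= shift + shift_sem) & (hi_band >= shift - shift_sem)
  open <- character(0)
  if (!any(overlap)) {
    ci <- c(conc_point, conc_point)
  } else {
    idx <- range(which(overlap))
    ci <- grid[idx]
    if (idx[1] == 1L) open <- c(open, "low")
    if (idx[2] == grid_n) open <- c(open, "high")
  }
  ci[1] <- min(ci[1], conc_point); ci[2] <- max(ci[2], conc_point)
  structure(list(conc_point = conc_point, ci68_low = ci[1],
                 ci68_high = ci[2]),
            class = "endogenous_estimate", open = open)
}

#' Peak amplitude and half-duration of a pulse-like trace
#'
#' The amplitude is measured from baseline to the extremum; the
#' half-duration is the width of the pulse at 50% of that amplitude, with
#' linear interpolation between samples at both crossings.
#'
#' @param t time base (ms).
#' @param y samples (current or voltage).
#' @param polarity `"positive"` or `"negative"`: direction of the dominant
#'   peak relative to baseline.
#' @param baseline baseline level; default the mean of the first 5% of
#'   samples.
#' @return list: `amplitude` (same units as `y`, positive), `half_duration`
#'   (ms), `t_peak` (ms).
#' @export
peak_halfwidth <- function(t, y, polarity = c("positive", "negative"),
                           baseline = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(length(t) == length(y), length(y) >= 5L)
  s <- if (polarity == "positive") y else -y
  if (is.null(baseline)) baseline <- mean(s[seq_len(max(2L, length(s) %/% 20L))])
  ipk <- which.max(s)
  amp <- s[ipk] - baseline
  if (amp <= 0) stop("no peak above baseline")
  half <- baseline + amp / 2
  ## walk out from the peak to the half crossings
  i1 <- ipk
  while (i1 > 1L && s[i1 - 1L] > half) i1 <- i1 - 1L
  i2 <- ipk
  n <- length(s)
  while (i2 < n && s[i2 + 1L] > half) i2 <- i2 + 1L
  if (i1 == 1L || i2 == n) stop("no half-amplitude crossing inside the trace")
  frac1 <- (half - s[i1 - 1L]) / (s[i1] - s[i1 - 1L])
  t_lo <- t[i1 - 1L] + frac1 * (t[i1] - t[i1 - 1L])
  frac2 <- (s[i2] - half) / (s[i2] - s[i2 + 1L])
  t_hi <- t[i2] + frac2 * (t[i2 + 1L] - t[i2])
  list(amplitude = amp, half_duration = t_hi - t_lo, t_peak = t[ipk])
}

#' Read or write dose-response tables as CSV
#'
#' Columns: `conc_uM`, `shift_mV`, `sem_mV`, `n`.
#'
#' @param path CSV file path.
#' @return `read_dose_response_csv`: a [dose_response_points()] data.frame.
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conc_uM", "shift_mV")
  if (!all(need %in% names(df)))
    stop("dose-response CSV must have columns: ", paste(need, collapse = ", "))
  dose_response_points(df$conc_uM, df$shift_mV,
                       sem = if ("sem_mV" %in% names(df)) df$sem_mV else NA_real_,
                       n = if ("n" %in% names(df)) df$n else NA_integer_)
}

#' @param points a [dose_response_points()] data.frame.
#' @rdname read_dose_response_csv
#' @export
write_dose_response_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}
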