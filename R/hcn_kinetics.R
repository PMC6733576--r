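#' Hodgkin-Huxley rate parameters for the HCN activation gate
#'
#' The single activation gate of the HCN channel is governed by
#' \deqn{dm/dt = \alpha(V)(1 - m) - \beta(V) m}
#' with voltage-dependent rates
#' \deqn{\alpha(V) = A e^{-(V - V_{1/2})/V_\alpha}, \qquad
#'       \beta(V)  = A e^{ (V - V_{1/2})/V_\beta}.}
#' `A` is the rate at the midpoint (where \eqn{\alpha = \beta = A}),
#' `v_half` the midpoint voltage, and `v_alpha`/`v_beta` the voltage scales
#' of the forward and backward rates.
#'
#' @param A peak rate at the midpoint. With `rate_unit = "per_s"` (default)
#'   `A` is in 1/s, so the time constant at the midpoint is `1/(2A)` seconds;
#'   with `"per_ms"` it is in 1/ms.
#' @param v_half midpoint voltage (mV).
#' @param v_alpha forward-rate voltage scale (mV), > 0.
#' @param v_beta backward-rate voltage scale (mV), > 0.
#' @param label condition tag, e.g. `"0mM_cAMP"`.
#' @param rate_unit `"per_s"` or `"per_ms"`; unit of `A`.
#' @return An object of class `rate_params`.
#' @seealso [hh_params()] for the two published parameter sets.
#' @export
rate_params <- function(A, v_half, v_alpha, v_beta, label = "",
                        rate_unit = c("per_s", "per_ms")) {
  rate_unit <- match.arg(rate_unit)
  stopifnot(is.numeric(A), is.numeric(v_half), is.numeric(v_alpha),
            is.numeric(v_beta), length(A) == 1L, length(v_half) == 1L)
  if (!is.finite(A) || A <= 0) stop("'A' must be finite and > 0")
  if (!is.finite(v_half)) stop("'v_half' must be finite")
  if (!is.finite(v_alpha) || v_alpha <= 0) stop("'v_alpha' must be > 0")
  if (!is.finite(v_beta) || v_beta <= 0) stop("'v_beta' must be > 0")
  structure(list(A = A, v_half = v_half, v_alpha = v_alpha,
                 v_beta = v_beta, label = label, rate_unit = rate_unit),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("HCN gate rate parameters [%s]\n", x$label))
  cat(sprintf("  A       = %.4g %s\n", x$A,
              if (x$rate_unit == "per_s") "1/s" else "1/ms"))
  cat(sprintf("  V1/2    = %.4g mV\n  V_alpha = %.4g mV\n  V_beta  = %.4g mV\n",
              x$v_half, x$v_alpha, x$v_beta))
  invisible(x)
}

#' Published HCN gate parameter sets
#'
#' Rate parameters of the axonal HCN2 Hodgkin-Huxley model fitted to
#' cerebellar mossy-fiber bouton recordings, for 0 mM and 1 mM intracellular
#' cAMP. The numeric value of `A` is as printed; its unit is interpreted as
#' 1/s by default (the tens-of-milliseconds time constants of the measured
#' gating identify the second-based reading; see the package vignette).
#'
#' @param condition `"0mM_cAMP"` or `"1mM_cAMP"`.
#' @param rate_unit unit in which `A` is expressed, see [rate_params()].
#' @return A `rate_params` object.
#' @export
hh_params <- function(condition = c("0mM_cAMP", "1mM_cAMP"),
                      rate_unit = c("per_s", "per_ms")) {
  condition <- match.arg(condition)
  rate_unit <- match.arg(rate_unit)
  switch(condition,
    "0mM_cAMP" = rate_params(6.907, -102.1, 18.71, 21.73,
                             label = condition, rate_unit = rate_unit),
    "1mM_cAMP" = rate_params(7.570, -87.31, 31.46, 10.84,
                             label = condition, rate_unit = rate_unit))
}

.check_v <- function(V) {
  if (!is.numeric(V) || any(!is.finite(V))) stop("voltage must be finite")
  V
}

#' Forward (opening) rate of the HCN gate
#'
#' @param V membrane potential (mV); vectorized.
#' @param p a [rate_params()] object.
#' @return \eqn{\alpha(V) = A e^{-(V - V_{1/2})/V_\alpha}}, in the unit of `A`.
#' @export
alpha_rate <- function(V, p) {
  stopifnot(inherits(p, "rate_params"))
  p$A * exp(-(.check_v(V) - p$v_half) / p$v_alpha)
}

#' Backward (closing) rate of the HCN gate
#'
#' @inheritParams alpha_rate
#' @return \eqn{\beta(V) = A e^{(V - V_{1/2})/V_\beta}}, in the unit of `A`.
#' @export
beta_rate <- function(V, p) {
  stopifnot(inherits(p, "rate_params"))
  p$A * exp((.check_v(V) - p$v_half) / p$v_beta)
}

#' Steady-state activation of the HCN gate
#'
#' \eqn{m_\infty(V) = \alpha/(\alpha+\beta) =
#'   1/(1 + e^{(V - V_{1/2})(1/V_\alpha + 1/V_\beta)})}; equals 0.5 at
#' `v_half` and decreases monotonically with depolarization.
#'
#' @inheritParams alpha_rate
#' @return open fraction in (0, 1).
#' @export
steady_state <- function(V, p) {
  stopifnot(inherits(p, "rate_params"))
  x <- (.check_v(V) - p$v_half) * (1 / p$v_alpha + 1 / p$v_beta)
  1 / (1 + exp(x))
}

#' Time constant of the HCN gate
#'
#' \eqn{\tau(V) = 1/(\alpha+\beta)}, returned in milliseconds regardless of
#' the unit of `A`.
#'
#' @inheritParams alpha_rate
#' @return time constant (ms), > 0.
#' @export
time_constant <- function(V, p) {
  tau <- 1 / (alpha_rate(V, p) + beta_rate(V, p))
  if (p$rate_unit == "per_s") tau * 1000 else tau
}

#' Advance the HCN gate by one time step
#'
#' Exact solution of the linear gate ODE over a step of constant voltage:
#' `m` relaxes exponentially toward \eqn{m_\infty(V)} with time constant
#' \eqn{\tau(V)}. Stable and within \[0, 1\] for any `dt`.
#'
#' @param m current open fraction in \[0, 1\]; vectorized with `V`.
#' @param V membrane potential (mV).
#' @param dt time step (ms), > 0.
#' @param p a [rate_params()] object.
#' @return updated open fraction.
#' @export
gate_step <- function(m, V, dt, p) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (ms)")
  if (any(m < 0 | m > 1)) stop("'m' must lie in [0, 1]")
  minf <- steady_state(V, p)
  tau <- time_constant(V, p)
  minf + (m - minf) * exp(-dt / tau)
}

#' Boltzmann activation function
#'
#' \eqn{1/(1 + e^{(V - V_{1/2})/k})}: the sigmoid used to describe
#' steady-state activation curves of hyperpolarization-activated channels
#' (decreasing in V; `k > 0` is the slope factor).
#'
#' @param V voltage (mV); vectorized.
#' @param v_half midpoint voltage (mV).
#' @param k slope factor (mV), > 0.
#' @return fraction in (0, 1).
#' @export
boltzmann <- function(V, v_half, k) {
  if (k <= 0) stop("'k' must be > 0")
  1 / (1 + exp((.check_v(V) - v_half) / k))
}

#' Construct activation-curve points
#'
#' @param V conditioning voltages (mV).
#' @param activation normalized tail amplitudes (nominal 0-1).
#' @param sem per-point uncertainties (optional).
#' @return data.frame of class `activation_points` with columns
#'   `V_mV`, `value`, `sem`, `kind`.
#' @export
activation_points <- function(V, activation, sem = NA_real_) {
  stopifnot(length(V) == length(activation))
  if (any(!is.finite(activation))) stop("activation values must be finite")
  structure(data.frame(V_mV = V, value = activation,
                       sem = rep_len(sem, length(V)), kind = "activation"),
            class = c("activation_points", "data.frame"))
}

#' Construct time-constant points
#'
#' @param V voltages (mV).
#' @param tau time constants (ms), > 0.
#' @param kind `"activation"` or `"deactivation"`.
#' @param sem per-point uncertainties (optional).
#' @return data.frame of class `tau_points`.
#' @export
tau_points <- function(V, tau, kind = c("activation", "deactivation"),
                       sem = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(length(V) == length(tau))
  if (any(!is.finite(tau) | tau <= 0)) stop("time constants must be > 0")
  structure(data.frame(V_mV = V, value = tau,
                       sem = rep_len(sem, length(V)), kind = paste0("tau_", kind)),
            class = c("tau_points", "data.frame"))
}

#' Fit a Boltzmann function to activation points
#'
#' Unweighted least-squares fit of [boltzmann()] by Levenberg-Marquardt,
#' initialized from the data's half-crossing. Deterministic for identical
#' input.
#'
#' @param points an [activation_points()] data.frame (or any data.frame with
#'   columns `V_mV` and `value`), at least 4 points spanning the transition.
#' @return list of class `boltzmann_fit`: `v_half`, `k`, `covariance` (2x2),
#'   `rss`, `fitted`.
#' @export
fit_boltzmann <- function(points) {
  V <- points$V_mV; y <- points$value
  if (length(V) < 4L) stop("need at least 4 activation points")
  if (diff(range(y)) < 0.2)
    stop("degenerate activation data: no transition spanned")
  ## initial v_half: interpolated half-crossing; k: from 25-75% span
  o <- order(V)
  v0 <- stats::approx(y[o], V[o], xout = 0.5, ties = mean)$y
  if (is.na(v0)) v0 <- stats::median(V)
  k0 <- abs(diff(range(V))) / 8
  fit <- minpack.lm::nls.lm(
    par = c(v_half = v0, k = k0),
    fn = function(par) y - boltzmann(V, par[1], max(par[2], 1e-6)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  par <- fit$par
  if (par["k"] <= 0) stop("Boltzmann fit failed: non-positive slope factor")
  rss <- sum(fit$fvec^2)
  J <- .num_jacobian(function(p) boltzmann(V, p[1], p[2]), par)
  covar <- .gn_covariance(J, rss, length(y), 2L)
  structure(list(v_half = unname(par["v_half"]), k = unname(par["k"]),
                 covariance = covar, rss = rss,
                 fitted = boltzmann(V, par["v_half"], par["k"])),
            class = "boltzmann_fit")
}

## forward-difference Jacobian (n x p)
.num_jacobian <- function(f, par, eps = 1e-6) {
  f0 <- f(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

## Gauss-Newton covariance, residual-variance scaled; NA matrix if singular
.gn_covariance <- function(J, rss, n, p, w = NULL) {
  JtJ <- if (is.null(w)) crossprod(J) else crossprod(J * sqrt(w), J * sqrt(w))
  s2 <- rss / max(n - p, 1L)
  cv <- try(solve(JtJ) * s2, silent = TRUE)
  if (inherits(cv, "try-error")) matrix(NA_real_, p, p) else cv
}

#' Globally fit the HCN Hodgkin-Huxley model to activation and kinetics data
#'
#' Simultaneously fits the four rate parameters (`A`, `v_half`, `v_alpha`,
#' `v_beta`) to (i) the steady-state activation curve via
#' \eqn{\alpha/(\alpha+\beta)} and (ii) the activation and deactivation time
#' constants via \eqn{1/(\alpha+\beta)}. Residuals of each of the three
#' datasets are weighted by the inverse of the square of that dataset's
#' maximum value, so the three dimensionally different curves contribute
#' comparably. Minimization is damped least squares (Levenberg-Marquardt)
#' with multiple restarts around data-driven initial guesses; 68% confidence
#' half-widths are the square roots of the diagonal of the inverse
#' Gauss-Newton Hessian of the weighted objective at the optimum, scaled by
#' the residual variance.
#'
#' @param act [activation_points()] steady-state activation data.
#' @param tau_act [tau_points()] activation time constants (ms).
#' @param tau_deact [tau_points()] deactivation time constants (ms).
#' @param rate_unit unit for the fitted `A`, see [rate_params()].
#' @param n_starts number of multi-starts (default 10).
#' @param label condition tag attached to the fitted parameters.
#' @return list of class `hh_fit`: `params` ([rate_params()]), `ci68`
#'   (named half-widths; `NA` if the Hessian is singular), `weighted_sse`,
#'   `converged`.
#' @export
fit_hh <- function(act, tau_act, tau_deact,
                   rate_unit = c("per_s", "per_ms"),
                   n_starts = 10L, label = "fit") {
  rate_unit <- match.arg(rate_unit)
  if (nrow(act) == 0L || nrow(tau_act) == 0L || nrow(tau_deact) == 0L)
    stop("all three datasets must be non-empty")
  Va <- act$V_mV;  ya <- act$value
  Vt1 <- tau_act$V_mV;  yt1 <- tau_act$value
  Vt2 <- tau_deact$V_mV; yt2 <- tau_deact$value
  w <- c(rep(1 / max(ya)^2, length(ya)),
         rep(1 / max(yt1)^2, length(yt1)),
         rep(1 / max(yt2)^2, length(yt2)))
  tau_scale <- if (rate_unit == "per_s") 1000 else 1

  resid_fn <- function(par) {
    ## par on log scale for A, v_alpha, v_beta to enforce positivity
    A <- exp(par[1]); vh <- par[2]; va <- exp(par[3]); vb <- exp(par[4])
    al_a <- A * exp(-(Va - vh) / va);  be_a <- A * exp((Va - vh) / vb)
    minf <- al_a / (al_a + be_a)
    tau1 <- tau_scale / (A * exp(-(Vt1 - vh) / va) + A * exp((Vt1 - vh) / vb))
    tau2 <- tau_scale / (A * exp(-(Vt2 - vh) / va) + A * exp((Vt2 - vh) / vb))
    sqrt(w) * (c(ya, yt1, yt2) - c(minf, tau1, tau2))
  }

  ## data-driven initial guesses
  o <- order(Va)
  vh0 <- stats::approx(ya[o], Va[o], xout = 0.5, ties = mean)$y
  if (is.na(vh0)) vh0 <- stats::median(Va)
  A0 <- tau_scale / (2 * max(c(yt1, yt2)))
  base <- c(log(A0), vh0, log(20), log(20))

  best <- NULL
  set.seed_local <- function(i) c(base[1] + stats::runif(1, -0.7, 0.7) * (i > 1),
                                  base[2] + stats::runif(1, -10, 10) * (i > 1),
                                  base[3] + stats::runif(1, -0.7, 0.7) * (i > 1),
                                  base[4] + stats::runif(1, -0.7, 0.7) * (i > 1))
  for (i in seq_len(max(1L, n_starts))) {
    start <- set.seed_local(i)
    fit <- try(minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, maxfev = 10000, ftol = 1e-10, ptol = 1e-8)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("HH fit failed in every start")
  fit <- best$fit
  par <- fit$par
  converged <- fit$info %in% 1:3

  p_nat <- c(A = exp(par[1]), v_half = par[2],
             v_alpha = exp(par[3]), v_beta = exp(par[4]))
  ## Gauss-Newton CI in natural parameter space
  nat_resid <- function(q) {
    lp <- c(log(q[1]), q[2], log(q[3]), log(q[4]))
    resid_fn(lp)
  }
  J <- .num_jacobian(nat_resid, p_nat)
  covar <- .gn_covariance(J, best$sse, length(w), 4L)
  ci68 <- sqrt(pmax(diag(covar), 0))
  names(ci68) <- names(p_nat)

  structure(list(
    params = rate_params(p_nat[["A"]], p_nat[["v_half"]], p_nat[["v_alpha"]],
                         p_nat[["v_beta"]], label = label,
                         rate_unit = rate_unit),
    ci68 = ci68, covariance = covar,
    weighted_sse = best$sse, converged = converged),
    class = "hh_fit")
}

#' @export
print.hh_fit <- function(x, ...) {
  cat("Global HH fit of HCN gating\n")
  print(x$params)
  ci <- x$ci68
  cat(sprintf("  68%% CI half-widths: A ±%.3g, V1/2 ±%.3g, V_alpha ±%.3g, V_beta ±%.3g\n",
              ci[1], ci[2], ci[3], ci[4]))
  cat(sprintf("  weighted SSE %.6g; converged: %s\n", x$weighted_sse,
              x$converged))
  invisible(x)
}

#' Read or write activation / time-constant tables as CSV
#'
#' Tables use columns `V_mV`, `value`, `sem`, `kind` where `kind` is one of
#' `activation`, `tau_activation`, `tau_deactivation`.
#'
#' @param path CSV file path.
#' @return `read_curve_csv`: a data.frame; `write_curve_csv`: `path`,
#'   invisibly.
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("V_mV", "value", "sem", "kind")
  if (!all(need %in% names(df)))
    stop("curve CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @param curve a curve data.frame (see [read_curve_csv()]).
#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Writes parameters, confidence half-widths, objective value and
#' convergence flag of an `hh_fit`, `boltzmann_fit` or `hill_fit`.
#'
#' @param fit a fit object from this package.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  if (inherits(fit, "hh_fit")) {
    x$params <- unclass(x$params)
  }
  x$covariance <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
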