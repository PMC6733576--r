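p0 <- hh_params("0mM_cAMP")
p1 <- hh_params("1mM_cAMP")

test_that("rate functions follow the exponential forms and their symmetries", {
  expect_equal(alpha_rate(p0$v_half, p0), p0$A)
  expect_equal(beta_rate(p0$v_half, p0), p0$A)
  ## direct high-precision evaluation as oracle
  expect_equal(alpha_rate(-150, p0), 6.907 * exp(47.9 / 18.71),
               tolerance = 1e-12)
  expect_equal(beta_rate(-70, p0), 6.907 * exp(32.1 / 21.73),
               tolerance = 1e-12)
  ## monotonicity
  V <- seq(-160, -40, by = 1)
  expect_true(all(diff(alpha_rate(V, p0)) < 0))
  expect_true(all(diff(beta_rate(V, p0)) > 0))
  ## mirror symmetry when the two voltage scales match
  ps <- rate_params(5, -100, 15, 15)
  expect_equal(beta_rate(-80, ps), alpha_rate(2 * (-100) - (-80), ps))
  expect_error(alpha_rate(NaN, p0), "finite")
  expect_error(rate_params(-1, -100, 10, 10), "A")
})

test_that("steady state is a Boltzmann with the composite slope", {
  expect_equal(steady_state(p0$v_half, p0), 0.5)
  expect_equal(steady_state(-80, p0),
               1 / (1 + exp(22.1 * (1 / 18.71 + 1 / 21.73))),
               tolerance = 1e-12)
  expect_lt(steady_state(1e3, p0), 1e-10)
  expect_gt(steady_state(-1e3, p0), 1 - 1e-10)
  V <- seq(-160, -40, by = 0.5)
  expect_true(all(diff(steady_state(V, p0)) < 0))
  ## exact agreement with boltzmann() at the matched slope factor
  k_eff <- 1 / (1 / p0$v_alpha + 1 / p0$v_beta)
  expect_lt(max(abs(steady_state(V, p0) - boltzmann(V, p0$v_half, k_eff))),
            1e-12)
})

test_that("time constant peaks at the midpoint and converts units", {
  expect_equal(time_constant(p0$v_half, p0), 1000 / (2 * p0$A))
  ## per-second reading of A: tau(-70) from the rate definitions
  a <- 6.907 * exp(-32.1 / 18.71); b <- 6.907 * exp(32.1 / 21.73)
  expect_equal(time_constant(-70, p0), 1000 / (a + b), tolerance = 1e-12)
  V <- seq(-250, 50, by = 1)
  tau <- time_constant(V, p0)
  imax <- which.max(tau)
  expect_true(imax > 1 && imax < length(V))   # single interior maximum
  expect_true(all(diff(tau[1:imax]) > 0) && all(diff(tau[imax:length(V)]) < 0))
  expect_lt(tau[1], 1); expect_lt(tau[length(V)], 1)
  pm <- rate_params(6.907, -102.1, 18.71, 21.73, rate_unit = "per_ms")
  expect_equal(time_constant(p0$v_half, p0),
               1000 * time_constant(pm$v_half, pm))
})

test_that("gate_step solves the gate ODE exactly", {
  V <- -120
  minf <- steady_state(V, p0)
  expect_equal(gate_step(minf, V, 5, p0), minf)
  expect_equal(gate_step(0.1, V, 1e9, p0), minf)
  ## two half steps equal one full step (exact-solution semigroup property)
  set.seed(11)
  for (i in 1:25) {
    m0 <- runif(1); Vr <- runif(1, -150, -50); dt <- runif(1, 0.01, 50)
    expect_equal(gate_step(gate_step(m0, Vr, dt / 2, p0), Vr, dt / 2, p0),
                 gate_step(m0, Vr, dt, p0), tolerance = 1e-14)
    expect_true(gate_step(m0, Vr, dt, p0) >= 0 &&
                gate_step(m0, Vr, dt, p0) <= 1)
  }
  expect_error(gate_step(0.5, -100, 0, p0), "dt")
  expect_error(gate_step(1.2, -100, 1, p0), "0, 1")
})

test_that("gate_step matches a fine-step explicit Euler oracle", {
  set.seed(21)
  for (i in 1:8) {
    m0 <- runif(1); V <- runif(1, -150, -50); tt <- runif(1, 0.5, 5)
    expect_lt(abs(gate_step(m0, V, tt, p0) - euler_gate(m0, V, tt, p0)),
              1e-6)   # absolute agreement with the fine-step oracle
  }
})

test_that("boltzmann has unit-slope offsets and valid range", {
  expect_equal(boltzmann(-103.3, -103.3, 9), 0.5)
  expect_equal(boltzmann(-103.3 - 9, -103.3, 9), 1 / (1 + exp(-1)))
  expect_error(boltzmann(-100, -103.3, -1), "k")
})

test_that("fit_boltzmann recovers exact parameters and rejects flat data", {
  V <- seq(-150, -80, by = 5)
  pts <- activation_points(V, boltzmann(V, -103.3, 9))
  fit <- fit_boltzmann(pts)
  expect_equal(fit$v_half, -103.3, tolerance = 1e-6)
  expect_equal(fit$k, 9, tolerance = 1e-6)
  fit2 <- fit_boltzmann(pts)
  expect_identical(fit$v_half, fit2$v_half)   # deterministic
  expect_error(fit_boltzmann(activation_points(V, rep(0.5, length(V)))),
               "degenerate")
  expect_error(fit_boltzmann(activation_points(V[1:3], c(0, 0.5, 1))),
               "4")
})

make_hh_data <- function(p, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Va <- seq(-150, -70, by = 5)
  Vt <- seq(-150, -70, by = 10)
  act <- steady_state(Va, p)
  ta <- time_constant(Vt[Vt <= -90], p)
  td <- time_constant(Vt[Vt > -110], p)
  if (noise > 0) {
    act <- act + rnorm(length(act), 0, noise * max(act))
    ta <- ta + rnorm(length(ta), 0, noise * max(ta))
    td <- td + rnorm(length(td), 0, noise * max(td))
  }
  list(act = activation_points(Va, act),
       tau_act = tau_points(Vt[Vt <= -90], pmax(ta, 1e-3), "activation"),
       tau_deact = tau_points(Vt[Vt > -110], pmax(td, 1e-3), "deactivation"))
}

test_that("fit_hh recovers the published parameter sets from noise-free data", {
  set.seed(1)
  for (p in list(p0, p1)) {
    d <- make_hh_data(p)
    fit <- fit_hh(d$act, d$tau_act, d$tau_deact, n_starts = 5)
    expect_true(fit$converged)
    expect_equal(fit$params$A, p$A, tolerance = 1e-3)
    expect_equal(fit$params$v_half, p$v_half, tolerance = 1e-3 * abs(p$v_half))
    expect_equal(fit$params$v_alpha, p$v_alpha, tolerance = 1e-3)
    expect_equal(fit$params$v_beta, p$v_beta, tolerance = 1e-3)
    expect_true(all(fit$ci68 >= 0))
    expect_lt(fit$weighted_sse, 1e-8)   # noise-free: global optimum is zero
  }
})

test_that("fit_hh exact-recovery holds over randomized physiological draws", {
  set.seed(42)
  for (i in 1:5) {
    p <- rate_params(runif(1, 3, 12), runif(1, -115, -90),
                     runif(1, 12, 30), runif(1, 12, 30))
    d <- make_hh_data(p)
    fit <- fit_hh(d$act, d$tau_act, d$tau_deact, n_starts = 4)
    expect_equal(fit$params$v_half, p$v_half, tolerance = 1e-2)
    expect_equal(fit$params$A, p$A, tolerance = 1e-2 * p$A)
  }
})

test_that("fit_hh 68% confidence intervals have near-nominal coverage", {
  set.seed(7)
  n_rep <- 200
  hits <- matrix(FALSE, n_rep, 2)
  for (r in seq_len(n_rep)) {
    d <- make_hh_data(p0, noise = 0.05)
    fit <- try(fit_hh(d$act, d$tau_act, d$tau_deact, n_starts = 1),
               silent = TRUE)
    if (inherits(fit, "try-error") || any(!is.finite(fit$ci68))) next
    hits[r, 1] <- abs(fit$params$v_half - p0$v_half) <= fit$ci68["v_half"]
    hits[r, 2] <- abs(fit$params$A - p0$A) <= fit$ci68["A"]
  }
  cov <- colMeans(hits)
  expect_true(all(cov >= 0.58 & cov <= 0.78))
})

test_that("curve tables and fit reports round-trip through CSV/JSON", {
  V <- seq(-150, -80, by = 10)
  pts <- activation_points(V, steady_state(V, p0), sem = 0.02)
  f <- tempfile(fileext = ".csv")
  write_curve_csv(pts, f)
  back <- read_curve_csv(f)
  expect_equal(back$value, pts$value)
  d <- make_hh_data(p0)
  fit <- fit_hh(d$act, d$tau_act, d$tau_deact, n_starts = 1)
  j <- tempfile(fileext = ".json")
  write_fit_json(fit, j)
  parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(parsed$params$v_half, fit$params$v_half, tolerance = 1e-9)
  expect_true(is.logical(parsed$converged))
  unlink(c(f, j))
})
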