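test_that("tail-current extraction round-trips a noise-free generator", {
  p <- rate_params(6.907, -103.3, 18, 18)   # Boltzmann slope 9 mV
  d <- gen_vclamp_dataset(p, noise_sd = 0, seed = 1)
  pts <- extract_tail_activation(d$sweeps)
  ## most hyperpolarized step is the normalization anchor
  expect_equal(pts$value[which.min(pts$V_mV)], 1)
  ## analytic truth: mean tail current over the window is proportional to
  ## the mean of the relaxing open fraction at the holding potential
  m_hold <- steady_state(-70, p)
  m_end <- steady_state(pts$V_mV, p) +
    (m_hold - steady_state(pts$V_mV, p)) *
    exp(-500 / time_constant(pts$V_mV, p))
  ## relaxation starts one sample before the detected step end, so the
  ## window samples have relaxed 1.0-3.0 ms at the holding potential
  decay <- mean(exp(-seq(1, 3, by = 0.5) / time_constant(-70, p)))
  tail_mean <- m_hold * (1 - decay) + decay * m_end
  truth <- tail_mean / tail_mean[which.min(pts$V_mV)]
  expect_lt(max(abs(pts$value - truth)), 1e-5)
  ## midpoint recovery carries only a small protocol-window offset
  fit <- fit_boltzmann(pts)
  expect_equal(fit$v_half, -103.3, tolerance = 3e-3)
  expect_equal(fit$k, 9, tolerance = 0.02)
})

test_that("tail extraction rejects degenerate inputs", {
  p <- rate_params(6.907, -103.3, 18, 18)
  d <- gen_vclamp_dataset(p, noise_sd = 0, t_tail = 100)
  expect_error(extract_tail_activation(d$sweeps, tail_window = c(200, 300)),
               "tail")
  d0 <- gen_vclamp_dataset(p, g_max = 0, noise_sd = 0)
  expect_error(extract_tail_activation(d0$sweeps), "zero maximum")
})

test_that("fit_monoexp recovers exact and noisy decay constants", {
  t <- seq(0, 400, by = 0.5)
  sw <- list(t = t, i = 12 * exp(-t / 50) + 3)
  fit <- fit_monoexp(sw, c(0, 400))
  expect_true(fit$ok)
  expect_equal(fit$tau, 50, tolerance = 1e-8)
  expect_equal(fit$amplitude, 12, tolerance = 1e-6)
  expect_equal(fit$offset, 3, tolerance = 1e-6)
  ## constant trace is flagged, not fitted
  flat <- fit_monoexp(list(t = t, i = rep(2, length(t))), c(0, 400))
  expect_false(flat$ok)
  ## noisy recovery stays near the generating value
  set.seed(5)
  noisy <- list(t = t, i = 12 * exp(-t / 50) + 3 + rnorm(length(t), 0, 0.2))
  nf <- fit_monoexp(noisy, c(0, 400))
  expect_true(nf$ok)
  expect_equal(nf$tau, 50, tolerance = 0.1)
  expect_error(fit_monoexp(sw, c(0, 2)), "10 samples")
})

make_ramp <- function(reversal, slope, act_V, v = seq(-60, 0, by = 2)) {
  ramp_iv(v, slope * (v - reversal), act_V)
}

test_that("reversal potential is the mean of pairwise line intersections", {
  ## three lines through a common point at -36 mV
  ramps <- list(make_ramp(-36, 0.5, -80), make_ramp(-36, 1.1, -110),
                make_ramp(-36, 1.9, -140))
  expect_equal(reversal_from_ramps(ramps)$reversal, -36, tolerance = 1e-9)
  ## lines constructed so the pairwise intersections sit at -20, -28, -24:
  ## slopes (0, 1, -1), intercepts (5, 25, -23); mean intersection -24
  l <- function(b, m, act) ramp_iv(seq(-60, 0, 2), b + m * seq(-60, 0, 2), act)
  ramps2 <- list(l(5, 0, -80), l(25, 1, -110), l(-23, -1, -140))
  expect_equal(sort(reversal_from_ramps(ramps2)$intersections),
               c(-28, -24, -20), tolerance = 1e-9)
  expect_equal(reversal_from_ramps(ramps2)$reversal, -24, tolerance = 1e-9)
  ## invariance under reordering
  expect_equal(reversal_from_ramps(ramps2[c(3, 1, 2)])$reversal,
               reversal_from_ramps(ramps2)$reversal)
})

test_that("random ramp triples match the closed-form intersection oracle", {
  set.seed(8)
  for (i in 1:20) {
    b <- runif(3, -50, 50); m <- runif(3, 0.2, 3) * sample(c(1, 1, 1), 3)
    ramps <- lapply(1:3, function(j)
      ramp_iv(seq(-60, 0, 2), b[j] + m[j] * seq(-60, 0, 2), c(-80, -110, -140)[j]))
    want <- mean(c(line_intersection_x(b[1], m[1], b[2], m[2]),
                   line_intersection_x(b[1], m[1], b[3], m[3]),
                   line_intersection_x(b[2], m[2], b[3], m[3])))
    expect_equal(reversal_from_ramps(ramps)$reversal, want, tolerance = 1e-6)
  }
  ## near-parallel pair is an error naming the pair
  par1 <- list(make_ramp(-36, 1, -80), make_ramp(-30, 1 + 1e-9, -110),
               make_ramp(-36, 2, -140))
  expect_error(reversal_from_ramps(par1), "parallel")
  expect_error(reversal_from_ramps(par1[1:2]), "three")
})

test_that("fit_hill recovers exact parameters and is units-equivariant", {
  concs <- c(3, 10, 30, 100, 300, 1000, 3000)
  pts <- dose_response_points(concs, hill(concs, 40, 18, 1))
  fit <- fit_hill(pts)
  expect_equal(fit$ec50, 40, tolerance = 1e-6)
  expect_equal(fit$s_max, 18, tolerance = 1e-6)
  expect_equal(fit$h, 1, tolerance = 1e-6)
  ## rescaling the concentration axis rescales only EC50
  pts10 <- dose_response_points(concs * 10, hill(concs, 40, 18, 1))
  fit10 <- fit_hill(pts10)
  expect_equal(fit10$ec50, 400, tolerance = 1e-5)
  expect_equal(fit10$s_max, 18, tolerance = 1e-5)
  expect_equal(fit10$h, 1, tolerance = 1e-4)
  expect_error(fit_hill(dose_response_points(c(10, 100), c(3, 9))), "distinct")
  ffix <- fit_hill(pts, fix_h = 1)
  expect_equal(ffix$ec50, 40, tolerance = 1e-6)
  expect_true(ffix$h_fixed)
})

test_that("endogenous cAMP point estimate inverts the mean Hill curve", {
  concs <- c(3, 10, 30, 100, 300, 1000, 3000)
  fit <- fit_hill(dose_response_points(concs, hill(concs, 40, 18, 1)))
  fit$covariance[] <- 0
  est <- estimate_endogenous_camp(fit, shift = 9, shift_sem = 0)
  expect_equal(est$conc_point, 40, tolerance = 1e-4)
  expect_equal(est$ci68_low, est$conc_point, tolerance = 1e-4)
  expect_equal(est$ci68_high, est$conc_point, tolerance = 1e-4)
  ## point estimate matches a bisection oracle for random parameter draws
  set.seed(31)
  for (i in 1:10) {
    ec <- runif(1, 5, 200); sm <- runif(1, 5, 30); h <- runif(1, 0.6, 2)
    f2 <- fit; f2$ec50 <- ec; f2$s_max <- sm; f2$h <- h
    sh <- runif(1, 0.1, 0.9) * sm
    want <- uniroot(function(cc) hill(cc, ec, sm, h) - sh,
                    c(1e-8, 1e10), tol = 1e-10)$root
    got <- estimate_endogenous_camp(f2, sh, 0)$conc_point
    expect_equal(got, want, tolerance = 1e-4)
  }
  expect_error(estimate_endogenous_camp(fit, shift = 30, shift_sem = 1),
               "between")
})

test_that("widening the shift uncertainty never narrows the CI", {
  set.seed(13)
  d <- gen_dose_response(seed = 99)
  fit <- fit_hill(d$points)
  widths <- vapply(c(0, 0.5, 1, 2, 4), function(s) {
    e <- estimate_endogenous_camp(fit, 8, s)
    expect_true(e$ci68_low <= e$conc_point && e$conc_point <= e$ci68_high)
    log(e$ci68_high / e$ci68_low)
  }, 0)
  expect_true(all(diff(widths) >= -1e-9))
})

test_that("peak_halfwidth handles analytic pulse shapes", {
  ## symmetric triangle: height 10, base 2 ms
  t <- seq(0, 4, by = 0.001)
  y <- pmax(0, 10 * (1 - abs(t - 2)))
  res <- peak_halfwidth(t, y, "positive", baseline = 0)
  expect_equal(res$amplitude, 10, tolerance = 1e-3)
  expect_equal(res$half_duration, 1, tolerance = 1e-3)
  ## Gaussian: half-width 2*sigma*sqrt(2 ln 2)
  sig <- 0.3
  yg <- 5 * exp(-(t - 2)^2 / (2 * sig^2))
  resg <- peak_halfwidth(t, yg, "positive", baseline = 0)
  expect_equal(resg$half_duration, 2 * sig * sqrt(2 * log(2)),
               tolerance = 1e-4)
  ## negative polarity
  resn <- peak_halfwidth(t, -yg, "negative", baseline = 0)
  expect_equal(resn$amplitude, 5, tolerance = 1e-6)
  expect_error(peak_halfwidth(t, rep(0, length(t)), "positive", baseline = 0),
               "peak")
})

test_that("peak_halfwidth agrees with a dense-resampling oracle", {
  set.seed(17)
  t <- seq(0, 10, by = 0.05)
  for (i in 1:10) {
    mu <- runif(1, 3, 7); s1 <- runif(1, 0.3, 1); a <- runif(1, 2, 20)
    y <- a * exp(-(t - mu)^2 / (2 * s1^2)) *
      (1 + 0.3 * sin((t - mu) / 2))        # smooth, single dominant peak
    got <- peak_halfwidth(t, y, "positive", baseline = 0)$half_duration
    want <- dense_halfwidth(t, y, 0)
    expect_equal(got, want, tolerance = 5e-3)
  }
})

test_that("dose-response tables round-trip through CSV", {
  d <- gen_dose_response(seed = 4)
  f <- tempfile(fileext = ".csv")
  write_dose_response_csv(d$points, f)
  back <- read_dose_response_csv(f)
  expect_equal(back$shift_mV, d$points$shift_mV)
  expect_equal(back$conc_uM, d$points$conc_uM)
  unlink(f)
})
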