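## Independent brute-force oracles, deliberately written without reusing the
## package's integration code paths.

## Fine-step explicit Euler for the HCN gate ODE dm/dt = a(1-m) - b m.
euler_gate <- function(m0, V, t_total, p, dt = 1e-4) {
  a <- alpha_rate(V, p); b <- beta_rate(V, p)
  if (p$rate_unit == "per_s") { a <- a / 1000; b <- b / 1000 }  # per ms
  m <- m0
  for (i in seq_len(round(t_total / dt)))
    m <- m + dt * (a * (1 - m) - b * m)
  m
}

## Explicit fine-step single-compartment oracle (classical RK4): same
## membrane equations as the cable core (one segment, no axial current),
## advanced by brute force with an independent derivative implementation.
rk4_single_compartment <- function(model, stim_amp, stim_on, stim_off,
                                   t_end, dt = 1e-4) {
  kin <- model$kinetics
  gate_inf <- function(V, p, sign) 1 / (1 + exp(sign * (V - p[["vh"]]) / p[["k"]]))
  gate_tau <- function(V, p) p[["tau_min"]] + p[["tau_amp"]] /
    cosh((V - p[["tau_vh"]]) / p[["tau_k"]])
  A_ms <- if (model$hcn$rate_unit == "per_s") model$hcn$A / 1000 else model$hcn$A
  deriv <- function(t, y) {
    v <- y[1]; mh <- y[2]; mna <- y[3]; hna <- y[4]; nk <- y[5]
    al <- A_ms * exp(-(v - model$hcn$v_half) / model$hcn$v_alpha)
    be <- A_ms * exp((v - model$hcn$v_half) / model$hcn$v_beta)
    i_ion <- model$g_nav[1] * mna^3 * hna * (v - model$e_na) +
      model$g_kv[1] * nk^kin$kv_power * (v - model$e_k) +
      model$g_leak_na[1] * (v - model$e_na) +
      model$g_leak_k[1] * (v - model$e_k) +
      mh * (model$g_hcn_na[1] * (v - model$e_na) +
            model$g_hcn_k[1] * (v - model$e_k))
    i_stim <- if (t >= stim_on && t < stim_off) stim_amp else 0
    c((-i_ion + i_stim) / model$cm_pF[1],
      al * (1 - mh) - be * mh,
      (gate_inf(v, kin$nav_m, -1) - mna) / gate_tau(v, kin$nav_m),
      (gate_inf(v, kin$nav_h, +1) - hna) / gate_tau(v, kin$nav_h),
      (gate_inf(v, kin$kv_n, -1) - nk) / gate_tau(v, kin$kv_n))
  }
  y <- c(model$v[1], model$gates[1, 1], model$gates[1, 2],
         model$gates[1, 3], model$gates[1, 4])
  n_steps <- round(t_end / dt)
  out_v <- numeric(n_steps + 1); out_v[1] <- y[1]
  for (s in seq_len(n_steps)) {
    t0 <- (s - 1) * dt
    k1 <- deriv(t0, y)
    k2 <- deriv(t0 + dt / 2, y + dt / 2 * k1)
    k3 <- deriv(t0 + dt / 2, y + dt / 2 * k2)
    k4 <- deriv(t0 + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out_v[s + 1] <- y[1]
  }
  list(t = seq(0, t_end, by = dt), v = out_v)
}

## Closed-form intersection of two lines y = b + m x.
line_intersection_x <- function(b1, m1, b2, m2) (b2 - b1) / (m1 - m2)

## Brute-force half-width of a sampled pulse by dense linear resampling.
dense_halfwidth <- function(t, y, baseline, n = 200001L) {
  tt <- seq(min(t), max(t), length.out = n)
  yy <- stats::approx(t, y, xout = tt)$y
  half <- baseline + (max(yy) - baseline) / 2
  above <- yy >= half
  range_idx <- range(which(above))
  tt[range_idx[2]] - tt[range_idx[1]]
}
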