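test_that("ATP conversion follows the 3 Na+ : 1 ATP pump stoichiometry", {
  expect_equal(atp_from_na(0), 0)
  expect_equal(atp_from_na(1), (1e-12 / 1.602176634e-19) / 3)
  a <- runif(1, 0, 5); b <- runif(1, 0, 5)
  expect_equal(atp_from_na(a + b), atp_from_na(a) + atp_from_na(b))
  expect_error(atp_from_na(-1), ">= 0")
})

test_that("resting Na influx decomposes per the analytic pathway oracle", {
  m <- get_model("control")
  sim <- integrate_model(m, dt = 0.1, t_end = 50,
                         record = m$bouton_center[1], record_pathways = TRUE)
  chg <- na_influx(sim)
  ## single-compartment oracle from printed densities, the Na/K split and
  ## the model's resting potential (density ratios uniform across regions)
  v0 <- m$v[m$bouton_center[1]]
  mh <- steady_state(v0, m$hcn)
  area_chain <- sum(m$area[m$chain_mask] *
                    ifelse(m$seg_type[m$chain_mask] == "internode", 0.1, 1))
  split <- hcn_split(0.3, 55, -97, -23.3)
  i_leak <- 0.0138 * 1e-3 * (v0 - 55) * area_chain           # pA
  i_hcn <- split[["g_hcn_na"]] * mh * 1e-3 * (v0 - 55) * area_chain
  expect_equal(chg[["leak_na"]], -i_leak * 50 / 1000, tolerance = 0.05)
  expect_equal(chg[["hcn_na"]], -i_hcn * 50 / 1000, tolerance = 0.05)
  ## NaV window influx at rest is a minor contribution
  expect_lt(chg[["nav"]], 0.5 * chg[["total"]])
  expect_equal(chg[["total"]],
               chg[["nav"]] + chg[["leak_na"]] + chg[["hcn_na"]])
  expect_error(na_influx(integrate_model(m, dt = 0.1, t_end = 1,
                                         record = 1L)), "pathway")
})

test_that("zero-current windows carry zero charge", {
  m <- get_model("no_hcn")
  sim <- integrate_model(m, dt = 0.1, t_end = 10,
                         record = m$bouton_center[1], record_pathways = TRUE)
  expect_equal(na_influx(sim)[["hcn_na"]], 0)
})

test_that("resting cost doubles when leak and HCN densities double", {
  den2 <- channel_densities(g_leak_na = 2 * 0.0138, g_leak_k = 2 * 0.18,
                            g_hcn = 2 * 0.3, g_hcn_axon = 2 * 0.03)
  m1 <- get_model("control")
  m2 <- init_steady_state(build_model("control", densities = den2))
  ## the doubled mixture has the same resting potential, so the influx
  ## scales linearly
  expect_equal(m2$v[m2$bouton_center[8]], m1$v[m1$bouton_center[8]],
               tolerance = 0.02)
  c1 <- resting_cost(m1)$atp_rest_per_mm_s
  c2 <- resting_cost(m2)$atp_rest_per_mm_s
  expect_equal(c2 / c1, 2, tolerance = 0.01)
})

test_that("energy scales linearly with membrane area at fixed voltages", {
  geo2 <- axon_geometry(bouton_diam = 16, internode_diam = 1.6,
                        wm_diam = 2.4)
  m1 <- get_model("control")
  m2 <- init_steady_state(build_model("control", geometry = geo2))
  expect_equal(m2$v[m2$bouton_center[8]], m1$v[m1$bouton_center[8]],
               tolerance = 0.02)
  expect_equal(resting_cost(m2)$atp_rest_per_mm_s /
                 resting_cost(m1)$atp_rest_per_mm_s, 2, tolerance = 0.01)
})

test_that("AP cost is resting-subtracted and matches the charge integrals", {
  m <- get_model("control")
  amp <- get_common_amp()
  cost <- ap_cost(m, stim_amplitude = amp)
  expect_gt(cost$atp_per_ap_per_mm, 0)
  expect_false(cost$subthreshold)
  ## a subthreshold pulse costs (almost) nothing
  sub <- ap_cost(m, stim_amplitude = 20)
  expect_true(sub$subthreshold)
  expect_lt(sub$atp_per_ap_per_mm, 0.02 * cost$atp_per_ap_per_mm)
  ## brute-force oracle: per-segment charge integrals over the whole run
  ## must reproduce the pathway-series integral used by na_influx
  sim <- integrate_model(m,
    stimuli = list(list(site = 1L, onset = 0.5, duration = 0.1,
                        amplitude = amp)),
    dt = 0.00125, t_end = 15, record = m$bouton_center[1],
    record_pathways = TRUE)
  from_series <- na_influx(sim)
  q <- colSums(sim$charge_seg[m$chain_mask, , drop = FALSE])
  expect_equal(from_series[["nav"]], -q[["nav"]],
               tolerance = 1e-9 * abs(q[["nav"]]))
  expect_equal(from_series[["hcn_na"]], -q[["hcn_na"]],
               tolerance = 1e-9 * abs(q[["hcn_na"]]))
})

test_that("the HCN energy share declines with firing rate", {
  expect_error(cost_share(2, 1, 1, -1), ">= 0")
  f <- c(0, 1, 4, 10, 40, 100)
  sh <- cost_share(3.6e7, 2e7, 6e7, f)
  expect_equal(which.max(sh), 1L)
  expect_true(all(diff(sh) < 0))
})

test_that("energy reports serialize to JSON", {
  m <- get_model("control")
  rep <- resting_cost(m)
  f <- tempfile(fileext = ".json")
  write_energy_json(rep, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$atp_rest_per_mm_s, rep$atp_rest_per_mm_s,
               tolerance = 1e-9)
  unlink(f)
})
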