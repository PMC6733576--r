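test_that("hcn_split reproduces the mixed reversal potential", {
  s <- hcn_split(0.3, 55, -97, -23.3)
  expect_equal(sum(s), 0.3)
  ## the defining identity: conductance-weighted reversal equals e_hcn
  expect_equal((s[["g_hcn_na"]] * 55 + s[["g_hcn_k"]] * (-97)) / sum(s),
               -23.3, tolerance = 1e-12)
  expect_equal(unname(hcn_split(0.3, 55, -97, 55)),
               c(0.3, 0))                       # e_hcn = e_na: all Na
  expect_equal(unname(hcn_split(0, 55, -97, -23.3)), c(0, 0))
  expect_error(hcn_split(0.3, 55, -97, 60), "between")
  expect_error(hcn_split(0.3, -97, 55, 0), "exceed")
})

test_that("build_model assembles the printed geometry and densities", {
  m <- build_model("control")
  expect_equal(length(unique(m$seg_sec)), 31)          # 2*15 + 1 sections
  ## bouton lateral area per section: pi * 8 * 8
  b1 <- which(m$seg_type == "bouton")[1:3]
  expect_equal(sum(m$area[b1]), pi * 8 * 8, tolerance = 1e-9)
  ## control bouton HCN density back out to 0.3 pS/um2
  expect_equal((m$g_hcn_na[b1[1]] + m$g_hcn_k[b1[1]]) / m$area[b1[1]] * 1000,
               0.3, tolerance = 1e-9)
  ## internodal HCN density 0.03, leaks scaled by 10
  i1 <- which(m$seg_type == "internode")[1]
  expect_equal((m$g_hcn_na[i1] + m$g_hcn_k[i1]) / m$area[i1] * 1000, 0.03,
               tolerance = 1e-9)
  expect_equal(m$g_leak_k[i1] / m$area[i1] * 1000, 0.018, tolerance = 1e-9)
  mr <- build_model("rm_model")
  expect_equal(mr$e_hcn, -85.5)
  expect_equal((mr$g_hcn_na[b1[1]] + mr$g_hcn_k[b1[1]]) / mr$area[b1[1]] * 1000,
               1, tolerance = 1e-9)
  mv <- build_model("vm_model")
  expect_equal(mv$e_k, -90)
  expect_true(all(mv$g_hcn_na == 0))
  expect_error(build_model("bogus"))
})

test_that("resting potentials match the leak-mixture analytic oracle", {
  ## no HCN, negligible NaV/KV window current: rest is the leak mixture
  mix <- function(gna, gk, ena, ek) (gna * ena + gk * ek) / (gna + gk)
  mn <- get_model("no_hcn")
  expect_equal(mn$v[mn$bouton_center[8]],
               mix(0.0138, 0.18, 55, -97), tolerance = 0.05)
  mv <- get_model("vm_model")
  expect_equal(mv$v[mv$bouton_center[8]],
               mix(0.0138, 0.18, 55, -90), tolerance = 0.05)
  ## spatial uniformity of the unstimulated rest
  expect_lt(diff(range(mn$v[mn$bouton_center])), 1e-6)
  ## HCN depolarizes; 1 mM cAMP gating depolarizes further
  rest <- function(v) get_model(v)$v[get_model(v)$bouton_center[8]]
  expect_gt(rest("control"), rest("no_hcn"))
  expect_gt(rest("camp_1mM"), rest("control"))
})

test_that("rest is independent of the spatial discretization", {
  geo2 <- axon_geometry(nseg_bouton = 7L, nseg_internode = 15L, nseg_wm = 21L)
  m2 <- init_steady_state(build_model("control", geometry = geo2))
  m1 <- get_model("control")
  expect_lt(abs(m1$v[m1$bouton_center[8]] - m2$v[m2$bouton_center[8]]), 0.05)
})

test_that("an equilibrated model stays at rest without stimulus", {
  m <- get_model("control")
  sim <- integrate_model(m, dt = 0.05, t_end = 100,
                         record = m$bouton_center[8])
  expect_lt(max(abs(sim$vm[, 1] - sim$vm[1, 1])), 1e-6)
})

test_that("charge is conserved across capacitive, ionic and stimulus paths", {
  m <- get_model("control")
  sim <- integrate_model(m,
    stimuli = list(list(site = 1L, onset = 0.5, duration = 0.1,
                        amplitude = get_common_amp())),
    dt = 0.00125, t_end = 12, record = m$bouton_center[8])
  q <- colSums(sim$charge_seg)
  q_ion <- sum(q[c("nav", "kv", "leak_na", "leak_k", "hcn_na", "hcn_k")])
  q_cap <- sum(sim$cm_pF * (sim$v_final - sim$v_start)) / 1000   # pC
  ## stimulus charge = capacitive charge + net ionic charge
  expect_equal(q[["stim"]], q_cap + q_ion,
               tolerance = 1e-3 * abs(q[["stim"]]))
})

test_that("an AP propagates through the bouton chain in order", {
  m <- get_model("control")
  sim <- integrate_model(m,
    stimuli = list(list(site = 1L, onset = 0.5, duration = 0.1,
                        amplitude = get_common_amp())),
    dt = 0.00125, t_end = 15, record = m$bouton_center)
  peaks <- apply(sim$vm, 2, max)
  expect_true(all(peaks > 0))
  t_peaks <- apply(sim$vm, 2, function(v) sim$t[which.max(v)])
  expect_true(all(diff(t_peaks) > 0))   # orthodromic order, boutons 1..15
})

test_that("halving the time step leaves recorded voltages unchanged", {
  m <- get_model("control")
  stim <- list(list(site = 1L, onset = 0.5, duration = 0.1,
                    amplitude = get_common_amp()))
  s1 <- integrate_model(m, stim, dt = 0.00125, t_end = 10,
                        record = m$bouton_center[8])
  s2 <- integrate_model(m, stim, dt = 0.000625, t_end = 10,
                        record = m$bouton_center[8])
  expect_lt(max(abs(s1$vm[, 1] - s2$vm[seq(1, nrow(s2$vm), 2), 1])), 0.1)
})

test_that("the implicit integrator matches an explicit fine-step oracle", {
  m <- single_bouton_model("control")
  amp <- 120   # pA, suprathreshold for one isolated bouton
  sim <- integrate_model(m,
    stimuli = list(list(site = 1L, onset = 1, duration = 1, amplitude = amp)),
    dt = 1e-4, t_end = 10, record = 1L)
  oracle <- rk4_single_compartment(m, amp, 1, 2, 10, dt = 1e-4)
  on_grid <- oracle$v
  expect_gt(max(sim$vm[, 1]), 0)        # the comparison spans a real AP
  expect_lt(max(abs(sim$vm[, 1] - on_grid)), 0.2)
})

test_that("integration rejects oversized steps and bad stimuli", {
  m <- get_model("control")
  expect_error(integrate_model(m, dt = 0.5, t_end = 1), "0.2")
  expect_error(integrate_model(m,
    stimuli = list(list(site = 1e5, onset = 0, duration = 1, amplitude = 1)),
    dt = 0.01, t_end = 1), "site")
})

test_that("simulation results export to CSV plus JSON sidecar", {
  m <- get_model("control")
  sim <- integrate_model(m, dt = 0.05, t_end = 5, record = m$bouton_center[1:2])
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_sim_result(sim, fc, fj)
  df <- read.csv(fc)
  expect_equal(nrow(df), length(sim$t))
  side <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_true(all(c("nav", "hcn_na") %in% names(side$pathway_charge_pC)))
  unlink(c(fc, fj))
})
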