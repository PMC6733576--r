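#' Geometry of the mossy-fiber axon model
#'
#' The model is an unbranched chain: one long cylinder representing the
#' axon in the white matter, followed by `n_units` repeats of a myelinated
#' internode plus an en passant bouton. Cylinder areas are lateral only
#' (no end caps).
#'
#' @param n_units number of bouton/internode repeats (default 15).
#' @param bouton_len,bouton_diam bouton length and diameter (µm).
#' @param internode_len,internode_diam internode length and diameter (µm).
#' @param wm_len,wm_diam white-matter cylinder length and diameter (µm).
#' @param nseg_bouton,nseg_internode,nseg_wm segments per section.
#' @return list of class `axon_geometry`.
#' @export
axon_geometry <- function(n_units = 15L,
                          bouton_len = 8, bouton_diam = 8,
                          internode_len = 35, internode_diam = 0.8,
                          wm_len = 150, wm_diam = 1.2,
                          nseg_bouton = 3L, nseg_internode = 7L,
                          nseg_wm = 11L) {
  vals <- c(bouton_len, bouton_diam, internode_len, internode_diam,
            wm_len, wm_diam)
  if (any(vals <= 0)) stop("all lengths and diameters must be > 0")
  structure(list(n_units = as.integer(n_units),
                 bouton_len = bouton_len, bouton_diam = bouton_diam,
                 internode_len = internode_len,
                 internode_diam = internode_diam,
                 wm_len = wm_len, wm_diam = wm_diam,
                 nseg_bouton = as.integer(nseg_bouton),
                 nseg_internode = as.integer(nseg_internode),
                 nseg_wm = as.integer(nseg_wm)),
            class = "axon_geometry")
}

#' Membrane specification
#'
#' @param cm specific membrane capacitance (µF/cm²).
#' @param ri axial (cytoplasmic) resistivity (Ω·cm).
#' @param e_na,e_k,e_hcn Na+, K+ and HCN (mixed) reversal potentials (mV).
#' @param myelin_factor divisor applied to internodal capacitance and
#'   conductance densities (myelination).
#' @param wm_myelinated whether the white-matter cylinder is treated as
#'   myelinated (scaled by `myelin_factor`) as well.
#' @return list of class `membrane_spec`.
#' @export
membrane_spec <- function(cm = 0.9, ri = 120,
                          e_na = 55, e_k = -97, e_hcn = -23.3,
                          myelin_factor = 10, wm_myelinated = TRUE) {
  if (cm <= 0 || ri <= 0) stop("'cm' and 'ri' must be > 0")
  if (!(e_na > e_hcn && e_hcn > e_k))
    stop("reversals must be ordered e_na > e_hcn > e_k")
  structure(list(cm = cm, ri = ri, e_na = e_na, e_k = e_k, e_hcn = e_hcn,
                 myelin_factor = myelin_factor,
                 wm_myelinated = wm_myelinated),
            class = "membrane_spec")
}

#' Channel densities (bouton values; internodes are scaled)
#'
#' Densities in pS/µm². NaV and KV are restricted to boutons (zero in the
#' internodes); leak and HCN densities are divided by the myelin factor in
#' the internodes.
#'
#' @param g_nav,g_kv voltage-gated Na+ / K+ densities (bouton).
#' @param g_leak_na,g_leak_k Na+ / K+ leak densities (bouton).
#' @param g_hcn HCN density in the bouton.
#' @param g_hcn_axon HCN density in internodes (not scaled further).
#' @return list of class `channel_densities`.
#' @export
channel_densities <- function(g_nav = 2000, g_kv = 1000,
                              g_leak_na = 0.0138, g_leak_k = 0.18,
                              g_hcn = 0.3, g_hcn_axon = 0.03) {
  v <- c(g_nav, g_kv, g_leak_na, g_leak_k, g_hcn, g_hcn_axon)
  if (any(v < 0)) stop("densities must be >= 0")
  structure(list(g_nav = g_nav, g_kv = g_kv, g_leak_na = g_leak_na,
                 g_leak_k = g_leak_k, g_hcn = g_hcn,
                 g_hcn_axon = g_hcn_axon),
            class = "channel_densities")
}

#' Split the HCN conductance into Na+ and K+ partial conductances
#'
#' HCN channels carry a mixed Na+/K+ current. For separate Na+ and K+
#' bookkeeping (ATP accounting) the total HCN conductance is split so that
#' the conductance-weighted reversal of the two branches reproduces the
#' measured mixed reversal potential:
#' \deqn{ratio_K = (e_{Na} - e_{HCN}) / (e_{Na} - e_K), \quad
#'       g_{HCN,K} = ratio_K\, g_{HCN}, \quad
#'       g_{HCN,Na} = (1 - ratio_K)\, g_{HCN},}
#' which guarantees
#' \eqn{(g_{Na} e_{Na} + g_K e_K)/(g_{Na} + g_K) = e_{HCN}}.
#'
#' @param g_hcn total HCN conductance density (pS/µm²), >= 0.
#' @param e_na,e_k,e_hcn reversal potentials (mV); `e_hcn` must lie between
#'   `e_k` and `e_na`.
#' @return named numeric: `g_hcn_na`, `g_hcn_k`.
#' @export
hcn_split <- function(g_hcn, e_na, e_k, e_hcn) {
  if (e_na <= e_k) stop("'e_na' must exceed 'e_k'")
  ratio_k <- (e_na - e_hcn) / (e_na - e_k)
  if (ratio_k < 0 || ratio_k > 1)
    stop("inconsistent reversals: e_hcn must lie between e_k and e_na")
  c(g_hcn_na = (1 - ratio_k) * g_hcn, g_hcn_k = ratio_k * g_hcn)
}

#' Default NaV / KV gate kinetics
#'
#' The voltage-gated Na+ (m³h) and K+ (n^p) mechanisms are parameterized in
#' steady-state/time-constant form: `inf(V) = 1/(1 + exp(±(V - vh)/k))` and
#' `tau(V) = tau_min + tau_amp / cosh((V - tau_vh)/tau_k)` (ms). Defaults
#' are calibrated so that a bouton fires a single brief action potential
#' and the NaV steady-state availability is 50% at −65 mV.
#'
#' @return named list with elements `nav_m`, `nav_h`, `kv_n` (each a named
#'   numeric of vh, k, tau_min, tau_amp, tau_vh, tau_k) and `kv_power`.
#' @export
default_gate_kinetics <- function() {
  list(
    nav_m = c(vh = -38, k = 6, tau_min = 0.02, tau_amp = 0.12,
              tau_vh = -38, tau_k = 12),
    nav_h = c(vh = -65, k = 8, tau_min = 0.12, tau_amp = 1.0,
              tau_vh = -65, tau_k = 12),
    kv_n = c(vh = -30, k = 8, tau_min = 0.15, tau_amp = 0.6,
             tau_vh = -50, tau_k = 12),
    kv_power = 4)
}

#' Steady-state NaV availability
#'
#' Steady-state value of the NaV inactivation gate h at a voltage: the
#' fraction of Na+ channels not inactivated.
#'
#' @param V voltage (mV), vectorized.
#' @param kin gate kinetics, see [default_gate_kinetics()].
#' @return availability in (0, 1).
#' @export
nav_availability <- function(V, kin = default_gate_kinetics()) {
  p <- kin$nav_h
  1 / (1 + exp((V - p[["vh"]]) / p[["k"]]))
}

#' Build a compartmental mossy-fiber axon model
#'
#' Assembles the 31-section chain (white-matter cylinder, then 15 repeats
#' of internode + bouton), applies the per-region densities and the model
#' variant, and sets all state variables to provisional resting values
#' (call [init_steady_state()] before simulating).
#'
#' Variants:
#' \describe{
#'   \item{control}{full model, 0 mM cAMP HCN gating.}
#'   \item{no_hcn}{HCN conductance removed (ZD7288 condition).}
#'   \item{camp_1mM}{HCN gating replaced by the 1 mM cAMP parameter set.}
#'   \item{vm_model}{HCN removed and `e_k` raised to −90 mV: reproduces
#'     only the HCN-mediated depolarization.}
#'   \item{rm_model}{HCN reversal lowered to −85.5 mV and density raised to
#'     1 / 0.1 pS/µm²: reproduces only the HCN-mediated conductance
#'     increase.}
#' }
#'
#' @param variant one of `"control"`, `"no_hcn"`, `"camp_1mM"`,
#'   `"vm_model"`, `"rm_model"`.
#' @param geometry an [axon_geometry()].
#' @param membrane a [membrane_spec()].
#' @param densities a [channel_densities()].
#' @param kinetics NaV/KV gate kinetics, see [default_gate_kinetics()].
#' @param hcn HCN gate parameters ([rate_params()]); the default depends on
#'   the variant (0 mM set, or 1 mM set for `camp_1mM`).
#' @return list of class `axon_model`.
#' @export
build_model <- function(variant = c("control", "no_hcn", "camp_1mM",
                                    "vm_model", "rm_model"),
                        geometry = axon_geometry(),
                        membrane = membrane_spec(),
                        densities = channel_densities(),
                        kinetics = default_gate_kinetics(),
                        hcn = NULL) {
  variant <- match.arg(variant)
  geo <- geometry; mem <- membrane; den <- densities

  if (is.null(hcn))
    hcn <- hh_params(if (variant == "camp_1mM") "1mM_cAMP" else "0mM_cAMP")
  e_hcn <- mem$e_hcn
  g_hcn_b <- den$g_hcn; g_hcn_a <- den$g_hcn_axon
  e_k <- mem$e_k
  if (variant %in% c("no_hcn", "vm_model")) { g_hcn_b <- 0; g_hcn_a <- 0 }
  if (variant == "vm_model") e_k <- -90
  if (variant == "rm_model") { e_hcn <- -85.5; g_hcn_b <- 1; g_hcn_a <- 0.1 }

  ## section table: wm, then (internode, bouton) x n_units
  sec <- data.frame(
    type = c("wm", rep(c("internode", "bouton"), geo$n_units)),
    L = c(geo$wm_len, rep(c(geo$internode_len, geo$bouton_len), geo$n_units)),
    diam = c(geo$wm_diam,
             rep(c(geo$internode_diam, geo$bouton_diam), geo$n_units)),
    nseg = c(geo$nseg_wm,
             rep(c(geo$nseg_internode, geo$nseg_bouton), geo$n_units)),
    stringsAsFactors = FALSE)
  sec$unit <- c(NA, rep(seq_len(geo$n_units), each = 2L))

  n_seg <- sum(sec$nseg)
  seg_sec <- rep(seq_len(nrow(sec)), sec$nseg)
  seg_type <- sec$type[seg_sec]
  seg_L <- sec$L[seg_sec] / sec$nseg[seg_sec]
  seg_diam <- sec$diam[seg_sec]
  area <- pi * seg_diam * seg_L                       # µm², no end caps
  pos <- cumsum(seg_L) - seg_L / 2                    # segment centers, µm

  myel <- ifelse(seg_type == "internode", mem$myelin_factor,
          ifelse(seg_type == "wm" & mem$wm_myelinated, mem$myelin_factor, 1))

  cm_pF <- mem$cm * 1e-2 * area / myel   # µF/cm² -> pF/µm² is 1e-2
  dens_scale <- 1 / myel
  is_bouton <- seg_type == "bouton"
  g_nav <- ifelse(is_bouton, den$g_nav, 0) * area * 1e-3        # pS -> nS
  g_kv <- ifelse(is_bouton, den$g_kv, 0) * area * 1e-3
  g_leak_na <- den$g_leak_na * dens_scale * area * 1e-3
  g_leak_k <- den$g_leak_k * dens_scale * area * 1e-3
  ## wm cylinder and internodes share the printed axonal HCN density
  g_hcn_dens <- ifelse(is_bouton, g_hcn_b, g_hcn_a)
  g_hcn_tot <- g_hcn_dens * area * 1e-3
  ## split against the ionic reversals of the membrane (not the variant's
  ## possibly shifted leak e_k)
  split <- hcn_split(1, mem$e_na, mem$e_k, e_hcn)
  g_hcn_na <- g_hcn_tot * split[["g_hcn_na"]]
  g_hcn_k <- g_hcn_tot * split[["g_hcn_k"]]

  ## axial conductances between adjacent segments (series half-cylinders)
  ri_ohm_um <- mem$ri * 1e4                            # Ω·cm -> Ω·µm
  half_R <- ri_ohm_um * (seg_L / 2) / (pi * (seg_diam / 2)^2)   # Ω
  g_axial <- 1e9 / (half_R[-n_seg] + half_R[-1])       # nS

  bouton_center <- which(is_bouton &
    stats::ave(seq_len(n_seg), seg_sec, FUN = function(ix)
      ix == ix[ceiling(length(ix) / 2)]) == 1)

  model <- structure(list(
    variant = variant, geometry = geo, membrane = mem, densities = den,
    kinetics = kinetics, hcn = hcn,
    e_na = mem$e_na, e_k = e_k, e_hcn = e_hcn,
    n_seg = n_seg, seg_type = seg_type, seg_sec = seg_sec,
    area = area, pos = pos, cm_pF = cm_pF,
    g_nav = g_nav, g_kv = g_kv,
    g_leak_na = g_leak_na, g_leak_k = g_leak_k,
    g_hcn_na = g_hcn_na, g_hcn_k = g_hcn_k,
    g_axial = g_axial,
    chain_mask = seg_type != "wm",
    bouton_center = bouton_center,
    v = rep(-80, n_seg),
    gates = NULL, at_rest = FALSE), class = "axon_model")
  model$gates <- .gates_at(model, model$v)
  model
}

#' @export
print.axon_model <- function(x, ...) {
  cat(sprintf("Mossy-fiber axon model [%s]: %d sections, %d segments\n",
              x$variant, length(unique(x$seg_sec)), x$n_seg))
  cat(sprintf("  e_na %.1f, e_k %.1f, e_hcn %.1f mV; HCN gate '%s'\n",
              x$e_na, x$e_k, x$e_hcn, x$hcn$label))
  if (x$at_rest)
    cat(sprintf("  at steady state, bouton Vm = %.2f mV\n",
                x$v[x$bouton_center[1]]))
  invisible(x)
}

## steady-state gate values at given voltages
.gates_at <- function(model, v) {
  kin <- model$kinetics
  p <- model$hcn
  minf_h <- steady_state(v, p)
  m <- 1 / (1 + exp(-(v - kin$nav_m[["vh"]]) / kin$nav_m[["k"]]))
  h <- 1 / (1 + exp((v - kin$nav_h[["vh"]]) / kin$nav_h[["k"]]))
  n <- 1 / (1 + exp(-(v - kin$kv_n[["vh"]]) / kin$kv_n[["k"]]))
  cbind(m_hcn = minf_h, nav_m = m, nav_h = h, kv_n = n)
}

## HCN A in 1/ms for the C++ core
.hcn_A_per_ms <- function(p) if (p$rate_unit == "per_s") p$A / 1000 else p$A

.run_core <- function(model, dt, n_steps, theta = 0.5, stim = NULL,
                      record_idx = model$bouton_center,
                      record_pathways = FALSE) {
  if (is.null(stim)) stim <- matrix(numeric(0), 0, 4)
  kin <- model$kinetics
  cable_integrate_cpp(
    model$cm_pF, model$g_nav, model$g_kv,
    model$g_leak_na, model$g_leak_k, model$g_hcn_na, model$g_hcn_k,
    model$e_na, model$e_k,
    c(.hcn_A_per_ms(model$hcn), model$hcn$v_half, model$hcn$v_alpha,
      model$hcn$v_beta),
    kin$nav_m, kin$nav_h, kin$kv_n, kin$kv_power,
    model$g_axial, model$v, model$gates,
    dt, as.integer(n_steps), theta, stim,
    as.integer(record_idx), model$chain_mask, record_pathways)
}

#' Equilibrate a model to its resting steady state
#'
#' Runs a coarse 1 s pre-equilibration (backward Euler, dt = 5 ms) followed
#' by a finer settling run, then verifies stationarity
#' (max |dV/dt| below `tol`).
#'
#' @param model an [build_model()] result.
#' @param tol stationarity tolerance (mV/ms) on every segment.
#' @return the model with `v`/`gates` at the fixed point and
#'   `at_rest = TRUE`.
#' @export
init_steady_state <- function(model, tol = 1e-6) {
  ## start from the leak-mixture voltage as a sane initial guess
  v0 <- (sum(model$g_leak_na) * model$e_na + sum(model$g_leak_k) * model$e_k) /
    (sum(model$g_leak_na) + sum(model$g_leak_k))
  model$v <- rep(v0, model$n_seg)
  model$gates <- .gates_at(model, model$v)
  res <- .run_core(model, dt = 5, n_steps = 200L, theta = 1)
  model$v <- res$v_final; model$gates <- res$gates_final
  res <- .run_core(model, dt = 1, n_steps = 500L, theta = 1)
  model$v <- res$v_final; model$gates <- res$gates_final
  ## stationarity check over a short fine run
  chk <- .run_core(model, dt = 0.5, n_steps = 20L, theta = 1,
                   record_idx = seq_len(model$n_seg))
  dv <- max(abs(chk$vm[nrow(chk$vm), ] - chk$vm[1, ])) / (0.5 * 20)
  if (dv > tol)
    stop(sprintf("equilibration failed: residual |dV/dt| = %.3g mV/ms", dv))
  model$at_rest <- TRUE
  model
}

#' Integrate the cable model
#'
#' Implicit (theta-method) integration of the cable equation with HH
#' channel gating; default Crank-Nicolson (`theta = 0.5`). Each membrane
#' pathway's current is recorded separately.
#'
#' @param model an equilibrated [axon_model] (see [init_steady_state()]).
#' @param stimuli list of stimuli, each
#'   `list(site =, onset =, duration =, amplitude =)` with `site` a segment
#'   index, times in ms, amplitude in pA (positive = depolarizing).
#' @param dt time step (ms), must be <= 0.2; default 0.00125.
#' @param t_end end time (ms).
#' @param record segment indices whose Vm is recorded (default: all bouton
#'   centers).
#' @param record_pathways record per-pathway membrane current time series
#'   (summed over the bouton/internode chain and the white-matter cylinder
#'   separately).
#' @param theta implicitness parameter (0.5 = Crank-Nicolson, 1 = backward
#'   Euler).
#' @return list of class `sim_result`: `t` (ms), `vm` (matrix, one column
#'   per recorded segment), `record` (indices), `pos` (their positions,
#'   µm), `charge_seg` (segments x pathways, pC), `currents` (when
#'   recorded: `$chain` and `$wm` step-midpoint pathway current matrices,
#'   pA), `pathways` (names), `v_final`, `gates_final`, `stimuli`, `dt`.
#' @export
integrate_model <- function(model, stimuli = list(), dt = 0.00125, t_end,
                            record = model$bouton_center,
                            record_pathways = FALSE, theta = 0.5) {
  if (dt > 0.2) stop("'dt' must be <= 0.2 ms")
  if (!model$at_rest)
    warning("model is not equilibrated; call init_steady_state() first")
  stim <- if (length(stimuli)) {
    do.call(rbind, lapply(stimuli, function(s) {
      if (s$site < 1 || s$site > model$n_seg) stop("invalid stimulus site")
      c(s$site, s$onset, s$onset + s$duration, s$amplitude)
    }))
  } else matrix(numeric(0), 0, 4)
  n_steps <- ceiling(t_end / dt)
  res <- .run_core(model, dt, n_steps, theta = theta, stim = stim,
                   record_idx = record, record_pathways = record_pathways)
  if (isTRUE(res$diverged))
    stop(sprintf("integration diverged at t = %.4g ms", res$t_fail))
  pathways <- c("nav", "kv", "leak_na", "leak_k", "hcn_na", "hcn_k", "stim")
  colnames(res$charge_seg) <- pathways
  out <- list(t = res$t, vm = res$vm, record = record,
              pos = model$pos[record],
              charge_seg = res$charge_seg / 1000,      # pA*ms -> pC
              pathways = pathways,
              v_final = res$v_final, gates_final = res$gates_final,
              v_start = model$v, cm_pF = model$cm_pF,
              stimuli = stimuli, dt = dt)
  if (record_pathways) {
    colnames(res$path_chain) <- pathways
    colnames(res$path_wm) <- pathways
    out$currents <- list(chain = res$path_chain, wm = res$path_wm)
  }
  structure(out, class = "sim_result")
}

#' Export a simulation result
#'
#' Writes the voltage traces as a wide CSV (`t_ms` plus one column per
#' recorded segment) and a JSON sidecar with per-pathway charge integrals.
#'
#' @param sim a `sim_result` from [integrate_model()].
#' @param csv_path,json_path output paths.
#' @return invisibly, the two paths.
#' @export
write_sim_result <- function(sim, csv_path, json_path) {
  df <- data.frame(t_ms = sim$t, sim$vm)
  names(df)[-1] <- paste0("seg", sim$record)
  utils::write.csv(df, csv_path, row.names = FALSE)
  charges <- as.list(colSums(sim$charge_seg))
  jsonlite::write_json(list(pathway_charge_pC = charges, dt_ms = sim$dt),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
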