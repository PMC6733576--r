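# hcnax

Biophysical modelling and analysis of HCN channels in central axons.

HCN (hyperpolarization-activated cyclic-nucleotide-gated) channels open on
membrane hyperpolarization, carry a mixed Na⁺/K⁺ current (I_h), and are
potentiated by intracellular cAMP. In cerebellar mossy-fiber axons they
depolarize the resting membrane potential, and through it control the
action-potential conduction velocity, the ability to fire at kilohertz
rates, and a substantial share of the axon's resting ATP budget. `hcnax`
is for electrophysiologists and modellers who want to work with this
system quantitatively: it pairs a compartmental cable model of the
mossy-fiber axon with the voltage-clamp, dose-response and
compound-action-potential analysis pipelines that constrain it, plus
seeded synthetic-data generators for every input class so that each
pipeline can be validated against known ground truth.

## The models

**HCN2 gating** is a single Hodgkin–Huxley activation gate,

> dm/dt = α(V)(1 − m) − β(V) m,  α = A·e^(−(V−V½)/Vα),  β = A·e^((V−V½)/Vβ),

with steady state α/(α+β) (a Boltzmann with midpoint V½ and slope
(1/Vα + 1/Vβ)⁻¹) and time constant 1/(α+β). Two fitted parameter sets are
bundled: 0 mM cAMP (A = 6.907 s⁻¹, V½ = −102.1 mV, Vα = 18.71 mV,
Vβ = 21.73 mV) and 1 mM cAMP (V½ = −87.31 mV). `fit_hh()` re-estimates all
four parameters from activation curves plus activation/deactivation time
constants by weighted Levenberg–Marquardt with Hessian-based 68%
confidence intervals.

**The axon** is a 31-section cable: a white-matter cylinder followed by 15
myelinated internodes alternating with en-passant boutons, carrying NaV,
KV, separate Na⁺/K⁺ leaks and the HCN mechanism (split into Na⁺ and K⁺
branches that reproduce the measured −23.3 mV mixed reversal, so that Na⁺
influx — and hence ATP demand at 3 Na⁺ per ATP — can be attributed to
pathways). Five variants reproduce the published comparisons: `control`,
`no_hcn` (ZD7288), `camp_1mM`, and the `vm_model`/`rm_model` pair that
isolates the depolarization and the conductance increase. Integration is
Crank–Nicolson with exact exponential gate updates (one tridiagonal solve
per 1.25 µs step, in C++), validated against an explicit RK4 reference.

## Worked example

```r
library(hcnax)

p <- hh_params("0mM_cAMP")
steady_state(-80, p)     # 0.0999  — ~10% of channels open at -80 mV
time_constant(-80, p)    # 47.1 ms — slow gating near rest

## synthetic 36-cell tail-current experiment, then the full analysis chain
set.seed(1)
rec <- recover_population_v_half(-103.3, cell_sd = 4.8, n_cells = 36)
rec$mean                 # -103.1 mV (SEM 0.7): pipeline recovers the
                         # generating activation midpoint

## the compartmental axon, with and without HCN
m  <- init_steady_state(build_model("control"))
mz <- init_steady_state(build_model("no_hcn"))
m$v[m$bouton_center[8]]  # -78.6 mV rest; blocked model rests at -86.2 mV

measure_velocity(m)$velocity    # 0.326 m/s
measure_velocity(mz)$velocity   # 0.301 m/s — blocking HCN slows
                                # conduction by ~8%

measure_input_resistance(mz)$r_in /
  measure_input_resistance(m)$r_in   # 2.04 — block doubles R_in

## energy budget
rest  <- resting_cost(m)$atp_rest_per_mm_s    # 3.6e7 ATP/mm/s
restz <- resting_cost(mz)$atp_rest_per_mm_s   # 2.0e7 — HCN makes rest
                                              # ~80% more expensive
apc <- ap_cost(m)$atp_per_ap_per_mm           # 4.4e7 ATP/mm per spike
cost_share(rest, restz, apc, c(4, 40))        # 0.084, 0.009 — the HCN
              # share of the budget falls ~9-fold from 4 Hz to 40 Hz
```

The same toolbox covers tail-current activation curves
(`extract_tail_activation()`, `fit_boltzmann()`), ramp-based reversal
potentials (`reversal_from_ramps()`), Hill dose-response fits with
endogenous-cAMP estimation (`fit_hill()`,
`estimate_endogenous_camp()`), two-electrode compound-AP delay analysis
(`peak_delay()`, `normalize_timecourse()`, `window_change()`),
high-frequency train protocols (`run_train()`,
`max_failure_free_frequency()`), and immunogold quantification arithmetic
(`particle_density()`, `channels_per_area()`).

See the methods vignette (`vignettes/hcnax-methods.Rmd`) for the model
assumptions, parameter provenance, numerical choices and known
limitations.

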