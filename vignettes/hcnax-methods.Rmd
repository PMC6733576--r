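---
title: "Models and methods: HCN-channel control of axonal conduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: HCN-channel control of axonal conduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hcnax` models the contribution of HCN2 channels to action-potential
conduction in cerebellar mossy-fiber axons and provides the analysis
pipelines that connect the biophysical model to the electrophysiological
measurements that constrain it. This vignette describes the science, the
numerical choices, and the boundaries of what the synthetic-data tests can
and cannot show.

## The HCN gating model

HCN channels open on hyperpolarization and carry a mixed Na⁺/K⁺ current
(`I_h`) that depolarizes the resting membrane. The package describes HCN2
gating with a single Hodgkin–Huxley activation gate and no inactivation:

$$\frac{dm}{dt} = \alpha(V)(1-m) - \beta(V)\,m, \qquad
\alpha = A e^{-(V-V_{1/2})/V_\alpha}, \qquad
\beta = A e^{(V-V_{1/2})/V_\beta}.$$

The steady state $m_\infty = \alpha/(\alpha+\beta)$ is a Boltzmann with
midpoint $V_{1/2}$ and composite slope $k = (1/V_\alpha + 1/V_\beta)^{-1}$;
the time constant is $1/(\alpha+\beta)$. Two fitted parameter sets are
bundled (`hh_params()`): one for 0 mM and one for 1 mM intracellular cAMP;
cAMP enters only through this discrete pair — no explicit
concentration-dependent gating scheme is modelled.

**Units of `A`.** The parameter `A` is printed in the source data as
6.907 "ms⁻¹", which would put the time constant at the midpoint near
0.07 ms — three orders of magnitude faster than the measured gating
(tens of milliseconds). The package therefore reads `A` in s⁻¹ by default
($\tau(V_{1/2}) = 1/(2A) \approx 72$ ms, consistent with the measured
activation and deactivation time constants); `rate_unit = "per_ms"` is
available for the literal reading. All quantities that depend only on
midpoints and curve shapes are unaffected by the choice.

`fit_hh()` re-estimates the four parameters by simultaneously fitting
$m_\infty$ to an activation curve and $1/(\alpha+\beta)$ to activation and
deactivation time constants, each dataset weighted by the inverse square of
its maximum so the three dimensionally different curves contribute
comparably. Minimization is Levenberg–Marquardt on a log scale for the
positive parameters, with multi-starts around data-driven initial guesses
($V_{1/2}$ from the activation half-crossing, $A$ from $1/(2\max\tau)$).
The 68% confidence half-widths are square roots of the diagonal of the
inverse Gauss–Newton Hessian of the weighted objective; we scale that
Hessian by the residual variance so the intervals keep near-nominal (≈68%)
coverage whatever the absolute noise scale — a choice verified by a
coverage test over 200 noisy replicates.

## Voltage-clamp analysis

Activation curves are extracted from tail currents: after a long
conditioning step, the current at the fixed post-step potential is
proportional to the open fraction reached during conditioning. The tail
amplitude is averaged over 0.5–2.5 ms after the step (skipping an 0.5 ms
settling window; the source protocol does not state an exact window) and
normalized to the most activated sweep. Because the analyzed sweeps are
blocker-subtracted and therefore leak-free, the default baseline is zero.
This matters for the 1 mM cAMP condition, where ~14% of channels are open
at the −70 mV holding potential: subtracting the pre-step holding current
(available as `baseline = "pre_step"`) subtracts part of the signal itself
and biases the recovered midpoint several mV hyperpolarized, which is
visible as a shrunken 0-vs-1 mM midpoint difference in the end-to-end
pipeline. The zero baseline keeps the recovered difference at the measured
~17 mV.

The reversal potential of `I_h` is estimated from three leak-subtracted
ramp I–V relationships recorded after conditioning at −80, −110 and
−140 mV: each is fitted with a line, and the mean of the three pairwise
intersection voltages is returned. Near-parallel line pairs are an error,
not a large number.

Dose-response data (midpoint shift versus cAMP concentration) are fitted
with a Hill equation, weighted by 1/SEM² when uncertainties are present.
The Hill coefficient is free by default and can be fixed to 1. The
endogenous cAMP concentration is estimated by intersecting the fit's 68%
confidence band — first-order (delta-method) propagation of the fit
covariance over a log-spaced grid (10⁻¹–10⁵ µM, 400 points) — with the
midpoint shift observed in perforated-patch recordings (4.8 ± 1.2 mV; the
source prints both 4.8 and 4.9 in different places, and the figure-legend
value used in the original estimation is adopted). Because the source does
not print the fitted maximal shift or Hill coefficient, the published
estimate (12.6 µM, CI 1.8–60.7 µM) is reproducible only in order of
magnitude, and is not used as a numeric target.

## The compartmental axon model

The mossy-fiber axon is an unbranched chain of 31 cylindrical sections: a
150 µm white-matter cylinder (1.2 µm diameter), then 15 repeats of a
myelinated internode (35 × 0.8 µm) plus an en-passant bouton (8 × 8 µm).
Membrane capacitance is 0.9 µF/cm², axial resistivity 120 Ω·cm; internodal
capacitance and conductance densities are divided by 10 (myelination). The
"specific membrane resistance was 0.9 µF/cm²" sentence in the source is
read, by its units, as the specific capacitance; membrane resistance
emerges from the leak densities. The white-matter cylinder is treated as
myelinated by default (the source is silent; a `membrane_spec()` switch
exposes the choice) and carries the axonal HCN density.

Bouton densities are NaV 2000, KV 1000, Na⁺ leak 0.0138, K⁺ leak 0.18, HCN
0.3 pS/µm² (internodes: NaV/KV zero, leaks ÷10, HCN 0.03). Reversals are
+55 (Na⁺), −97 (K⁺) and −23.3 mV (HCN; the source also prints −23.4 in a
different section — the model-definition value is used).

**Na⁺/K⁺ split of the HCN conductance.** For ATP accounting the HCN
conductance is split into Na⁺ and K⁺ branches. The split is defined by the
requirement that the conductance-weighted reversal of the two branches
equals the measured mixed reversal:
$\mathrm{ratio}_K = (e_{Na} - e_{HCN})/(e_{Na} - e_K) \approx 0.515$. The
formula as printed in the source ($e_{Na} + e_{HCN}$ in the numerator,
with $e_{HCN} = -23.3$) yields a mixed reversal of **+23.3 mV** and a
negative K⁺ conductance for the Rm-model's −85.5 mV reversal; it is
evidently a sign slip, and the package implements the self-consistent
form (which equals the printed formula if $e_{HCN}$ is entered as a
magnitude).

**Model variants** (`build_model()`): `control`; `no_hcn` (ZD7288);
`camp_1mM` (1 mM cAMP gating); `vm_model` (HCN removed, K⁺ reversal raised
to −90 mV — only the depolarization); `rm_model` (HCN reversal −85.5 mV,
density raised to 1 / 0.1 pS/µm² — only the conductance increase).

**NaV/KV kinetics.** The source cites external mechanism files without
printing equations, so the voltage-gated Na⁺ (m³h) and K⁺ (n⁴,
power-configurable) kinetics are the package's own, parameterized in
steady-state/time-constant form and calibrated against the anchors the
source does state: NaV availability ($h_\infty$) is 50% at −65 mV, a
bouton fires a single brief action potential (~115 mV amplitude, ~0.2 ms
half-duration), and the qualitative HCN physiology below emerges. All
quantities that depend on these kinetics carry deliberately broad
tolerances in the tests; only orderings and ratios are asserted.

### Numerics

The cable equation is integrated by a theta-method (Crank–Nicolson by
default, backward Euler for coarse equilibration runs): ionic currents are
ohmic at fixed gate values, gates advance by the exact exponential update
of the linear gate ODE at the pre-step voltage, and each step reduces to
one tridiagonal (Thomas) solve over the 161 default segments. Stimulus
currents are applied with exact per-step overlap so the delivered charge is
independent of the step size. Per-pathway membrane currents (NaV, KV, both
leaks, both HCN branches, stimulus) are recorded separately at the
step-midpoint voltage, which makes the scheme exactly charge-conserving:
the stimulus charge equals the capacitive plus ionic charge to solver
precision, a property the tests assert.

The default step is 1.25 µs for action-potential work: with the calibrated
fast NaV kinetics this is where halving the step changes any recorded
voltage sample by < 0.1 mV (convergence is second order; at a 12.5 µs step
the halving error is ~3 mV at the AP peak, dominated by peak-time shift).
Passive protocols use 50 µs. Equilibration runs 1 s of backward Euler at
5 ms, then finer settling, and verifies stationarity to
|dV/dt| < 10⁻⁶ mV/ms. The integrator is validated against an independent
explicit RK4 reference on a single isolated bouton (< 0.2 mV through a full
action potential) — a first-order explicit Euler reference at any feasible
step carries a phase error of several mV on the ~500 mV/ms upstroke and
cannot discriminate at that level.

Resting potentials are discretization-independent (< 0.05 mV) because leak
and HCN density ratios are uniform across regions; the default
discretization is 3 segments per bouton, 7 per internode, 11 for the
white-matter cylinder.

## In-silico protocols

*Input resistance and membrane time constant* follow the experimental
definition: a −10 pA, 300 ms step at the central bouton; `r_in` from the
steady-state deflection, `tau_m` from a mono-exponential fit to the first
150 ms. *Sag* is quantified as steady-state deflection over peak deflection
(the convention that makes a half-relaxed response ≈ 0.5; the complement is
available by flag). With the printed densities the model's sag ratio at a
−150 mV peak is ~0.7 — shallower than the measured 0.497 ± 0.030, because
the model's HCN conductance saturates at deep hyperpolarization; the tests
therefore assert a qualitative sag (present in control, absent without
HCN) rather than the measured ratio.

*Conduction velocity* is measured between boutons 5 and 12 (301 µm apart,
away from both ends) from quadratically interpolated action-potential peak
times, after a 100 µs suprathreshold pulse at the distal end of the
white-matter cylinder (emulating white-matter stimulation). *Trains* of 20
pulses at 100–1666 Hz count failures (peak ≤ −40 mV at the terminal
bouton). Train comparisons across variants use a **common** stimulus
intensity, 1.5× the control model's threshold: this emulates bath drug
application during a recording whose stimulation intensity was set once,
and it is the condition under which blocking HCN halves the maximal
failure-free frequency in the model; with per-variant re-thresholding, the
initiation-threshold contribution of the HCN depolarization is normalized
away and the ordering disappears. The measured growth of conduction delay
during 200 Hz trains after HCN block is *not* reproduced: without an
activity-dependent hyperpolarizing process (Na⁺/K⁺-pump or
Ca²⁺-activated K⁺ currents, which the printed model specification does not
include), the inter-spike residual in the model is net depolarizing, and
delays stay flat or shrink. This is a known limitation, not a tested claim.

*Velocity versus resting potential* sets the rest by solving the
steady-state current balance for the (global) K⁺ reversal in closed form —
so every point is a true steady state — then measures velocity and NaV
availability. Rest targets above about −63 mV have no stable fixed point
(the NaV window current destabilizes the rest) and are flagged as
unreachable rather than silently approximated.

## Energy accounting

Na⁺ influx is integrated per pathway (NaV, Na⁺ leak, HCN Na⁺ branch) over
the bouton/internode chain and converted to ATP with the 3 Na⁺ : 1 ATP
pump stoichiometry. "Per mm of axon" divides by the 645 µm repeat chain
(15 × 43 µm), excluding the white-matter cylinder by default (it is a
stimulation lead-in, not part of the repeating fiber structure; a switch
includes it). The action-potential cost integrates from stimulus onset to
10 ms past the terminal bouton's peak and subtracts the resting influx
over an equal window; the Na⁺ tail beyond 10 ms is negligible at these
kinetics. The HCN share of the budget at firing rate $f$ is
$(rest_{HCN} - rest_{noHCN})/(rest_{noHCN} + f\cdot AP)$, which is
strictly decreasing in $f$; in the calibrated model the resting cost with
HCN is ~1.8× the cost without, the per-AP cost varies < 20% across
variants, and the share falls about ninefold between 4 and 40 Hz. The
absolute share values depend on the NaV/KV calibration (the model's AP
cost per millimeter is of the same order as one second of resting cost)
and are asserted only as orderings.

## Synthetic data and what the tests show

Every input class has a seeded generator that embeds its ground truth in a
manifest (`gen_vclamp_dataset()`, `gen_cell_population()`,
`gen_dose_response()`, `gen_cap_recording()`, `gen_sag_trace()`). Defaults
are the study conditions: voltage-clamp sweeps carry additive Gaussian
noise at 2% of the maximal current; cell populations scatter their
midpoints with SD = SEM·√n of the published statistics (4.8 mV for both
the 0 mM condition, n = 36, SEM 0.8, and the 1 mM condition, n = 16, SEM
1.2); dose-response noise uses the 1.2 mV SEM class (per-concentration
uncertainties other than at 1 mM are unprinted); the maximal Hill shift is
anchored so the curve passes through the measured 17 mV shift at 1 mM
(s_max ≈ 17.69 mV); compound-action-potential experiments use a biphasic
difference-of-Gaussians waveform (waveform shape is irrelevant to
delay-based analyses by construction) with a programmable effect
time-course and rundown.

The generators emulate the *statistical* structure the analyses assume —
they do not emulate capacitive transients, series-resistance errors,
electrode drift, or non-stationary noise. Passing recovery tests therefore
demonstrate that the pipelines are unbiased and correctly propagate the
assumed noise, not that they are robust to every artifact of real
recordings. Note also that with the prescribed population sizes, the
sampling error of a single synthetic "experiment" is real: the recovered
0-vs-1 mM midpoint difference has a standard error near 1.5–2 mV, so
single-seed values scatter accordingly around the generating 16.7 mV.

## Reproduction problem sizes

The end-to-end reproduction (`repro_targets()`, wrapped by
`scripts/acceptance.R`) uses: closed-form midpoint solves; 36- and 16-cell
tail-current pipelines at 8 sweeps per cell; 100 seeded dose-response
replicates; and the full 161-segment model for the blocked resting
potential. The qualitative-physiology suite runs all five variants through
velocity, resistance, train and energy protocols at the default 1.25 µs
step. These sizes were chosen to keep each pipeline's Monte-Carlo error
well below the tolerance it is compared against.
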