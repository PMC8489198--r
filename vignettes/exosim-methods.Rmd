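---
title: "Modeling calcium-dependent exosomal release in neurons and astrocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling calcium-dependent exosomal release in neurons and astrocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exosim)
```

## The model

Exosomes are nano-sized extracellular vesicles whose release from neurons and
glia is calcium-dependent: depolarization opens voltage-gated calcium channels
(VGCCs), the local Ca²⁺ concentration near open channel mouths and below the
plasma membrane rises, and exocytosis of multivesicular bodies follows. This
package implements a deterministic biophysical model of that chain, in four
coupled layers:

**Neuron.** A modified Hodgkin–Huxley membrane (Na⁺, K⁺, leak, an induced
current `I_ind`) drives a four-compartment Ca²⁺ mass balance: the microdomain
around an open L-type channel (`C_L`, fed by the single-channel current
`i_CL = g_CL (v_m − V_C)/N_L`), the sub-membrane shell (`C_m`, fed by the
T-type current and by exchange with the `N_L` microdomains weighted by the
open probability `m_CL² h_CL`), the bulk cytosol (`C_c`), and the endoplasmic
reticulum (`C_r`, SERCA uptake and passive leak). Relative release rates are
Hill functions of the local concentrations:
`R_CL = m²h·H(C_L, K_L, n_L) + (1 − m²h)·H(C_m, K_L, n_L)` and
`R_Cm = H(C_m, K_m, n_m)`, with `H(x, K, n) = xⁿ/(xⁿ + Kⁿ)`.

**Astrocyte.** Electrically silent, depolarized by a control signal `v_ind`
added to the resting potential (−70 mV). IP₃ is produced at a constant rate
while the stimulus is on and relaxes to its baseline `P₀ = 0.160` µM with time
constant `τ_P ≈ 7.14` s; ER Ca²⁺ release follows the Li–Rinzel two-variable
reduction of the IP₃-receptor model (activation `m_P∞³`, slow inactivation
`h_P³`, ER free Ca²⁺ `(c0 − C_c)/c1`). L- and N-type microdomains mirror the
neuronal ones; the astrocytic release adds the N-type term
`R_CN` (weight `m_CN² h_CN`, `K_N = 2` µM, `n_N = 4`).

**Amyloid-β flux network.** A scalar burden `l` scales four astrocytic Ca²⁺
pathways — L-type VGCC current (`1 + A_VL l`), ryanodine-receptor sensitivity
(`k_d + A_RyR l`), PLC/IP₃ production (`1 + A_m l`), and membrane leak
(`+ A_in l^{n5}`) — in a cytosol/ER/IP₃ balance with CICR, SERCA,
plasma-membrane extrusion, and T/L/N/R-type VGCC influx
(`J_VGCC = −I_VGCC/(z_Ca F λ_ast)`, Ca valence `z_Ca = 2`). Astrocytic Ca²⁺
feeds back on the neuron through the depolarizing current
`I_astro = A_astro ln(1000 C_c − 196.69)`, gated to zero until its logarithm
is positive. In the coupled network the neuron's spiking membrane potential
is what gates the astrocytic VGCCs.

**Temperature and TRPM8.** Gate kinetics accelerate with temperature through
the factors `φ_mK = 4.3518·2.7^((T−20)/10)`, `φ_mNa = 4.4288·3^((T−20)/10)`,
`φ_hNa = 3.8923·2.3^((T−20)/10)` (rates scaled, steady states untouched);
peak Na⁺/K⁺ conductances follow Gaussian profiles centered at 31.83 °C and
27.88 °C. The cold-sensing TRPM8 channel has a two-state thermodynamic open
probability `a_m8 = B((T+273.15)ΔS, ΔH − zFv_m, R(T+273.15))` with
`ΔH = −156` kJ/mol, `ΔS = −550` J/(mol·K) and gating charge `z = 0.87`: it
opens on cooling and on depolarization, and carries the current
`g_m8 a_m8 (V_m8 − v_m)` toward its ~0 mV reversal in the membrane equation.

## Parameters

`default_parameters()` is the registry of every constant, each tagged with its
unit and source; `load_overrides()` applies config-file or list overrides with
name and positivity validation. Values are stored in their printed units — the
electrical and neuronal-calcium constants are per millisecond, the Li–Rinzel
and amyloid-network rates per second — and `canonical_units()` (used
internally by the engine) moves everything to the millisecond base. Parameters
that matter most in practice:

* `I_ind` pulses of 10–20 µA/cm² for 500 ms are the reference neuronal drive;
  `v_ind` steps of 10–30 mV the astrocytic one.
* `l ∈ {0, 0.4, 1}` spans the amyloid-β conditions studied; all four pathway
  weights default to 1.
* `g_m8 ∈ {3, 5, 10}` mS/cm² spans the TRPM8 conductances studied; 0 disables
  the channel.
* `K_L = 50` µM, `K_m = K_N = 2` µM with Hill exponent 4 set the release
  sensitivity of the three pathways.

Two constants required interpretation. The source table lists `a_2` twice;
unit analysis assigns 0.5 µM⁻¹s⁻¹ to the IP₃-receptor inactivation rate
(`a2_ip3r`) and 0.02 s⁻¹ to the membrane-leak slope (`a2_in`), and overriding
a bare `a2` is rejected. The plasma-membrane extrusion half-saturation `K_pm`
is never given; the package calibrates it once from the model's own printed
resting condition — flux balance `J_pm = J_VGCC + J_in` at `C_c = 0.1` µM,
`l = 0`, `v = −70` mV — giving `K_pm = 1.3329` µM. (The naive small value of
0.1 µM makes the pump operate near saturation at rest, drains the resting
cytosol to ~0.008 µM, and puts the `I_astro` activation threshold of
0.198 µM permanently out of reach, contradicting the coupled-network behavior
the model exists to produce.) Both choices are recorded in every run's
metadata as assumptions.

## Printed-form corrections (and the literal switches)

Four places in the source material, taken literally, produce a model that
cannot reproduce its own reported behavior. The package defaults to the
corrected reading and keeps the literal one behind a flag in `sim_options()`:

* **HH rate strings** (`literal_rates`): the printed shorthand substitutes a
  logistic for the linear-over-exponential α forms (which then go negative
  below −40 mV) and gives the K⁺ closing rate a decay constant of 18 mV
  instead of 80 mV; no repetitive spiking survives. The default uses the
  classic forms (resting potential −65 mV convention), whose removable
  singularities are evaluated by their limits.
* **Microdomain/ER signs** (`literal_signs`): the printed microdomain and ER
  balances are self-amplifying (the microdomain equation grows like
  `e^{f B_ud t}`, overflowing within ~300 ms); the default uses the
  mass-conserving signs, which also match the upstream compartment models.
* **Feedback gate** (`literal_heaviside`): the printed Heaviside form
  `H[1000y]·ln(y)` is negative for `0 < y < 1` and undefined for `y ≤ 0`; the
  default gates on `ln(y) > 0`, which is continuous at the threshold.
* **Thermal peak conductances** (`literal_gmax`): the printed Gaussian
  amplitudes (1.60, 0.42) used as absolute conductances abolish spiking at
  every temperature; the default normalizes the Gaussians so the
  temperature-independent conductances are recovered at each Gaussian peak.

Boltzmann midpoints printed as positive shorthand (e.g. activation at
"45 mV") are interpreted as their negatives, consistent with the explicitly
signed table entries and with physiological activation ranges; inactivation
slopes are negative. The membrane TRPM8 term uses the conductance form
`g a (V_rev − v)` so the channel drives the potential toward its reversal;
`trpm8_current()` itself returns the conventional outward-positive current.

## Numerics

Two integrators are built in and serve as mutual oracles: fixed-step classic
RK4 (default `dt = 0.01` ms, bit-reproducible) and an adaptive Cash–Karp 4(5)
with per-component error control for the slow IP₃/amyloid scenarios (minutes
of model time with millisecond-scale gate stiffness; `max_step` should stay
below ~2× the fastest gate time constant, 0.25 ms by default, because the
method is explicit). On the reference neuron scenario the two methods agree
to under 10⁻⁴ mV in sup-norm. Stimulus discontinuities are aligned to step
boundaries; pulse windows are half-open with a 10⁻⁹ ms tolerance, and the
final stage of every step samples the drive just inside the step, which keeps
the spike times invariant across `dt` refinements. Gate ODEs keep their
states in [0, 1] for any step below the local time constant; concentrations
are not clipped, and a non-finite state aborts integration with the failure
time. The model contains no randomness; `--seed` is recorded but unused.

Degenerate inputs: `hill()` rejects negative concentrations and non-positive
constants; the T-type activation bell has a printed zero baseline, floored at
10⁻³ ms to keep its ODE well-posed; logistic arguments are clamped at ±700
before exponentiation.

## Scenarios and what a green test establishes

`scenario_names()` lists eleven canonical configurations reproducing the
reference simulation experiments (neuron and astrocyte step responses, the
autonomous and driven amyloid networks, the coupled network, the thermal and
TRPM8 variants). Where the source leaves protocol details open, the registry
fixes them once: the autonomous amyloid runs use 600 s of model time with the
membrane clamped at −70 mV; the coupled runs drive the neuron with a
sustained 20 µA/cm² current for 60 s so the slow astrocytic Ca²⁺ pool can
reach the feedback threshold; the TRPM8 ramp goes 30 → 5 → 30 °C over
2 × 2000 ms (a physiological cold sweep; the source states no duration).
Spike detection is operationalized as upward 0 mV crossings with a 2 ms
refractory period, and "released exosome concentration" as the time integral
of the dimensionless release rate — both choices are logged in run metadata.

The scenarios generate all test inputs; nothing is fitted to data. A green
suite therefore establishes that the equations, units and couplings are
implemented as documented and that the qualitative directions the model is
known for (stimulus–response monotonicity, amyloid-β raising Ca²⁺ baseline,
oscillation frequency and coupled excitability, thermal spike suppression,
TRPM8 cold block at high conductance, down/up ramp asymmetry) emerge from
those equations. It does not establish quantitative agreement with any real
neuron or astrocyte, nor with figures whose producing parameter sets differ
from the printed tables.

## Known limitations

* With the printed parameter set, the sub-membrane pathway contributes ~41%
  of the cumulative release during the 20 µA/cm² reference pulse, not the
  reported three-quarters. The open L-type microdomain rests near 32 µM
  (`H(C_L, 50, 4) ≈ 0.15`), so each spike's brief overlap of high open
  probability with the still-high `C_L` dominates `R_CL`, while `C_m` peaks
  near 0.46 µM where `H(C_m, 2, 4) ≤ 0.003`. The alternative readings of the
  microdomain current (whole-cell gated, or per-channel gated) push the
  fraction to ~0.03 or ~1.0 respectively and were rejected. The corresponding
  acceptance test is left failing by design rather than re-tuned.
* The astrocyte variant keeps the printed bulk-cytosol equation, which has no
  sub-membrane→cytosol return flux; total astrocytic Ca²⁺ is therefore not
  conserved (plasma-membrane pumps dominate), matching the printed model.
* Exosome pools are non-depleting; glutamate itself, gap-junction coupling,
  astrocyte networks, stochastic channel gating and spatial gradients are out
  of scope.

## Worked example

```{r example, eval = FALSE}
res <- run_scenario("fig2_neuron_pulse", amplitude = 20)
detect_spikes(res$time, res$states[, "v_m"])$count   # 46 spikes in 500 ms
release_breakdown(res, window = c(50, 550))
# cumulative R_CL 1.3683, R_Cm 0.9569 (rate x ms); R_Cm fraction 0.4115
```
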