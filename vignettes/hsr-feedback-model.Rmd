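---
title: "Modeling feedback control of the heat shock response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling feedback control of the heat shock response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The circuit

The heat shock response (HSR) in budding yeast is driven by the
transcription factor Hsf1 and shut off by the chaperone Hsp70, which binds
and represses Hsf1 when enough of it is free to do so. `hsrkit` implements
a deterministic mass-action model of this circuit with two feedback layers:

* a **core expression feedback loop** — free Hsf1 (`Ff`) drives Hsp70
  synthesis through a Hill function, and free Hsp70 (`Hf`) represses Hsf1
  by complex formation (`HF`);
* an **auxiliary feedback acting on Hsp70 availability** — Hsp70 bound to
  unfolded client proteins (`HU`) is returned to the free pool by
  *productive release* at rate `k_rel`, the single parameter through which
  a family of HSE-deletion mutants (Fes1, Ubi4, Gre3, Pin3) is modeled.

The state is `(U, Hf, HU, HF, Ff, Y, Ym)`: free clients, free Hsp70, the
Hsp70–client and Hsp70–Hsf1 complexes, free Hsf1, and immature/mature
reporter (HSE-YFP). The equations implemented in `hsr_derivatives()` are

```
dU   = k_U0 s − k_bU Hf U + k_offU HU − γ U
dHU  = k_bU Hf U − (k_rel + k_offU + γ) HU
dHf  = β0 + β1 Hill(Ff; K_hsf, n_hsf) + (k_rel + k_offU) HU
       − k_bU Hf U − k_bF(U) Hf Ff + k_uF HF − γ Hf
dHF  = k_bF(U) Hf Ff − (k_uF + γ) HF
dFf  = −k_bF(U) Hf Ff + (k_uF + γ) HF
dY   = α_y Hill(Ff; K_y, n_y) − (m_mat + γ) Y
dYm  = m_mat Y − γ Ym
```

with the client-dependent **affinity switch**

```
k_bF(U) = k_bF0 / (1 + (U / K_sis)^h_sis)
```

representing titration of the J-domain protein Sis1 away from Hsf1 by
accumulated clients. Three structural choices deserve comment:

* **Hsf1 is conserved** (`Ff + HF = F_tot` exactly): the regulated
  quantity is Hsf1 *activity*, not abundance, so the Hsf1 moiety of a
  diluted Hsp70–Hsf1 complex returns to the free pool. Every trajectory
  satisfies the conservation law to the solver tolerance, and the test
  suite asserts it.
* **Stress enters as client influx.** A temperature- or ethanol-dependent
  drop in the spontaneous folding rate of new proteins is phenomenologically
  identical, at the level of client accumulation, to a step increase of
  unfolded-client production; we use one multiplier `s` (`s_heat`,
  `s_eth`) switched on instantaneously and inclusively at the onset time,
  matching abrupt culture transfer.
* **Productive vs non-productive release.** `k_rel` consumes the client
  (folding/clearance); `k_offU` returns it unfolded. Only the productive
  path is the auxiliary feedback lever; `k_offU = 0.1 k_rel` by default so
  simple dissociation is present but minor.

## Default calibration

Units are arbitrary (a.u.) and minutes; all reporter comparisons are fold
change over the pre-stress level, which cancels units. The defaults live
in one versioned config, `inst/extdata/default_calibration.yaml`, loaded by
`hsr_calibration()`; they were chosen once, by forward simulation, to
satisfy jointly:

1. the wild type rises several-fold under heat and settles within the
   four-hour course;
2. the strain lacking Hsf1-dependent Hsp70 induction (`HSP70_DFBL`,
   modeled as `β1 = 0` with `β0` raised to preserve the pre-stress Hsp70
   level) keeps accumulating reporter;
3. reducing `k_rel` to 20–40 % of wild type produces an elevated,
   Fes1-mutant-like plateau;
4. the endpoint reporter output is monotone non-increasing in `k_rel`
   across two decades around the default;
5. wild-type transcription adapts (instantaneous reporter transcription at
   240 min below twice basal) while the broken core loop does not.

Two tensions shaped the numbers. Monotonicity over the full `k_rel` range
requires the circuit to *still adapt* at one hundredth of the default
release rate — otherwise basal activation at tiny `k_rel` inflates the
pre-stress reporter and deflates the fold change, reversing the trend at
the low end. That bounds the Hsp70 synthesis capacity `β1/γ` from below.
Endpoint adaptation together with a multi-fold reporter response requires
the adaptation transient to be slow (on the order of 100 min), which bounds
`β1` from above. The frozen compromise (`β1 = 2.5`, `γ = 0.004`,
`n_hsf = 6`) gives a wild-type fold change that peaks near 4.4 around
80 min and relaxes to about 3 by 240 min. A perfectly flat plateau is not
attainable in this architecture: once transcription has adapted, the mature
reporter necessarily relaxes toward the adapted level at the dilution rate
`γ`. We treat the gentle decline as a model property and document it
rather than distort the dilution term.

Basal repression holds about 96 % of Hsf1 in the Hsp70-bound state
(`Ff/F_tot ≈ 0.04`), consistent with a mostly-off pathway under
non-stress conditions.

## Numerical choices

* Simulations integrate with `deSolve::lsoda` (relative tolerance 1e-8,
  absolute 1e-10) from the pre-stress steady state; the stress step is
  handled by splitting the integration at onset so the discontinuity never
  sits inside a solver step. States within −1e-9 of zero are clipped to
  zero; anything lower raises an error.
* `basal_steady_state()` relaxes the system for 6000 min and polishes the
  root with damped Newton iterations on the reduced six-dimensional system
  (the Hsp70–Hsf1 complex is eliminated through Hsf1 conservation, whose
  presence would otherwise make the Jacobian singular). The returned state
  has derivative max-norm below 1e-8 and reproduces itself over a further
  100 min of integration to relative 1e-6.
* The adaptive solution is cross-checked in the test suite against a
  brute-force fixed-step classical RK4 integration at `dt = 0.01` min;
  agreement is within relative 1e-4 on all states at all sample times
  (observed: ~5e-7).
* Nonlinear least squares (logistic and Hill fits) use
  `minpack.lm::nlsLM` with data-driven starting values and default
  convergence control. The baseline and plateau are unbounded in the
  optimizer — a lower bound of zero makes the Levenberg–Marquardt scaling
  singular when the start sits on it — and the type invariants
  (`M ≥ B ≥ 0`, `k > 0`) are enforced on the result, with violations
  reported as degenerate fits rather than errors so library-wide sweeps
  never abort. Constant or decreasing series are flagged degenerate up
  front.

## Fitting strain data

`rss()` is the unweighted residual sum of squares between observed and
simulated reporter fold changes at the observation times (a weighted
variant using the carried per-time standard deviations exists but is off
by default, since the calibration data are summarized as unweighted
means). `fit_release_scale()` minimizes it over release scales in
`[0.01, 1]` — reductions only, since the mutants modeled this way lose
release activity — with a 40-point log-spaced grid scan followed by
golden-section refinement to 1e-3; optima pinned at a search bound are
flagged `boundary` rather than silently accepted. On noiseless
self-generated data the RSS profile is unimodal and the generating scale is
recovered to three decimals; with 5 % replicate noise the median absolute
recovery error across 20 seeds is well below 0.05.

For ethanol stress, `fit_ethanol_baseline()` re-fits only the client
production multiplier (`s_eth`) and the client–Hsp70 association rate
(`k_bU`) — the two knobs describing how a chemically different stress
loads the same circuit — as multiplicative factors optimized in log space
(scale-free, positivity-preserving) by Nelder–Mead from a 3 × 3 grid of
starts. All core-loop parameters are returned bit-identical to the input.

## What the synthetic data emulate — and what they do not

The generators stand in for the study's flow-cytometry datasets; every
analysis module has a recovery test wired to its generator, and all
generators are pure functions of `(spec, seed)`.

* `gen_regulon_library()` emulates a 42-gene reporter library: basal
  levels log-uniform over 3.3 decades, induction fold changes log-uniform
  over 1.05–10×, both drawn stratified (one draw per equal log-bin,
  jittered within the central half of the bin) so the configured extremes
  are realized in every library; induction timing `t50` is coupled to fold
  change through a Gaussian copula with correlation −0.75, encoding that
  rapidly induced genes induce more. Mean traces are four-parameter
  logistics with `k·t50 ≥ 5`, keeping the pre-stress level at baseline.
  Replicates apply 5 % multiplicative lognormal noise to the mean.
* `gen_mutant_panel()` wraps model simulations with per-replicate
  multiplicative noise, re-referencing each replicate to its own time-zero
  value as the cytometry workflow does.
* `gen_ethanol_panel()` draws 4-hour reporter responses from an increasing
  Hill curve (true EC50 6.9 % v/v) and relative growth from a decreasing
  Hill curve (true IC50 6.6 %), both stored in the calibration config, with
  per-concentration time courses that are sigmoidal in time at and above
  6 % ethanol and a shallow drift below.
* `gen_flow_sample()` produces per-event side scatter and fluorescence
  with lognormal cell-to-cell variability (standard for cytometry
  intensities and strictly positive) plus a configurable dead-cell
  subpopulation with attenuated scatter and more strongly attenuated
  fluorescence — exactly the artifact that dividing by side scatter and
  taking the median is meant to reject.
* `gen_growth_curves()` produces two-phase logistic OD600 curves (30 °C
  for 4 h, then a shifted phase whose rate carries each strain's deficit),
  sampled every 20 min over 24 h with two replicates.

What passing tests on these data do **not** show: the generators contain
no mRNA-stability differences between reporters, no cell-cycle or
cell-size structure, no autofluorescence background, no instrument drift,
and no growth-dependent dilution coupling between the reporter and the
stress response. Conclusions about estimator correctness transfer to real
data only to the extent that these omissions are second-order for the
summary statistics used (medians of ratios, fold changes, fitted curve
parameters).

## Regulon dynamics analysis

The induction-curve family is the four-parameter logistic
`B + (M−B)/(1+exp(−k(t−t50)))`, chosen because the two statistics the
analysis extracts are closed-form in it: the time to half-maximal
induction is `t50` and the maximal induction rate is `k(M−B)/4`. PCA on
the genes-by-times matrix is column-centered but **not** variance-scaled:
on raw levels this deliberately lets expression magnitude dominate PC1
(which is the observation being reproduced — PC1 tracks basal level and
carries ≥95 % of the variance); induction dynamics are studied on the
fold-change-normalized matrix instead. Component signs are fixed by making
each loading's largest-magnitude entry positive, so results are
reproducible across BLAS implementations. The timing–rate tradeoff is
summarized by OLS of `log10(max rate)` on `log10(t50)` with a
1000-resample bootstrap band; degenerate (non-induced) genes are excluded
from fits but retained in matrices.

## Dose–response and growth

Hill fits initialize the coefficient at 4 (bounded to [0.5, 20]; the
shape is not otherwise constrained) and mirror the curve for decreasing
(growth-inhibition) readouts, so EC50 and IC50 are the same `C50` field.
Per-concentration reporter time courses switch family at 6 % ethanol:
sigmoid at and above, quadratic polynomial at and below 5 %, where the
response never leaves baseline and a sigmoid is unidentifiable. The IC50
readout is based on the maximal post-shift growth rate relative to the
no-ethanol condition — the growth-rate basis matches the quantitative
growth assay, where the log-phase rate is the maximum derivative of the
OD600 curve after 3-point moving-average smoothing, searched only after
the temperature-shift time (default 240 min).

## Problem sizes

Defaults throughout are the study-scale sizes: 42 genes × 10 time points
× 3 replicates for the regulon; 10 ethanol concentrations × 3 replicates;
10⁴ events per flow sample; 73 OD600 points × 2 replicates per growth
curve; release-scale recovery is assessed over 20 seeds. The full test
suite, including all property checks, runs in minutes on one CPU.

## Known limitations

* The model has no spatial compartments; "nuclear-available Hsp70" is the
  free pool `Hf`. No stochastic simulation is provided.
* The early-time hyperactivation seen in one mutant class (the Hsp42-like
  signature) is deliberately not modeled; the package instead demonstrates
  that release-rate reduction *cannot* fit such data (the fit's RSS
  degrades by more than an order of magnitude), which is the diagnostically
  useful property.
* Equation-level identity with earlier published variants of the circuit
  is not claimed; the architecture (core loop, affinity switch, productive
  release) is what the implementation fixes.
* Fold-change plateaus decline slowly at rate `γ` after adaptation (see
  above); endpoint comparisons between strains are unaffected because all
  strains share `γ`.
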