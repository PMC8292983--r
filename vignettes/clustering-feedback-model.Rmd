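---
title: "A two-compartment model of clustering-gated kinase feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-compartment model of clustering-gated kinase feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterfb)
```

## The model

The package implements a minimal kinetic model of how clustering of the
membrane scaffold LAT gates a positive feedback loop among three
species: LAT, the Syk-family kinase Zap70 that phosphorylates it, and an
Src-family kinase (Src) that phosphorylates and activates Zap70. The
cell is reduced to two well-mixed compartments — cytosol and a
membrane/cluster compartment — with Src and Zap70 held at constant
cytosolic concentrations and free to diffuse into the membrane
compartment.

Cluster formation is volume exclusion, not new chemistry: the membrane
compartment shrinks by a partition coefficient $K \ge 1$, so every
membrane species is concentrated $K$-fold,

$$[\mathrm{LAT}] = K\,[\mathrm{LAT}]_0 .$$

Two equilibrium binding steps sit on top of this (binding and diffusion
are assumed fast relative to phosphorylation):

* Zap70 binds LAT through a light-switchable heterodimerization pair
  (association constant $K_A^{\mathrm{iLID}}$, 100-fold tighter in the
  light). The fraction of LAT carrying a Zap70 is
  $f = [\mathrm{Zap70}]_0 K_A / (1 + [\mathrm{Zap70}]_0 K_A)$, the
  bound Zap70 pool is $f\,[\mathrm{LAT}]$, and free Zap70 at
  $[\mathrm{Zap70}]_0$ also diffuses in, so total membrane Zap70 is
  $f\,[\mathrm{LAT}] + [\mathrm{Zap70}]_0$. The same $f$ splits LAT
  into bound and free sub-pools.
* Src binds phosphorylated LAT through its SH2 domain, which releases
  autoinhibition: active Src is
  $[\mathrm{pLAT}]\,[\mathrm{Src}]_0 K_A^{\mathrm{SH2}} /
  (1 + [\mathrm{Src}]_0 K_A^{\mathrm{SH2}})$, while autoinhibited Src
  diffuses in at $[\mathrm{Src}]_0$. The pLAT concentration here is the
  total phosphorylated pool (free plus bound).

Four phospho-pools evolve by mass-action/Michaelis-Menten kinetics:
membrane pZap70 (phosphorylated by active Src, fast, and by
autoinhibited Src, slow and leaky), cytosolic pZap70 (inactive Src
only), and free and bound pLAT (Michaelis-Menten phosphorylation by
membrane pZap70; bound LAT is additionally phosphorylated first-order
at rate $k_{\mathrm{teth}}$ through the tethered complex pool
$[\mathrm{LAT}]_{n,\mathrm{bound}}\,[\mathrm{pZap70}]/[\mathrm{Zap70}]$).
All pools dephosphorylate first-order. The inhibitor PP2 is
non-competitive and scales both Src catalytic constants by
$K_I/(K_I + [\mathrm{PP2}])$.

The feedback loop — pLAT recruits and activates Src, active Src makes
more pZap70, pZap70 makes more pLAT — is what makes the system a
switch. Clustering feeds the loop twice: it concentrates the substrate
pools and it concentrates pLAT, which multiplies active Src. At the
default calibration the dark state sits on the low branch (about 0.4%
pLAT) and illumination with $K = 10$ ignites the loop.

## Default parameters and calibration

Concentrations are µM, time is seconds. Defaults
(`model_parameters()`):

| parameter | value | rationale |
|---|---|---|
| `lat_total` | 0.5 | sub-µM scaffold on an unclustered membrane |
| `zap70_cyt` | 1 | cytosolic kinase excess over scaffold |
| `src_cyt` | 0.2 | mid-range of the robustness window |
| `ka_ilid_dark` / `ka_ilid_light` | 0.1 / 10 | lit $K_D$ 0.1 µM, dark 100-fold weaker |
| `ka_sh2` | 1 | SH2-phosphotyrosine $K_D$ of order 1 µM |
| `kcat_src_active`, `km_src_active` | 3.56, 30 | see calibration note below |
| `kcat_src_inactive`, `km_src_inactive` | 5e-4, 0.1 | weak, saturating basal leak |
| `kdeph_zap70`, `kdeph_lat` | 0.1 | ~10 s dephosphorylation timescales |
| `kcat_pzap70`, `km_pzap70` | 12, 50 | near-linear LAT phosphorylation |
| `k_tethered` | 0.6 | preferential intra-complex phosphorylation |
| `ki_pp2` | 1 | µM-range inhibition constant |
| `partition_k_light` | 10 | 10-fold lit-state LAT concentration |

The set was calibrated once, before any tests were written against it,
to satisfy four structural constraints simultaneously: (i) the dark
state carries a small but nonzero pZap70 pool (leaky basal Src
activity) and does not ignite for any Src concentration; (ii) lit
clustering at $K = 10$ ignites the loop while lit recruitment alone
($K = 1$) does not; (iii) the lit/dark contrast stays above 10-fold
across at least two decades of `src_cyt`; and (iv) the $K$-scan of the
lit steady pLAT fraction reaches 90% of its $K = 100$ asymptote at
$K = 10$, matching the observation that signaling plateaus once LAT is
concentrated about 10-fold. `kcat_src_active` is the fine-tuning knob
for (iv) — hence its unrounded value. A loop-gain analysis guided the
choices: at a low-phospho state the product of the pLAT-to-active-Src,
Src-to-pZap70 and pZap70-to-pLAT small-signal gains must cross 1
between the unclustered and clustered lit states, which is what makes
the response a clustering sensor rather than a recruitment sensor.

## Scenarios

`apply_scenario()` encodes the experimental regimes as deterministic
parameter/equation modifications (see its help page for the list). Two
conventions are worth stating:

* **Zap70-K362E.** Both phospho-forms of the mutant phosphorylate LAT,
  with `kcat_pzap70` scaled by 0.1 and `km_pzap70` by 10 (configurable).
  The statement covers the catalytic mechanism but not the tethered
  channel, so the same kcat factor is applied to `k_tethered` and the
  tethered complex pool is taken to cover *all* bound LAT:Zap70
  complexes (the complex fraction is 1 rather than
  $[\mathrm{pZap70}]/[\mathrm{Zap70}]$), since the mutant's activity no
  longer depends on its phosphorylation state. The scenario runs in the
  unclustered ($K = 1$) regime, mirroring the corresponding experiment.
* **No-recruitment (Jurkat) scenario.** Both iLID association
  constants are zero while clustering still occurs on illumination.
  The basal pZap70 seed (`basal_pzap70_frac`, default 1%) is applied to
  the dark initial condition *and* as a floor at the light switch: the
  claim under test is that a pZap70 pool present when clustering begins
  can initiate feedback, and a seed applied only before dark
  equilibration decays away whenever the leaky inactive-Src pathway is
  disabled. With the default leak the floor is inactive (the dark
  steady state already exceeds it).

The mutant scaling factors (0.1/10 for K362E, 10/0.1 for the SH2/SH3
deletion) are conventions, not measurements; they are configurable
through `scenario_config()`.

## Numerics

* **Integration.** `deSolve::ode` with `lsoda`, `rtol = 1e-8`,
  `atol = 1e-10`. The positive feedback makes the system moderately
  stiff near ignition, so a stiff-capable adaptive method is used even
  though the dynamics are non-stiff elsewhere. Tolerances are recorded
  in timecourse attributes and the CSV sidecar.
* **Steady states.** Operational criterion
  $\lVert \dot{x} \rVert_\infty < 10^{-9}$ µM/s after integrating at
  least ten times the slowest dephosphorylation timescale, continued in
  chunks until satisfied, then polished by damped Newton iterations
  with a forward-difference Jacobian (accepted only when the residual
  decreases and the iterate stays inside the physical box).
* **The light switch.** Phospho-*fractions* are conserved across the
  instantaneous change of $K$ and $f$: membrane pZap70 keeps its
  phosphorylated fraction of the new total, total pLAT keeps its
  fraction of total LAT, and LAT phospho/non-phospho material is
  redistributed proportionally between the bound and free sub-pools by
  the new $f$. This is the consistent limit of the fast-equilibrium
  assumption.
* **Bistability.** `hysteresis_probe()` reports the steady states
  reached from the all-zero and fully-phosphorylated corners
  separately and flags disagreement; nothing is averaged. Scans and
  titrations always follow the physical protocol (dark equilibration,
  then light), so they report the branch an experiment would see.
* **Dose-response fitting.** PP2 enters the equations only through
  $[\mathrm{PP2}]/K_I$, so the lit steady response is a
  one-dimensional profile $g(x)$; `fit_dose_response()` screens a
  deterministic multi-start (every observed dose as a $K_I$ candidate)
  against a precomputed monotone-spline profile and polishes the best
  candidate by Levenberg-Marquardt, by default against exact
  steady-state evaluations. Noiseless data are recovered to machine-level
  accuracy because data and model share the same steady-state pipeline.
* **Degenerate inputs.** States outside the physical pool box are
  rejected by `model_rhs()`; non-positive nuclear signals in
  `cn_ratio()` become flagged `NA`s; a non-positive minimum in
  `normalize_gcamp()` is an error naming the cell; an empty field of
  view is an error.

## Quantification conventions

* **AUC** is the baselined *plain sum*
  $\sum_t (v_t - v_0)$ — deliberately not a trapezoidal integral —
  over the full sampling grid (61 points at 15 s for the fibroblast
  protocol). A 61-point trace sitting one unit above baseline from the
  second point on has AUC exactly 60.
* **Sustained-response classification** operates on min-normalized
  traces: the peak must exceed a noise threshold and a consecutive run
  of samples at or above half the peak must span at least 30 s
  ($\ge 7$ samples at 5 s; spans are $(n-1)\,dt$). Cumulative
  non-consecutive time is not counted, so isolated blinks never
  qualify. The run level is floored at the noise threshold: without the
  floor, any trace whose peak is below twice its baseline would count
  its entire baseline toward the run, and a single low spike would be
  called sustained. The default threshold is a fixed 1.5-fold change
  over the per-trace minimum — on min-normalized flat noise traces
  (multiplicative, ~5%), the max/min ratio concentrates around 1.2,
  well below 1.5, while genuine calcium responses are several-fold. An
  adaptive alternative (1 + 3 MAD of the pre-stimulus samples,
  `noise_threshold = NULL`) is available but has poor specificity with
  only three pre-stimulus samples, which is why it is not the default.
* **Membrane clustering metric**: per-frame coefficient of variation
  of masked pixel intensities, reported as $CV_t - CV_0$. CV is
  dimensionless and invariant to the overall brightening that
  illumination causes, which is why it is preferred over the plain
  variance (available as an option).

## What the synthetic data emulate — and what they do not

The generators produce the statistical structure the quantification
assumes: GCaMP-like traces (3 min at 5 s) with sigmoidal sustained
responders, single-sample "blinkers" and flat non-responders under
multiplicative log-normal noise; KTR-like cytoplasm/nucleus channel
pairs (15 min at 15 s, ratio rising from 1 toward a plateau of ~3 with
a known analytic AUC); membrane images where a conserved total
intensity is redistributed into Gaussian puncta; and noisy steady-state
model readouts for parameter-recovery studies. Shape parameters (rise
times of tens of seconds for calcium, minutes for the reporter
plateau, 2–4-fold amplitudes) are synthetic conventions chosen to be
realistic for these biosensors, not measurements.

They do not emulate photobleaching, cell movement or segmentation
error, spatially correlated noise, the optics of punctum formation, or
cell-to-cell kinetic heterogeneity beyond the sampled amplitude and
timing ranges. Passing the classifier-validation test therefore shows
the decision rule is correct and well-margined under the assumed noise
model, not that it is robust to all real imaging artifacts.

## Problem sizes used by the test suite

The suite validates the right-hand side against an independently
transcribed oracle on 100 random parameter/state draws (1e-12
relative), adaptive integration against a fixed-step RK4 reference at
$dt = 10^{-3}$ s on 20 draws (1e-6 relative), box invariance on 40
integrated trajectories, classifier performance on a 1000-trace
labeled fixture, and $K_I$ recovery on 200 noisy replicates of an
8-dose titration (at least 90% within 20%). Scans use 4–8 points per
decade with bisection refinement of threshold crossings, so reported
crossings are grid-independent.

## Known limitations

* The membrane and cytosolic pZap70 pools do not exchange mass, even
  though Zap70 binding is at equilibrium — the literal form of the
  compartment equations. Whether dissociating phospho-Zap70 should
  carry its phospho-state into the cytosol is left open; the model is
  implemented as written and the question is flagged here rather than
  resolved.
* Free-diffusing (non-tethered) Zap70 inside the cluster shares the
  single membrane phospho-fraction variable; it has no separate state.
* One phosphorylatable tyrosine on LAT; no explicit phosphatases, no
  spatial or stochastic cluster nucleation, no upstream receptor
  module, and only a single dark-to-light step (no pulsed inputs).
* The readout "amplitude" in dose-response fitting is a single
  multiplicative scale between the model's pLAT fraction and
  blot-ratio units; nothing more structured is attempted.
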