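# clusterfb

Why does T-cell-like signaling fire when the scaffold protein LAT is
*clustered* with the kinase Zap70, but not when the two are merely
dimerized? `clusterfb` implements a compact kinetic answer: a
two-compartment model in which cluster formation shrinks the membrane
compartment by a partition coefficient *K*, concentrating LAT, its
kinase and the Src-family feedback kinase together, and thereby
igniting a bistable positive feedback loop (pLAT → active Src → pZap70
→ pLAT). The package is for modelers and quantitative cell biologists
who want to simulate the switch, scan its parameters, fit inhibitor
dose-response data, and quantify the associated live-cell biosensor
readouts.

## The model in brief

Membrane LAT concentration: `[LAT] = K·[LAT]₀`. Zap70 reaches the
membrane bound to LAT (fraction `f = [Zap70]₀·KA/(1+[Zap70]₀·KA)`,
light tightens KA 100-fold) and by free diffusion; Src is activated in
proportion to phosphorylated LAT through an SH2–pY interaction,
`[Src]ₐ = [pLAT]·[Src]₀·KA/(1+[Src]₀·KA)`. Four phospho-pools
(membrane and cytosolic pZap70, free and bound pLAT) follow
Michaelis–Menten phosphorylation with first-order dephosphorylation,
plus a first-order intra-complex channel for LAT tethered to pZap70.
PP2 scales both Src catalytic constants by `K_I/(K_I+[PP2])`
(non-competitive). Seven experimental scenarios (base "iLID-Drop",
recruitment-only, two Zap70 mutants, non-phosphorylatable LAT,
feedback-disconnected Src, and clustering-without-recruitment) are
deterministic parameter transforms. See the vignette
(`vignettes/clustering-feedback-model.Rmd`) for the equations,
calibration rationale and numerical choices.

## Worked example

```r
library(clusterfb)
res <- run_six_scenarios(model_parameters())
res[, c("scenario", "dark_plat_frac", "lit_plat_frac", "lit_dark_ratio")]
#>       scenario dark_plat_frac lit_plat_frac lit_dark_ratio
#> 1    ilid_drop        0.00370       0.89138         240.78
#> 2    ilid_only        0.00370       0.02965           8.01
#> 3  zap70_k362e        0.05720       0.35610           6.23
#> 4     zap70_kd        0.00000       0.00000           0.00
#> 5      lat_fff        0.00000       0.00000           0.00
#> 6 src_dsh2dsh3        0.00264       0.00313           1.19
```

Each row is one simulated experiment: dark steady state, then 20 min of
light. Clustering plus recruitment (`ilid_drop`) drives phosphorylation
of ~89% of LAT — a 240-fold induction — while recruitment alone
(`ilid_only`), kinase-dead Zap70 and non-phosphorylatable LAT stay
near zero, the weakly active K362E mutant reaches an intermediate
level, and feedback-disconnected Src barely notices the light
(ratio 1.19).

The robustness statistic behind the Src scan:

```r
w <- src_contrast_range(model_parameters())
c(w$lo, w$hi, w$decades)
#> 0.0101 1.2970 2.11
```

i.e. the 10-fold light/dark contrast survives across 2.1 decades of
cellular Src concentration. Other entry points: `scan_parameter()`
(K- and Src-scans), `pp2_titration()` / `fit_dose_response()`
(inhibitor dose-response and K_I estimation), `quantify_traces()`
(biosensor C/N ratios, baselined-sum AUCs, sustained-response calls,
per-field responder fractions), `membrane_cv_timeseries()` (clustering
metric on masked image stacks), and the seeded `gen_*` generators for
synthetic traces, images and readouts.

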