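---
title: "Methods: the delayed NRF2-AMPK feedback model and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the delayed NRF2-AMPK feedback model and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrf2ampk)
```

## The scientific setting

Acute oxidative stress activates AMPK (Thr172 phosphorylation) within an
hour, and AMPK switches on autophagy through ULK1-Ser555. If the stress
persists, the antioxidant master regulator NRF2 (SKN-1 in *C. elegans*)
accumulates, binds ARE sites in the *AMPK*/*aak-2* locus and represses its
transcription. Because this repression must propagate through mRNA decay,
protein turnover and dephosphorylation before it reaches autophagosome
formation, the loop behaves as a *delayed negative feedback*: autophagy
rises several-fold, peaks after one to two hours, and returns to near-basal
levels by four hours. When NRF2 is silenced the loop is broken and
autophagy stays high — which, in worms under sustained peroxide stress, is
harmful: autophagy-deficient mutants paralyse far less than wild type.

This package reconstructs that network as a deterministic ODE model. The
source study reports network topology and phenotypic readouts, not
equations; everything below is therefore an explicit reconstruction, and
each structural choice is justified here.

## Model structure

The eight states are AMPK mRNA (`mA`), total AMPK protein (`A`), active
phospho-AMPK (`Ap`, a sub-pool of `A`), NRF2 mRNA (`mN`), active NRF2
(`N`), ULK1-S555-P (`U`, bounded by the pool size `U_T`), autophagosome
abundance (`L`, the LC3-II / GFP::LGG-1 proxy) and p62 (`P`). Units are
arbitrary, normalised so the wild-type stress-free steady state has
`mA = A = L = 1`; time is in hours. The stress input is a step of
amplitude `dose` held from `t = 0` (sustained TBHP exposure); `dose = 1`
is each system's reference exposure (100 uM TBHP for the cell line, 1 mM
plates for worms).

Three transforms of the raw dose appear on the right-hand side:

* `s_sat = s / (1 + s / K_s)` — saturation of NRF2 induction at high dose;
* `s_cl = s / (1 + s / K_c)` — saturation of stress-enhanced autophagosome
  clearance;
* `s_amp = s / (1 + (a_S * N)^h_S)` — the stress signal *as sensed by the
  AMPK axis*, quenched as NRF2's antioxidant program (the NQO1/HO-1 arm
  measured in the study) neutralises the oxidant load.

The full system is printed in the README. Structural decisions:

* **No explicit delay term.** The delay is emergent from the
  transcription-translation-activation cascade (mRNA and protein stages
  with finite turnover). AMPK's long protein half-life is what separates
  the mRNA decline (41% at 4 h) from the much later protein decline.
* **Repression acts on AMPK transcription only**, as a decreasing Hill
  function `1/(1 + (N/K_N)^h)` — the study localises the negative effect
  to the transcriptional level.
* **A second NRF2 arm (`s_amp`) is mathematically required.** With `Ap`
  driven by `s (A - Ap)` under a sustained step, `Ap` tracks `A`. The
  human-cell observations force `A(4 h)` to stay well above basal (the
  protein peak is 4–9x while mRNA is still 41% of control at 4 h), so no
  parameterisation of the transcriptional loop alone can return ULK1
  activity — and with it `L` — to near-basal by 4 h. Letting NRF2's
  antioxidant output quench the *signal* that drives AMPK phosphorylation
  (and its stress-boosted synthesis) is the biologically natural
  resolution: phospho-AMPK collapses at 3–4 h even though total AMPK is
  still elevated, exactly the observed pattern. Setting `a_S = 0` (and
  `K_N = Inf`) recovers a feedback-free model, which is how the
  "transience requires feedback" property is tested.
* **Basal activities `s0` and `u0`.** The printed system with zero basal
  AMPK tone would have `Ap = U = L = 0` at rest, making every relative
  autophagy readout undefined and the worm's stress-induced *decrease* of
  autophagy impossible. `s0` (basal AMPK-activating tone, worm) and `u0`
  (AMPK-independent basal ULK1 drive, both systems) give the resting state
  a finite autophagic flux. With `s0 = u0 = a_S = e_L = 0` and
  `K_s = K_c = Inf` the model reduces exactly to the bare reconstruction.
* **Worm vs human.** The two systems share equations but have independent
  parameter sets. In the cell line, stress *activates* autophagy
  transiently (peak 5x); in the worm, 3 h of 1 mM TBHP *reduces* the
  GFP::LGG-1 signal by 80% (40% without AAK-2, 33% without SKN-1). The
  worm set therefore routes most basal ULK1 drive through basal
  phospho-AMPK (`s0`-driven), which stress removes via SKN-1's repression
  of *aak-2*, plus a SKN-1-independent clearance arm (`e_L`) that accounts
  for the reduction still seen in *aak-2* and *skn-1* loss-of-function
  animals.
* **Steep worm repression (`h = 8`).** SKN-1 binds three clustered sites
  in the *aak-2* locus, and the phenotypes demand a switch-like response:
  a 20-fold knockdown of SKN-1 must essentially abolish repression while a
  3-fold gain-of-function must nearly saturate it. A high effective Hill
  coefficient (multi-site occupancy) is the simplest encoding. The human
  set uses `h = 2` (NRF2 binds as a dimer).
* **mTOR is not an explicit state**; its inhibition by AMPK is absorbed
  into the effective ULK1 activation rate `k_U`.

## Parameters that matter

All rates are per hour; factors are dimensionless. The shipped sets are in
`default_parameters()`; the most consequential entries:

| parameter | meaning | human | worm |
|---|---|---|---|
| `d_mA` | AMPK mRNA decay; sets the mRNA-decline timescale | 0.24 | 1.1 |
| `e_A` | stress boost of AMPK synthesis; sets the protein peak | 8 | 0.038 |
| `k_p`, `k_dp` | Thr172 (de)phosphorylation | 8, 6 | 5, 1 |
| `s0` | basal AMPK tone | 0 | 1 |
| `a_S`, `h_S` | NRF2-dependent signal quenching | 0.12, 6 | 0 (unused), 1 |
| `K_N`, `h` | repression threshold/steepness | 0.40, 2 | 3.67, 8 |
| `u0` | AMPK-independent basal ULK1 drive | 0.54 | 0.02 |
| `e_L`, `K_c` | stress-enhanced clearance | 0 (unused) | 1.11, 1.5 |

Perturbations are multiplicative: NRF2/SKN-1 silencing scales `k_mN` by a
knockdown factor (default 0.05), `skn1_GOF` scales it by 3, `aak2_null`
sets `k_A = 0`, `atg11_null` sets `k_L = 0`; conditions compose.

## Calibration

`builtin_constraints()` encodes the published fold-changes as targets:
six human-cell rows (41% mRNA, 194% mRNA, 5-fold peak, return to <= 1.5x,
protein peak in [4, 9] as two inequalities, 7-fold basal ratio) and three
worm rows (relative GFP::LGG-1 at 3 h: 0.20, 0.60, 0.67). `feedback_fit()`
minimises the weighted sum of squared *relative* residuals (all targets are
fold-changes) by Levenberg-Marquardt in log-parameter space (positivity,
scale-spanning; default box 1e-3 to 1e3), with seeded multistart (default
seed 20181002). Inequalities contribute only their violation. The free
subset is deliberately small and near-diagonal in its effect on the
equality targets — human: `d_mA`, `c_N`, `u0`, `K_N`; worm: `e_L`, `d_A`,
`e_A` — which makes the fit fast, reproducible, and identifiable: these are
also the subsets `recovery_experiment()` recovers (exactly from noiseless
targets; median absolute relative error well under 0.25 at 10% lognormal
target noise over 20 replicates). The remaining parameters were fixed
once, by the structural reasoning above, and shipped after a release-gate
fit verified every constraint within its 10% tolerance; refitting from the
shipped optimum cannot worsen the objective, so the acceptance pipeline's
from-scratch fits converge in seconds.

The initial condition of every simulation is the condition-specific
stress-free steady state. At `s = 0` the system collapses to a
one-dimensional monotone fixed-point equation in basal AMPK mRNA (every
other basal level is an explicit function of it); `steady_state()` solves
it with `uniroot` at tolerance 1e-14 rather than by long integration —
exact, fast, and verified against `model_rhs` in the tests.

## The paralysis hazard

`paralysis_curve()` turns a trajectory into an expected paralysed fraction
via an instantaneous hazard affine in autophagosome abundance,
`h(t) = (h0 + gamma L(t)) 1{dose > 0}`, integrated by trapezoid;
`F(t) = 1 - exp(-cumulative hazard)`. The hazard parameters are *shared
across genotypes* — genotype effects enter only through `L(t)` — so the
published susceptibility ordering (SKN-1-depleted > wild type > protected
mutants) is a prediction of model structure, not per-genotype fitting.
`fit_phenotype()` jointly fits `h0`, `gamma` and one effective dose
multiplier for the 10 mM paralysis assay (relative to the 1 mM puncta
reference dose) to the seven printed 7-h fractions.

Two rows are held out (weight 0): the combined-RNAi genotypes
(*aak-2*;*skn-1* RNAi, 23%; *skn-1* GOF + RNAi, 30%). The study itself
attributes these outcomes to incomplete RNAi silencing in neurons, a
cell-autonomy effect that a multiplicative whole-animal knockdown cannot
represent; with material weight, the GOF+RNAi row (for which the model, by
construction, predicts RNAi-like hyperactive autophagy) distorts the shared
hazard away from every other genotype. They are reported as predictions in
the fit table. The gain-of-function row keeps the reduced weight 0.5 (the
source text qualifies that measurement).

Two structural limits are worth stating plainly. First, the
autophagy-deficient *atg-11* mutant has `L = 0`, so its fraction
`1 - exp(-7 h0)` is the model's floor, and any genotype with residual
autophagy (e.g. *aak-2*, printed *below* *atg-11*) must sit above it: the
printed 11% < 16% ordering is unreachable under a shared affine hazard with
`gamma >= 0`, and the least-squares compromise places both near 9–13%,
within +-0.08 of their targets. Second, the fitted effective paralysis dose
saturates (the exposure profile is dose-insensitive above roughly ten times
the reference), so the multiplier rests at the upper end of its allowed
range; the fit is insensitive to it there.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure* of the study's
measurements, not the biology of real blots or images:

* `gen_densitometry()` — band intensities at 0, 0.5, 1, 2, 3, 4 h, three
  replicates, with median-unbiased multiplicative lognormal noise
  (`value = mu * exp(N(0, sd))`; default sd 0.2, a choice — the study
  prints no usable variance estimates). NQO1 and HO-1 are reported as
  proxies of the `N` state. Positivity and ratio-scaling motivate the
  lognormal.
* `gen_puncta_cohort()` — per-worm GFP::LGG-1 area fractions as a Beta
  distribution with given mean and concentration (cohort sizes default to
  the study's 15–100 range).
* `gen_paralysis_cohort()` — hourly-observed paralysis times drawn from
  the discrete distribution a hazard curve implies, with right-censoring
  at the assay end.
* `gen_planted_sequences()` — uniform-ACGT backgrounds with concrete
  degenerate-motif instances planted at anchor-relative offsets; the
  `exclusive` flag re-draws backgrounds with accidental extra hits.

All generators are pure functions of their arguments and a seed. What
passing tests on these data do **not** show: robustness to correlated
replicate noise, blot saturation, image segmentation error, or
non-uniform genomic background composition.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable), `rtol = 1e-8`,
  `atol = 1e-10`; output grids of 0.01 h for calibration and 0.02 h for
  hazard fitting. Halving tolerances moves readouts by < 1e-4 relative
  (tested). Nonnegativity is checked post hoc at tolerance 1e-6, never
  clipped.
* Decoupled linear subsystems match their closed-form exponentials to
  1e-6 (tested), and relative readouts interpolate linearly between grid
  points.
* Motif scanning is 0-based half-open internally, 1-based inclusive in
  written reports. A sequence `N` matches only pattern code `N`
  (conservative for masked regions). Overlapping and nested hits are all
  reported; a palindromic site yields one hit per strand; hits sort by
  start, then + before -. Conservation grouping is single-linkage on
  anchor-relative offsets with gap threshold `window_bp`.
* Anchor kind (ATG vs TSS) is caller-supplied metadata: published site
  positions are quoted both relative to a transcription start site and to
  the ATG, and the two are never asserted equivalent.
* Statistics: pooled-variance Student's t (as named in the study; Welch
  behind a flag), two-sided throughout, Bonferroni as `min(1, m p)`;
  ANOVA/Tukey via `stats::aov`/`TukeyHSD` (Tukey-Kramer for unbalanced
  designs); zero within-group variance with unequal means is flagged and
  reported as `F = Inf, p = 0`.
* Test problem sizes: 300–1000 random sequences for the scanner oracle,
  25 random parameter sets for boundedness, 20 replicates for noisy
  recovery, 10,000 null simulations for type-I calibration.

## Known limitations

* The model is a reconstruction from topology plus printed readouts; the
  shipped parameters are one consistent calibration, not an inference with
  uncertainty (no posterior, no profile likelihoods —
  `recovery_experiment()` is the lightweight identifiability check).
* The worm calibration implies much lower basal autophagosome abundance in
  *aak-2* mutants than wild type, whereas the study reports no significant
  basal difference; the joint puncta-plus-paralysis pattern forces this
  compromise under the shared-hazard assumption.
* Dose non-monotonicity of NRF2 mRNA at high TBHP (a slight decrease at
  300 uM) is out of scope; only the reference-dose regime is modelled.
* `Ap <= A` is treated as a sub-pool identity even though the study
  normalises phospho-AMPK to GAPDH rather than total AMPK.
* Spatial compartments, explicit KEAP1, stochastic kinetics and
  bifurcation analysis are out of scope.
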