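---
title: "Isobolographic analysis of ototoxic drug interactions: methods"
author: "otoisobol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isobolographic analysis of ototoxic drug interactions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otoisobol)
```

## The problem

Aminoglycoside antibiotics (amikacin, AMI) and loop diuretics (furosemide,
FUR) are both ototoxic, and they are often co-administered. In the mouse
model this package targets, ototoxicity is quantified by auditory brainstem
response (ABR) thresholds: the lowest click level (dB SPL) that evokes a
detectable wave-V response, measured in each animal before and after drug
treatment. The analysis asks two questions:

1. *Dose–response*: what dose of each drug — alone, or on top of a constant
   dose of the other — decreases hearing by 20% or 50% (the
   hearing-threshold-decreasing doses HTDD~20~ and HTDD~50~, analogues of
   ED~20~/ED~50~)?
2. *Interaction*: is a fixed-dose combination more toxic, less toxic, or
   exactly as toxic as dose-equivalence (Loewe additivity) predicts, and
   does the antioxidant N-acetylcysteine (NAC) shift the combination's
   toxicity?

## From thresholds to effects

The raw observation per animal is a pair (pre_dB, post_dB) with a stimulus
ceiling of 90 dB SPL. The percent "hearing threshold decrease" convention
is configurable because the mapping from a dB shift to a percentage admits
more than one natural definition:

* **headroom** (default): `100 * (post - pre) / (ceiling - pre)`. The
  effect is 0 when the threshold is unchanged and 100 exactly when the
  animal no longer responds at the loudest stimulus, so the effect scale is
  anchored at both ends of what the instrument can observe.
* **baseline**: `100 * (post - pre) / pre`, the shift relative to the
  pre-treatment threshold.

Every fit, table and report records which convention produced it. Records
where the post-treatment threshold is *below* the pre-treatment one are
excluded with a logged warning rather than clipped to zero: in this design
a negative shift indicates a measurement or labelling problem, and clipping
would silently bias the low-dose groups.

## The dose–response model

Within each treatment arm the effect is modelled as linear in log dose,

$$E_i = a + b\,\log_{10}(d_i) + \varepsilon_i,\qquad
\varepsilon_i \sim N(0, \sigma^2),$$

fitted by ordinary least squares over individual animals. A full sigmoidal
(4-parameter logistic) model is deliberately *not* used: each curve rests
on three dose groups, which cannot constrain four parameters, and the
20–80% band of a sigmoid is its near-linear region. The design requires at
least three distinct doses; fewer is an error, and an arm whose fitted
effects at the extreme doses fail to bracket the 20% and 50% targets is
flagged as extrapolating (with a warning) but still fitted.

Inverting the line gives the HTDD at level $p$:

$$\widehat{HTDD}_p = 10^{g},\qquad g = \frac{p - a}{b},$$

with a delta-method standard error on the dose scale,

$$\mathrm{Var}(g) = \frac{\mathrm{Var}(a) + g^2\,\mathrm{Var}(b)
  + 2g\,\mathrm{Cov}(a,b)}{b^2},\qquad
SE = \ln(10)\,\widehat{HTDD}_p\,\sqrt{\mathrm{Var}(g)},$$

carrying $n - 2$ residual degrees of freedom. The delta method is the
default because it is a reproducible closed form; a parametric bootstrap
(`htdd_bootstrap_se()`, resampling $(a, b)$ from the fitted bivariate
normal) ships as a cross-check and the test suite requires the two to agree
within 15% on every calibrated arm.

Group-level inference needs per-animal replicate values, which the summary
tables of such studies imply (4 arms × 6 replicates giving F(3; 20)) but
whose construction is rarely written down. This package's explicit,
documented construction is `per_animal_htdd()`: each animal's observed
effect is slid along the arm's common slope,

$$\log_{10}(HTDD_{p,i}) = \log_{10}(d_i) + \frac{p - E_i}{b},$$

and the replicate set for the ANOVA is the middle-dose group (n = 6 per
arm), reproducing the (3, 20) degrees-of-freedom shape. Using all 18
animals per arm instead is available via the `doses` argument.

## Isobolography for a fixed-dose design

The combinations studied here fix one drug's dose and vary the other, so
the classical fixed-ratio isobologram does not apply directly. Under Loewe
additivity the two drugs act as dose-equivalents, and the additive dose of
the variable drug at a constant co-drug dose $d_{fix}$ is the point on the
isobole line between the single-drug intercepts:

$$D_{add} = B_p\left(1 - \frac{d_{fix}}{A_p}\right),$$

where $A_p$ is the co-drug-alone HTDD~p~ and $B_p$ the variable-drug-alone
HTDD~p~ (point **A** of the isobologram). Its variance propagates both
single-drug uncertainties,

$$\mathrm{Var}(D_{add}) = \left(1 - \tfrac{d_{fix}}{A_p}\right)^2
\mathrm{Var}(B_p) + \left(\tfrac{B_p d_{fix}}{A_p^2}\right)^2
\mathrm{Var}(A_p),$$

with Welch–Satterthwaite effective degrees of freedom over the two
components — which is why comparisons against point A carry fractional dfs.
The experimental combination HTDD (point **B**) and the modifier-treated
combination (point **C**) are ordinary HTDD estimates.

Comparisons use Student's t on the dose scale,
$t = |d_1 - d_2| / \sqrt{SE_1^2 + SE_2^2}$: **A-vs-B** with Welch df
(one side carries propagated variance), **B-vs-C** with pooled df over the
replicate-based points (two 6-animal groups give df = 10). The
classification rule is: antagonistic if B is significantly *above* A (more
drug needed than additivity predicts), synergistic if significantly below,
additive otherwise; α = 0.05 two-sided throughout, one-sided variants
deliberately not offered as defaults.

An alternative "effect-subtraction" additive point — the dose of the
variable drug producing $p$ minus the co-drug's own fitted effect at
$d_{fix}$, read off the variable drug's curve — is available behind
`variant = "effect-subtraction"` for sensitivity analysis. The two variants
answer slightly different null hypotheses (dose-equivalence vs
effect-addition) and can disagree when the two drugs' slopes differ
strongly; reports name the variant used.

## Multiple comparisons

Across the four arms of each experiment set, per-animal HTDD replicates are
compared by classical one-way fixed-effects ANOVA followed by pooled
two-sample t-tests for all 6 unordered pairs, adjusted by the Holm–Šidák
step-down procedure: order the $m$ raw p-values ascending, set
$\tilde p_{(i)} = 1 - (1 - p_{(i)})^{m-i+1}$, enforce monotonicity by a
running maximum, and reject while $\tilde p \le \alpha$. This is uniformly
at least as powerful as Holm–Bonferroni, which the test suite asserts as a
property. The pairwise family is all pairs (the star/hash annotation
schemes of such studies reference at least three distinct baselines);
Welch correction is off by default for these pairwise tests, matching the
pooled df = 10 shape.

## The synthetic-data generator

No per-animal data are published for this design, so the generator is a
first-class module: it emulates the statistical structure the analysis
assumes, and calibration scenarios are seeded from the published HTDD
tables.

* **Calibration** inverts the model: `calibrate_curve(htdd20, htdd50)`
  solves $b = 30/(\log_{10} HTDD_{50} - \log_{10} HTDD_{20})$,
  $a = 20 - b \log_{10} HTDD_{20}$, so the true curve passes through both
  anchors exactly. One published arm (AMI+FUR(30)+NAC(500)) prints
  HTDD~20~ > HTDD~50~ — its two levels come from separate experiments with
  different drug-to-measurement intervals — so no single increasing line
  exists for it; it is flagged non-calibratable, and the bundled scenario
  substitutes a stand-in anchored at its HTDD~50~ with the slope of the
  matching AMI+FUR(30) arm so that the 4-arm design stays complete.
* **Dose design.** Doses default to the levels whose latent effects are
  15%, 35% and 65%: below 20, above 50, clear of both the 0% floor and the
  100% ceiling. A fixed-ratio design such as {0.7, 1, 1.3} × HTDD~50~ looks
  natural but fails for steep curves — the furosemide anchors imply a slope
  near 590 %/decade, for which that ratio design would place latent effects
  at −41% and +117%, and truncation would bias HTDD recovery by almost 10%.
  Choosing doses on the effect scale respects the design rule that observed
  effects must bracket the targets, for every slope.
* **Noise** is Gaussian, homoscedastic, on the percent-effect scale
  (matching the fitting model), with σ = 8% by default — a free parameter,
  since the underlying animal-level variance is not published; 8% makes the
  simulated standard errors at n = 6 the size of the published ones.
  Latent effects are truncated (not resampled) to [0, 100], preserving the
  alignment between seed position and animal index. Pre-treatment
  thresholds are Uniform(25, 45) dB SPL under a 90 dB ceiling; only the
  effect convention, not any biology, depends on this choice.
* **Interaction ground truth** (`generate_interaction_scenario()`) places
  the combination arm's true HTDD~p~ at `factor ×` the Loewe value,
  holding the variable drug's single-drug slope — the simplest model
  consistent with the fixed-dose design. Defaults: factor 1 (additive),
  2 (antagonistic), 0.5 (synergistic).

What the generator does **not** emulate: ABR waveforms or wave-V picking
(only the resulting thresholds), 5/10 dB quantisation of thresholds,
between-animal heterogeneity in drug sensitivity beyond the additive noise
term, dose-dependent variance, pharmacokinetic interactions between the
drugs, and any time course. Tests passing on synthetic data therefore show
that the *estimators and tests* behave correctly under the model's
assumptions at the study's design — not that real ABR data satisfy those
assumptions.

## Numerical and degenerate-input choices

* OLS is fitted by `stats::lm`; the coefficient covariance is recomputed
  directly from the normal equations so that noise-free (perfect-fit)
  input yields an exact zero covariance without spurious warnings.
* Fewer than 3 distinct doses, non-positive doses, or an all-identical
  dose column are errors, never a silent singular fit.
* `estimate_htdd` refuses non-positive slopes and levels outside (0, 100);
  extrapolation beyond the fitted effect range warns (suppressible).
* A comparison of two zero-variance points is an error unless the doses are
  exactly equal (then t = 0, p = 1).
* Satterthwaite dfs are computed on variance components and never rounded;
  pooled dfs are integer sums.
* Seeded generation saves and restores the caller's RNG state, so
  `generate_animals` is reproducible without clobbering an outer
  simulation loop.

## Problem sizes

The packaged simulations use the study's own design: 3 doses × 6 animals
per arm. Recovery checks run 500 simulated datasets per arm and require
the Monte-Carlo mean HTDD~20~/HTDD~50~ within 5% of the calibration truth;
test calibration runs 1000 additive-truth replicates (rejection rate
expected near α) and 500 antagonism-factor-2 replicates (power well above
50%); bootstrap cross-checks use 10,000 coefficient draws. These sizes give
Monte-Carlo standard errors comfortably below the tolerances they are
checked against.

## A short example

```{r example, eval = FALSE}
report <- run_pipeline(run_config(scenario = "ami-fur", seed = 42,
                                  outdir = tempfile("oto_")))
print(report)
report$htdd                      # the HTDD20/HTDD50 table
report$interactions$FUR_p20$a_vs_b   # antagonism call on the FUR axis
```

## Known limitations

* The effect convention is a modelling choice: the published description
  ("pretreatment threshold predicted to be 100%") is compatible with both
  implemented conventions, and without raw thresholds neither can be
  verified against data. All outputs carry the convention label.
* The replicate construction behind per-arm ANOVA (and hence the exact
  published F values) is not documented in studies of this design; the
  package's `per_animal_htdd` construction reproduces the degrees-of-freedom
  structure but not any specific published statistic.
* The printed t statistics for comparisons along the constant-FUR axis are
  not recoverable from the printed summary values under either additivity
  variant; the package reports both variants and makes no claim to
  reproduce those statistics.
* No probit/logit latent-tolerance modelling, no mixed-effects animal
  models, no fixed-ratio isobolograms, and no three-drug additivity
  surface (NAC is treated strictly as a modifier).
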