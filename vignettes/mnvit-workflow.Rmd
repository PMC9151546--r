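---
title: "From plate to priority: the mnscreen MNvit analysis workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plate to priority: the mnscreen MNvit analysis workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnscreen)
```

## The problem

The flow-cytometric in vitro micronucleus (MNvit) test detects chromosome
fragments and whole lost chromosomes as micronuclei in the cytoplasm of
divided cells; hypodiploid (sub-2N) nuclei additionally flag aneugenic
mechanisms. Run in a high-throughput format — each chemical at 19
concentrations spanning a 1.25× geometric series up to 200 µM, one well
per concentration, with and without S9 metabolic activation — the design
trades concentration-level replication for breadth, which makes
benchmark-concentration (BMC) modeling rather than pairwise testing the
natural potency analysis. `mnscreen` implements the complete
interpretation chain: QC and batch referencing, a hazard decision tree,
trend testing, BMC modeling, in vitro-to-in vivo extrapolation (IVIVE),
and bioactivity-exposure-ratio (BER) prioritization.

## Endpoints and cytotoxicity

Each well yields `%MN` and `%hypodiploid` (events in the endpoint gate as
a percent of nucleated events) and relative survival (the nuclei:bead
ratio over the vehicle-control ratio, ×100). Survival is deliberately not
clipped at 100 — proliferative responses above control occur in real
screens. Concentrations are categorized by fixed cut points:
cytotoxic below 40% survival, adequate at 40–60%, non-cytotoxic above
60%. The two boundary values are assigned to "adequate" so the three
categories partition the survival axis; this matches the strictness of
the two defining inequalities. Only non-cytotoxic and adequate
concentrations enter trend testing and BMC modeling, because damage
observed under overt cytotoxicity is uninterpretable as genotoxicity.

## Batch referencing and QC

Every assay date is a batch. Solvent-control (DMSO) wells are pooled per
batch and S9 condition, and the upper 95th percentile of control `%MN`
and `%hypodiploid` becomes the reference threshold each treated
concentration is compared against. The percentile estimator is fixed to
the linearly interpolated type-7 quantile (the default of this
statistical environment): reproducing reference tables depends on the
quantile definition, so it is pinned rather than left to chance.

Outlier screening of pooled controls uses the robust median ± k·MAD rule
(k = 3.5, scaled MAD). Flags are advisory only: data removal happens
exclusively through an explicit (batch date, plate) exclusion list,
mirroring how an analyst removes a failed plate after inspection.

## The decision tree

A dataset (one chemical in one S9 condition) is evaluated as:

1. **Exceedance pattern (a, b).** At least two *consecutive*
   concentrations in the ordered series must exceed the batch reference
   threshold, both at non-cytotoxic or adequate cytotoxicity. Exceedances
   confined to cytotoxic concentrations are negative evidence, not
   positive.
2. **Two-fold filter (optional).** A conservative variant additionally
   requires at least one usable concentration strictly above 2× the
   concurrent control. It can only shrink the positive set.
3. **Trend (c).** The Jonckheere–Terpstra test for an increasing
   concentration–response, at one-sided α = 0.05.
4. **Potency bound (d).** The BMC at the endpoint's benchmark response
   must exist and lie within the modeled concentration range.

If the exceedance pattern fails, the verdict is negative provided the top
tested concentration reached at least adequate cytotoxicity, and
*inconclusive* otherwise — a flat response in a test that never stressed
the cells cannot rule the chemical out. Every negative or inconclusive
call carries machine-readable reason codes, so a verdict can be replayed
from its trail.

Conditions combine as: chemical positive if either ±S9 dataset is
positive; negative only if both are negative; inconclusive otherwise.
Replicate tests of the same chemical and condition aggregate
any-positive, then any-negative — the interpretation we adopt for a
design in which a chemical may appear on several plates; it is exposed in
`combine_replicates()` so other policies can be substituted.

Aneugenicity is assessed twice: by the identical decision tree on
`%hypodiploid` with a 60% benchmark response, and by the stricter
fold-change rule (positive only if some concentration shows both %MN fold
change > 3 *and* %hypodiploid fold change > 10 over the concurrent
control, strict inequalities, no cytotoxicity gate).

### Trend test details

The JT statistic counts increasing cross-group pairs with ties as half.
The solvent-control group (concentration 0) is included as the lowest
ordered group: with one well per treated concentration it anchors the
trend. P-values are exact — the full permutation distribution, obtained
by recursive enumeration of distinct group assignments — whenever the
total sample size is at most 10 *and* the number of assignments (the
multinomial coefficient) is at most 10⁵; beyond that a normal
approximation with tie-corrected variance is used. The cap exists because
ten singleton groups already imply 3.6 million arrangements; every
configuration with n ≤ 8 stays exact.

## BMC modeling

The EFSA model-5 continuous families,

$$\text{exponential5: } y = a\,[c - (c-1)e^{-(x/b)^d}], \qquad
  \text{hill5: } y = a\,[1 + (c-1)\tfrac{x^d}{b^d + x^d}],$$

are fitted by maximum likelihood under multiplicative lognormal errors
(normal on log response), the natural model for strictly positive
percentage endpoints whose spread grows with the mean. Parameters:
background `a` (%), potency `b` (µM), maximum fold change `c`
(dimensionless, > 1 for an increasing response), shape `d`.

Numerical choices, all configurable:

* **Zero responses** (possible at low concentrations) are replaced by
  half the smallest positive response in the dataset before the log
  transform; the count is recorded.
* **Optimization** is a deterministic multi-start Nelder–Mead on
  log-parameters (9 starts: `b` over concentration quartiles × `d` over
  0.5/1/2, with `a` and `c` from the data), so fits are reproducible
  without a random seed.
* **Shape bound** `d ≤ 4`. Unconstrained, the shape parameter can run
  away (fits of 20–130 were observed on simulated data), collapsing the
  curve to a step function whose confidence interval is spuriously tight;
  bounding the shape is standard benchmark-dose practice.
* **Model selection**: lowest AIC (`2k − 2ℓ`, `k` = 4 curve parameters +
  1 variance; 2 for the constant model) among converged full fits, kept
  only if it beats the constant model by more than 2 AIC units —
  otherwise the dataset has "no concentration–response". The margin of 2
  is the conventional information-criterion rule of thumb.

The BMC inverts the fitted curve at a benchmark response defined as a
fractional increase over background: 0.30 for `%MN` and 0.60 for
`%hypodiploid`, each chosen to approximate one standard deviation of the
control distribution for that endpoint. When the fitted plateau is below
the benchmark response the BMC does not exist and the dataset cannot be
positive.

**Confidence limits** are profile-likelihood bounds with the BMC itself
as a model parameter (`b` is recovered from `(BMC, c, d)`). Because the
residual variance is estimated from ~20 points, the deviance threshold is
the F-calibrated `n·log(1 + q_F(0.90, 1, n-4)/(n-4))` rather than the
χ² limit — the standard small-sample calibration for nonlinear-regression
profiles. The profile is walked outward in 1.4× steps with warm starts
and the crossing refined by root finding; an upper bound that never
crosses within six decades of the tested range is reported as unbounded.

## IVIVE and BER

Microsomal intrinsic clearance (µL/min/mg protein) is scaled to
hepatocellularity units by 32 mg microsomal protein/g liver ÷ 99×10⁶
cells/g liver, then to whole-liver clearance (L/h/kg bw) via liver mass.
The three-compartment steady-state model combines well-stirred hepatic
clearance, `Q_l·fup·CL_int / (Q_l + fup·CL_int/R_b)`, with renal
filtration `GFR·fup`, giving the plasma concentration at a constant
1 mg/kg bw/day infusion; linearity then gives `AED = BMC / Css`.

The Css is a deterministic point estimate. Population Monte-Carlo
variants exist in dedicated toxicokinetics packages, but a fixed
parameter set is reproducible and sufficient for rank-based
prioritization; the physiology is exposed and overridable:
GFR 0.31 L/h/kg, liver blood flow 5.4 L/h/kg, liver mass 24.5 g/kg bw,
blood:plasma ratio 1, and a fraction-unbound floor of 10⁻⁴ that keeps
total clearance positive for extensively bound chemicals. These are
order-of-magnitude human values; because the AED enters prioritization
on the log scale, rankings are insensitive to modest changes in them.
The parent compound's kinetics are used even for activation-dependent
positives — a deliberately conservative metabolite assumption.

BERs are computed on both exposure bases (median and 95th percentile)
side by side, reported on arithmetic and log scales (exact transforms of
each other), and banded at log10BER 0, 2 and 3; a BER below 100
(log10BER < 2) is the conventional priority flag. Chemicals with missing
or zero exposure are excluded from ranking with an explicit flag rather
than given an infinite ratio.

## The synthetic-study generator

`simulate_study()` emulates the screening design: per plate, 8 DMSO
wells, 6 positive-control wells (vinblastine −S9 at 0.00625/0.0125/0.025,
cyclophosphamide +S9 at 1.25/2.5/5, in duplicate), and 4 chemicals × (19
concentrations + a concurrent control well); plates are assigned to batch
dates whose control levels carry a lognormal offset (sd 0.10). The
concentration series completes the printed 1.25× geometric ladder
downward with 3.60 µM to give 19 points ending at 200 µM.

Endpoint noise is multiplicative lognormal with a coefficient of
variation of 0.30 for `%MN` and 0.60 for `%hypodiploid` — the same
dispersion that motivates the 30%/60% benchmark responses — so the
generator and the fitting error model agree and parameter-recovery tests
are well-posed. Control means (1.2/1.1 `%MN`, 0.35/0.20 `%hypodiploid`
for −S9/+S9) were chosen so the implied batch 95th percentiles fall in
the range reported for real DMSO controls. Survival declines follow a
logistic curve in concentration with 8% multiplicative noise. The default
truth set (10 clastogens with Hill plateaus of 3–6× background, two of
them S9-dependent; 2 aneugens with 20–25× hypodiploidy induction; 8
inactives, half cytotoxic at the top of the range and half not) exercises
every branch of the decision tree, and each chemical's true BMC30/BMC60
follows in closed form from its planted Hill parameters.

What the generator does *not* emulate — and what green tests therefore do
not establish about real data: plate-position effects, correlated noise
within plates, solubility or volatility artifacts, apoptosis-driven
distortion of the hypodiploid gate, fold-change baselines from very low
control counts, and model-form error (real concentration–responses are
not exactly Hill). The three reproduction tests against the real study's
published counts exist precisely to close that gap when the converted
dataset is available.

## Known limitations

* With one well per concentration the trend test relies on its normal
  approximation for most real datasets; exact inference is available only
  for small designs.
* AIC selection between the two model-5 families is unreliable at
  realistic noise (they mimic each other on this design); the BMC is
  nevertheless stable because both families must pass through the same
  benchmark region. Model averaging would be a natural extension.
* The fold-change aneugen rule divides by a single concurrent-control
  well; with a low draw in that well, occasional false positives are
  expected, which is inherent to the published rule rather than to this
  implementation.
* IVIVE covers the parent compound only, with deterministic physiology;
  chemicals whose activity is driven by intracellular accumulation or by
  metabolites outside the conservative equal-clearance assumption need
  higher-tier models.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the default 20-chemical,
2-batch study (940 wells), 200 seeded replicates for interval coverage,
the exhaustive trend-test sweep over all 219 group configurations with
n ≤ 8, and 1000 random parameter draws for the closed-form/numeric BMC
equivalence — sizes chosen so the whole suite completes in minutes on a
single CPU while still exercising every code path.
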