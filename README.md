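# mnscreen

Quantitative interpretation of high-throughput **in vitro micronucleus
(MNvit)** screens: from per-well flow-cytometry plate data to genotoxic
hazard calls, benchmark-concentration (BMC) potencies, administered
equivalent doses (AEDs), and bioactivity exposure ratio (BER) risk
rankings.

The package is written for genetic toxicologists and computational
toxicologists who run (or re-analyze) plate-based MNvit screens in which
each chemical is tested over a wide concentration series (by default 19
concentrations up to 200 µM, one well per concentration) with
plate-level DMSO solvent controls and ±S9 metabolic activation, and who
want reproducible, machine-auditable positive/negative/inconclusive
calls plus risk-based prioritization instead of a bare dichotomous
verdict.

## What it computes

**Endpoints.** Per well: `%MN` (micronucleated cells as a percent of
nucleated events), `%hypodiploid` (sub-2N nuclei, the aneugenicity
readout), and relative survival (nuclei:bead ratio over the vehicle
control, ×100 — the cytotoxicity metric). Concentrations are categorized
as cytotoxic (survival < 40%), adequate (40–60%), or non-cytotoxic
(> 60%); only the latter two enter statistical analysis.

**QC.** Solvent controls are pooled per batch date and the upper 95th
percentiles of control %MN and %hypodiploid (type-7 quantiles) become
batch-specific reference thresholds. Robust median/MAD flags screen
control outliers; actual removals are always explicit (batch, plate)
exclusions.

**Hazard decision tree.** A dataset (chemical × S9 condition) is
positive when (a) two consecutive concentrations exceed the batch
reference at acceptable cytotoxicity, (b) optionally at least one
response is > 2× the concurrent control, (c) the Jonckheere–Terpstra
test shows an increasing concentration–response (exact permutation
p-value for small n, tie-corrected normal approximation otherwise), and
(d) the BMC is within the tested range. Conditions (−S9, +S9) combine
as: positive if either is positive, negative only if both are.

**Potency.** Concentration–response is modeled with the EFSA model-5
continuous families under multiplicative lognormal errors,

    exponential5:  y = a·[c − (c−1)·exp(−(x/b)^d)]
    hill5:         y = a·[1 + (c−1)·x^d/(b^d + x^d)]

selected by AIC against a constant model, and inverted at a benchmark
response (BMR) of a 30% increase for %MN (60% for %hypodiploid — one
control SD in each case) to give the BMC, with two-sided 90%
profile-likelihood confidence limits (BMCL, BMCU).

**IVIVE & BER.** Microsomal intrinsic clearance is scaled by 32 mg
microsomal protein/g liver and 99×10⁶ cells/g liver; a three-compartment
steady-state model (well-stirred hepatic clearance + renal filtration of
the unbound fraction) gives the plasma Css at a 1 mg/kg bw/day infusion,
and `AED = BMC/Css`. Against exposure estimates,
`log10BER = log10(AED) − log10(exposure)` ranks chemicals into priority
bands (< 0, 0–2, 2–3, ≥ 3).

A seeded synthetic-study generator (`simulate_study()`) reproduces the
plate layout with known ground truth (planted clastogens, aneugens,
inactives, and their closed-form true BMCs), so the whole pipeline is
testable end to end without external data.

## Worked example

```r
library(mnscreen)

## a synthetic 20-chemical study with known truth
sim <- simulate_study(simulation_config(seed = 1))
res <- run_pipeline(sim$wells)
print(res)
#> <mn_pipeline_result>
#>   wells: 940 read, 0 excluded; 2 batch(es); 20 chemical(s)
#>   MN calls:   12 positive / 4 negative / 4 inconclusive
#>   hypo calls: 2 positive / 14 negative / 4 inconclusive
#>   fold-change aneugens: 2
```

All 12 planted genotoxicants (10 clastogens + 2 aneugens, which also
induce micronuclei) are called MN-positive; the 8 inactives split into
negative (cytotoxic at the top of the range, so conclusively negative)
and inconclusive (never cytotoxic, so the test cannot rule them out).

```r
## one dataset by hand: fit, BMC, IVIVE, BER
x <- c(0, default_concentration_series())
set.seed(99)
y <- 1.2 * (1 + 2 * x^2 / (15^2 + x^2)) * exp(rnorm(length(x), 0, 0.2))
fit <- fit_dose_response(x, y, bmr = 0.30, ci = TRUE)
#> BMC30 = 6.72 uM, 90% CI [0.64, 17.25]  (hill5 selected by AIC)

css <- css_unit_infusion(molecular_weight = 250, fup = 0.3, hlm_clint = 12)
aed <- compute_aed(fit$bmc, css)
#> Css = 0.648 uM per mg/kg/day  ->  AED = 10.38 mg/kg bw/day

compute_ber(aed, exposure = 1e-5)
#> ber = 1037652, log10ber = 6.02   (band "gt_3": low priority)
```

A thin command-line wrapper with `simulate`, `qc`, `classify`, and
`run-all` verbs is at `inst/scripts/mnscreen-cli.R`.

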