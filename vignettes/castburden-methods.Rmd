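---
title: "Methods: CAST burden testing with Firth regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAST burden testing with Firth regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castburden)
```

## The problem

Clinical whole-exome sequencing of children with neurodevelopmental
disorders (NDDs) leaves the majority of cases without a molecular
diagnosis. Gene burden testing asks a complementary question: are rare
predicted loss-of-function (LoF) variants *collectively* enriched in a
gene among cases relative to population controls, even when no single
variant is individually diagnostic? The setting this package targets
is highly unbalanced — on the order of 10^2 pediatric cases against
10^3 population-matched controls — with very rare qualifying alleles,
which is exactly the regime where naive logistic regression fails.

## The statistic

For each gene, qualifying variants are collapsed into a per-sample
binary carrier indicator (the CAST statistic): a sample scores 1 if it
carries at least one qualifying allele at any of the gene's surviving
sites. Zygosity does not add weight; a homozygote counts once. Two
tests are then applied to the indicator:

1. **Right-tailed Fisher exact test** on the 2×2 case/control by
   carrier/non-carrier table. The p-value is the upper tail of the
   central hypergeometric distribution at the observed case-carrier
   count, computed by enumeration in log space so the 10^3-control
   margin cannot overflow.
2. **Firth bias-reduced logistic regression** of case status on the
   carrier indicator, adjusted for sex (0/1), age (standardized to
   mean 0, SD 1) and family history (0/1). The fit maximizes the
   Jeffreys-penalized log-likelihood
   $\ell(\beta) + \tfrac12 \log\det I(\beta)$,
   which keeps estimates finite under complete separation — the
   normal situation for a gene with several case carriers and zero
   control carriers.

Each test's p-value column is adjusted with the Benjamini–Hochberg
step-up procedure across eligible genes, and a gene is flagged when
its adjusted q-value is at or below 0.005 (an FDR of 0.5%, boundary
inclusive). A gene is *eligible* when it retains at least 5 distinct
LoF sites after filtering; the threshold counts variant sites, not
carriers — the carrier-count reading of "at least 5 rare LoF variants"
is available through `qc_thresholds(min_lof_variants = )` but is not
the default.

### Which Firth p-value

`run_burden()` reports the **penalized likelihood-ratio test** of the
carrier term as `firth_p` (the null model without the indicator is
fitted once per cohort), while the odds ratio and its 95% interval
come from the Wald machinery ($e^{\hat\beta}$, $e^{\hat\beta \pm
1.96\,\mathrm{se}}$). This split follows the established convention
for bias-reduced logistic software: under near-separation the Wald
statistic collapses — the penalty shrinks $\hat\beta$ while the
standard error inflates, so a gene with six case carriers and zero
control carriers gets a Wald p around 5×10⁻⁴ no matter how
overwhelming the evidence, and could never clear an FDR of 0.5%
against dozens of genes. The likelihood-ratio statistic does not
suffer this collapse and agrees closely with the Fisher exact tail in
that regime. `wald_inference()` remains the default summary for
standalone `firth_logit()` fits, where effect reporting rather than
screening is the goal.

## Variant filters

* **Depth**: genotype calls with read depth below 20× are set to
  missing (the call, not the site, is removed); 20× exactly is kept.
  Missing genotypes count as non-carriers throughout.
* **Frequency**: sites with population (gnomAD-style) MAF at or above
  5% are removed; the bound is exclusive, so MAF = 0.049 survives and
  0.050 does not. Sites absent from the reference database are treated
  as rare and retained.
* **Consequence**: only predicted LoF classes enter the burden path.
  The default vocabulary is {stop_gained, frameshift_variant,
  splice_acceptor_variant, splice_donor_variant, start_lost,
  stop_lost}; the source annotation never enumerates its LoF classes,
  so the set is configurable.
* **Penetrant-model filter**: any variant carried by at least one
  control — het or hom — is excluded, so every surviving case-observed
  variant is case-private. This emulates a fully penetrant Mendelian
  disease model. Variant identity is the exact
  `chrom:pos:ref:alt` key. Control-only variants are dropped from the
  analysis set too; they cannot contribute to case burden, so CAST
  carrier counts among cases are identical either way (a property the
  tests verify). Compound heterozygosity is not reconstructed: sites
  are modeled independently, and any non-zero dosage at any site makes
  a control a carrier of that site, which subsumes the intent of the
  "any zygosity" rule.

The filters commute on the case-carried variant set and are
idempotent; tightening a threshold can only shrink the surviving set.

## The synthetic cohort generator

`simulate_cohort()` generates the statistical structure the burden
test assumes, not sequence-level realism. Defaults mirror the study
design the package emulates: 94 cases versus 1246 unrelated
population-matched controls; planted burden genes with **exactly** 6
case carriers and 0 control carriers (counts are exact, not
expectations — the planted truth must be unambiguous for recovery
studies); cases aged 1–168 months; 27% of cases and 5% of controls
with a positive family history; case subgroup shares of 36/39/13/6
across ASD/ID/GDD/SLD; constant 100× depth.

Choices the source design leaves open, fixed here once:

* **Background carrier frequency** 0.005 per gene per sample — a
  realistic cumulative carrier frequency of rare LoF alleles for an
  average gene.
* **Control ages** span 1–216 months, overlapping the case range. If
  the two age ranges were disjoint, case status would be perfectly
  predictable from age alone and every age-adjusted fit on the cohort
  would be degenerate; an age-matched control panel is the design a
  covariate-adjusted analysis presupposes.
* **Carrier realization**: every carrier receives one heterozygous
  private site by default (rare LoF carriers are overwhelmingly het);
  `hom_carrier_prob` plants homozygotes and `plant_shared_sites`
  plants case/control-shared sites to exercise the zygosity-blind
  penetrant filter.
* **Sex** is Bernoulli (cases 61/94 male), **age** uniform over its
  range, **family history** Bernoulli.

What the generator does **not** model: linkage disequilibrium,
relatedness, population stratification, non-LoF variant classes,
annotation error, or depth-correlated genotyping error. Passing
recovery and calibration studies on this generator therefore
demonstrate the statistical machinery, not robustness to those
real-data complications (the emulated study handles relatedness and
ancestry by sample exclusion upstream).

### The penetrant filter and calibration studies

Under the generator's sharing-free output the penetrant filter has a
structural side effect: every control carrier in a *null* gene holds a
private variant, so the filter removes all control carriers and turns
every null gene into a case-only gene — by construction, not by
signal. This is a deliberate enrichment device of the emulated design,
not a calibrated test component. The recovery and null-calibration
studies therefore feed QC-filtered genotypes directly to
`run_burden()` (whose contract takes already-filtered input), and the
filter's contract — no surviving case-carried key in any control, in
any zygosity — is verified separately on adversarial simulations with
planted shared and homozygous control sites.

## Numerical choices

* **Fisher two-sided p** uses the probability-mass rule (the sum over
  tables whose point probability does not exceed the observed one),
  with a relative tolerance of 1e-7 on the comparison so
  floating-point ties count; no mid-p, no doubling.
* **Firth solver**: Newton iteration on the modified score
  $U^*(\beta) = X^\top(y - p + h(\tfrac12 - p))$ with $h$ the
  leverages of the weighted hat matrix; initialization at
  $\beta = 0$; inverse of $X^\top WX$ as both step matrix and
  covariance at convergence. Steps are capped at 5 log-odds units per
  coordinate and halved (up to 5 times) when the penalized
  log-likelihood genuinely decreases, with a small noise tolerance so
  full steps survive near the optimum. Because $X^\top WX$ only
  approximates the Jacobian of $U^*$, near-degenerate directions can
  overshoot by up to a factor 2 and oscillate; an adaptive damping
  factor (halved while the score is not contracting, relaxed once it
  is) removes the oscillation. Convergence is declared at
  $\max|U^*| < 10^{-6}$ (configurable) within 100 iterations.
  Zero-variance and collinear columns are dropped with a warning
  before fitting.
* **Ties and ordering**: burden results sort by Firth q-value, then
  gene symbol; BH is applied over eligible genes only (whether the
  emulated analysis adjusted genome-wide is unstated).
* **Degenerate inputs**: a gene with no carriers in either group gets
  p = 1 from both tests; a gene whose indicator is dropped as
  degenerate gets `firth_p = 1`; non-converged fits propagate `NA`
  p-values and are excluded from BH.

## Diagnostic yield conventions

`compute_yields()` counts a case as diagnosed when it has at least one
reported finding of any class (pathogenic, likely pathogenic, or VUS);
a compound heterozygote with two variant records counts once. Subgroup
yields are reported under two denominators: `yield_vs_cohort` divides
by the whole cohort size — the convention that reproduces the emulated
study's printed subgroup yields — and `yield_within_group` divides by
the subgroup size. Pairwise subgroup comparisons use two-sided Fisher
tests on within-group diagnosed/undiagnosed tables, optionally adding
a pooled ID/GDD group against the groups outside the pool. The printed
pairwise p-values of the emulated study cannot be regenerated from any
2×2 table constructible from its printed counts; the package makes no
attempt to match them and reports the p-values its own tables imply.

## Validation study sizes

The shipped test suite exercises: exact Fisher agreement with full
enumeration for all 2×2 tables with N ≤ 30 (both tails, 1e-12);
intercept-only Firth fits against the closed form
$\mathrm{logit}((k+\tfrac12)/(n+1))$ for all $k \le n \le 50$ (1e-8)
and separated two-parameter fits against grid search (1e-3); 1000
random completely separated datasets (all finite, |β| < 50); planted
recovery over 20 seeds at 60 cases / 1246 controls / 50 genes / 4
planted; and null calibration over 500 genes at the default cohort
size. These sizes give stable pass/fail behavior at interactive run
times while matching the emulated study's dimensions where it states
them.

## Known limitations

* The Wald covariance is the inverse penalized information at the
  optimum; profile-penalized-likelihood intervals are not implemented.
* The simulator plants marginal carrier enrichment only; it cannot
  express epistasis, variable expressivity, or per-gene mutation-rate
  heterogeneity.
* The penetrant filter keys on exact allele identity; position- or
  gene-level matching would be stricter and is not offered.
* Burden results on real cohorts depend on upstream annotation
  (consequence calls, population frequencies) that the package
  consumes as given.
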