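Package: castburden
Title: Rare-Variant Gene Burden Testing with CAST Collapsing and Firth
    Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case/control gene burden analysis of rare predicted
    loss-of-function variants for clinical whole-exome cohorts.
    Collapses qualifying variants per gene into a CAST (Cohort Allelic
    Sums Test) carrier indicator, tests enrichment with a right-tailed
    Fisher exact test and a covariate-adjusted Firth bias-reduced
    logistic regression, and controls the false discovery rate with
    Benjamini-Hochberg adjustment. Includes a deterministic synthetic
    cohort simulator with planted burden-enriched genes, the variant
    quality-control and fully-penetrant-model filters used upstream of
    the burden test, and diagnostic-yield summaries with pairwise
    two-tailed Fisher comparisons for clinical exome cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
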