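Package: dtmr
Title: Drug-Target Mendelian Randomization with Correlated Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for drug-target Mendelian randomization (MR) from GWAS
    summary statistics: cis-pQTL instrument selection with LD clumping,
    Wald-ratio and inverse-variance weighted (IVW) estimators including a
    generalized least squares (GLS) IVW estimator for LD-correlated
    instruments, single-causal-variant Bayesian colocalization (PP.H0-H4),
    genetic-mimicry concordance between common and protein-truncating
    variants, fixed- and random-effects meta-analysis with Cochran Q, and
    phenome-wide single-variant MR scans with per-family Bonferroni
    multiplicity. A synthetic summary-statistics generator with known ground
    truth (autoregressive LD, cis regions, rare-carrier 2x2 tables,
    metabolite panels) makes every stage testable without access to
    restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
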