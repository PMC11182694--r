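---
title: "Drug-target Mendelian randomization with correlated cis instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with correlated cis instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmr)
```

## The problem

Drug-target Mendelian randomization (MR) asks what happens to a disease
outcome when a protein is pharmacologically inhibited, using genetics as the
experiment nature already ran: variants near the target gene that lower the
plasma abundance of its protein (cis-pQTLs) stand in for the drug, and their
association with the outcome, scaled by their effect on the protein, estimates
the causal effect of target inhibition. The approach rests on the usual
instrumental-variable assumptions — the variants affect the protein
(relevance), are not confounded with the outcome (independence), and act on
the outcome only through the protein (exclusion). `dtmr` implements the full
analysis cycle for this design: instrument selection, estimation with
LD-correlated instruments, colocalization, concordance validation against
protein-truncating variants (PTVs), study-level meta-analysis and
phenome-wide scanning — together with a synthetic summary-statistics
generator so that every estimator can be validated by parameter recovery
against known truth.

## Estimators

For a single variant the causal effect is the **Wald ratio**
$\hat\theta = \hat\beta_Y / \hat\beta_X$ with first-order standard error
$se_Y / |\hat\beta_X|$. The exposure-side uncertainty is ignored at first
order; for the strong instruments this design requires (cis-pQTL z-scores
of 10–60), the second-order term is negligible and the first-order SE is
conservative.

Multiple independent instruments combine by **inverse-variance weighting
(IVW)**, the slope of the zero-intercept regression of outcome on exposure
betas weighted by $1/se_Y^2$. Cochran's Q over the per-variant ratios
summarizes heterogeneity; the random-effects variant inflates the SE by the
multiplicative overdispersion factor $\max(1, \sqrt{Q/(k-1)})$ — the
two-sample-MR convention, chosen over an additive $\tau^2$ because it never
reports a smaller SE than the fixed-effect model.

Instruments drawn from one cis window stay correlated even after clumping,
and plain IVW then overstates the information. The **GLS-IVW** estimator
restores valid inference by whitening with the LD-induced covariance of the
outcome effects: with $X$ the exposure betas, $Y$ the outcome betas and
$\Omega_{ij} = se_{Y_i} se_{Y_j} r_{ij}$,

$$\hat\theta = (X^\top \Omega^{-1} X)^{-1} X^\top \Omega^{-1} Y,
\qquad se(\hat\theta) = \sqrt{(X^\top \Omega^{-1} X)^{-1}}.$$

The exposure betas are treated as fixed (outcome-SE-only covariance), the
standard correlated-instrument IVW convention; whether one should propagate
bivariate uncertainty instead is a genuinely open design point, and the
outcome-SE convention was chosen because it is the published norm and is
exact under the strong-instrument regime the selection thresholds enforce.
With identity LD the estimator reduces algebraically to fixed-effect IVW,
and at one instrument to the Wald ratio — the test suite asserts this chain
at $10^{-10}$.

Two practical guards matter here. First, $\Omega$ must be invertible:
input LD matrices that fail positive semi-definiteness (a common artifact
of reference-panel noise or row subsetting) are conditioned by clipping
eigenvalues at $10^{-8}$ and re-normalizing the diagonal to 1. Second, even
a PSD $\Omega$ can be numerically ruinous when two instruments are nearly
collinear; `gls_ivw()` refuses when the condition number exceeds $10^8$ and
advises stricter clumping — which is exactly why the default clumping
threshold removes pairs at $r^2 \ge 0.10$.

## Instrument selection

`select_cis()` keeps variants within 2.5 kb of the gene body (the `cis_pad`
default) reaching $P \le 5\times10^{-8}$ on the exposure, then greedily
clumps: visit candidates by ascending p-value, accept, and drop everything
with $r^2 \ge$ `clump_r2` (default 0.10) to an accepted variant. Ties in p
break by position then id; the output is therefore invariant to input row
order, and equals the lexicographically-first maximal pairwise-compatible
subset — the property the test suite checks against an exhaustive
subset-enumeration oracle on random 10-variant instances. Genome-wide mode
(for positive-control analyses on a polygenic exposure) adds a positional
window (default 500 kb) between accepted index variants and is meant to be
used with a much stricter `clump_r2` (0.001), after which plain IVW is
appropriate.

The sensitivity filter `filter_functional_variants()` restricts instruments
to plausibly functional variants at a relaxed $P \le 0.01$: damaging
missense (SIFT deleterious, or PolyPhen probably/possibly damaging — the
PolyPhen vocabulary has no "likely", so this mapping is a documented
choice) plus UTR, splice, stop-gained and frameshift classes.
`flag_ptv()` marks truncating consequences below 5% allele frequency.

## Colocalization

A significant cis MR association can be an LD artifact: a distinct causal
variant for the outcome, correlated with the pQTL. `colocalize()` runs the
standard single-causal-variant Bayesian test over the ±250 kb region. Each
variant's evidence is the Wakefield approximate Bayes factor
$ABF = \sqrt{1-K}\exp(Kz^2/2)$, $K = W/(W+se^2)$, and the five hypotheses
(no association; trait 1 only; trait 2 only; both, distinct variants;
both, shared variant) are scored by configuration sums evaluated entirely
in log space, so that z-scores in the hundreds (routine for strong pQTLs)
cannot overflow. Priors default to the field-standard
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$; the prior effect variance
defaults to $W = 0.15^2$ for quantitative traits, with $0.2^2$ recommended
on the log-OR scale. Posteriors sum to 1 on every input, $PP.H_4$ is
monotone in $p_{12}$, and on small problems the log-space evaluation
matches direct enumeration to $10^{-9}$ — all asserted in tests.

## Concordance and meta-analysis

`mimicry()` quantifies whether common-variant models "mimic" gene
inactivation: across a metabolite panel, the PTV collapsing estimates
(scaled by their 1-s.d. TG effect) are regressed on the common-variant MR
estimates and concordance is reported as $R^2$. `meta_fixed()` pools
sequencing-genotyped PTV studies per allele or per mmol/L TG; the per-TG
scale divides each study's log-OR by its own $|$TG effect$|$, substituting
the pooled IVW TG estimate where a study lacks one. The per-TG SE ignores
denominator uncertainty (first-order) — a deliberate, documented
simplification matching standard practice. The absolute value is used for
the denominator with orientation left to the caller, since protective
alleles would otherwise silently flip signs. `carrier_log_or()` supplies
the Woolf 2×2 estimator with Haldane–Anscombe correction for zero cells.

## Multiplicity and phenome-wide scans

Each analysis family carries its own Bonferroni divisor, composed as
outcomes × exposures + extra models: 40 for the primary disease outcomes
(5 × (3 protein + 4 TG exposures) + 5 genome-wide models), 45 for risk
factors (15 × 3), 33 for imaging (11 × 3), 129 for blood chemistry
(43 × 3) and 2082 phenome-wide (694 × 3). Safety-signal scans use $m = 1$:
when the point is to surface potential harms, a missed true signal is
costlier than a false positive. CIs are widened to the $1 - 0.05/m$ level
when a divisor is attached. `phewas_scan()` reports outcomes missing the
instrument as *not testable* rather than null — absence of data is not
absence of effect.

## The synthetic-data generator

`simulate_region()` draws a cis window under a single-causal-variant model:
AR(1) LD $r_{ij} = \rho^{|i-j|}$ (one parameter, realistic monotone decay;
a two-block option with zero cross-block correlation provides the
distinct-signals colocalization scenario), marginal exposure effects equal
to the causal effect propagated through LD on the standardized-genotype
scale, outcome effects $\theta$ times the exposure effects (the exclusion
restriction), and multivariate-normal sampling noise whose correlation is
the LD matrix — the property that makes naive IVW under-cover and GLS
recover. Binary-outcome effects are generated directly on the log-OR scale
with Gaussian noise rather than via individual-level logistic draws:
two-sample MR consumes only summary statistics, and the summary-level
formulation keeps the oracle analytic (conditional on the exposure betas,
the GLS z-statistic is exactly standard normal under the null, so type-I
error is exact by construction, not approximately calibrated).
Exposure and outcome samples are independent (two-sample design, no
overlap knob).

Defaults were fixed once, to values a practitioner would call realistic
for this design, and are not tuned: causal effect 1.0 s.d. protein per
allele (published cis-pQTL instruments for these targets span 0.22–2.19),
exposure n = 35 000 (large pQTL GWAS), outcome n = 300 000 with case
fraction 0.25 (disease-GWAS meta-analysis scale), $\rho_{LD} = 0.6$, MAF
drawn from (0.05, 0.5). `simulate_ptv_study()` emulates a sequencing study
of rare carriers (binomial 2×2 draws under a per-allele OR, plus a TG
shift of −0.81 mmol/L by default, the magnitude seen for truncating
alleles of these genes). `simulate_metabolite_panel()` emulates the
167-trait metabolomics setting with latent-profile correlation
`concordance_rho`; at the defaults (effect spread 0.25, SEs 0.02), a panel
at $\rho = 0.91$ yields observed $R^2 \approx 0.82$ — the attenuation
arithmetic is $\left(\rho \cdot v/(v + se^2)\right)^2$ with
$v = 0.25^2$.

What the generator does **not** emulate: real allele-frequency spectra,
real LD panels (and hence reference-panel mismatch), sample overlap,
pleiotropy, population stratification, or selection-induced winner's
curse. Passing tests therefore demonstrate the estimators' correctness
under their stated assumptions, not robustness to those violations.

## Problem sizes and numerical choices

Simulation-based checks use 500 replicates for coverage/recovery, 2000 for
type-I error, 200 for each colocalization scenario and the mimicry
distributions, and 1000 random instances for the clumping oracle — sizes
at which Monte-Carlo error is small relative to the tolerances being
asserted while the whole suite runs in about a minute. Ties in clumping
break deterministically (p, then position, then id). Degenerate inputs are
typed outcomes, not crashes: an empty selection is a `"no instruments"`
set, a single-variant colocalization has $PP.H_3 = 0$ exactly, a single
study passes through `meta_fixed()` unchanged, and a single instrument
under random-effects IVW falls back to fixed with a warning.

## A worked example

```{r example}
sim <- simulate_region(sim_config(seed = 7))
h <- harmonize(sim$exposure, sim$outcome)
inst <- select_cis(h, gene_region("GENE", "1", 1008000, 1012000),
                   sim$ld, selection_params())
inst
gls_ivw(inst)
colocalize(sim$exposure, sim$outcome,
           gene_region("GENE", "1", 1008000, 1012000), W2 = 0.2^2)
```

The configured truth here is $\theta = -0.5$ log-OR per s.d. protein; the
GLS-IVW estimate recovers it within its CI, and colocalization identifies
the shared causal variant (H4).

## Limitations

The package analyses summary statistics only; it neither computes LD from
genotypes nor runs variant-effect prediction (annotations are consumed as
input columns). Colocalization assumes at most one causal variant per
trait per region — fine for the single-signal cis windows it is meant for,
wrong for complex loci where conditioning or SuSiE-style methods are
needed. MR-Egger and median-type pleiotropy-robust estimators are out of
scope by design: the cis-instrument framework addresses pleiotropy through
locus restriction and colocalization instead.
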