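#' Configuration for the synthetic cis-region generator
#'
#' Bundles and validates the parameters of [simulate_region()]. Defaults
#' describe a strong cis-pQTL locus read against a large binary-outcome
#' GWAS: per-allele effects on plasma protein abundance of common loss-of-
#' function-like variants are typically several tenths of a standard
#' deviation up to >2 s.d., so the causal effect defaults to 1 s.d. protein
#' per allele; exposure and outcome sample sizes default to the scale of
#' modern pQTL (tens of thousands) and disease (hundreds of thousands)
#' GWAS.
#'
#' @param n_variants Number of variants in the cis window.
#' @param ld_decay AR(1) LD parameter `rho` in `[0, 1)`: `r_ij =
#'   rho^|i-j|`.
#' @param maf_range Range the minor-allele frequencies are drawn from,
#'   within (0, 0.5].
#' @param causal_index Index of the causal variant (1-based), or `"none"`
#'   for a region with no exposure signal.
#' @param beta_protein Causal per-allele effect on the exposure, in s.d.
#'   protein.
#' @param theta Causal effect of the exposure on the outcome (log-OR per
#'   s.d. protein for binary outcomes).
#' @param n_exposure,n_outcome GWAS sample sizes (>= 100).
#' @param case_fraction Case fraction of the binary outcome GWAS.
#' @param outcome_type `"binary"` (log-OR betas) or `"quantitative"`.
#' @param ld_structure `"ar1"` (default) or `"two_block"`: two equal AR(1)
#'   blocks with zero correlation between them, for distinct-signal
#'   colocalization scenarios.
#' @param platform_noise_sd Between-assay s.d. of the discrepancy added to a
#'   second protein-measurement platform (see the `exposure2` output of
#'   [simulate_region()]).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 20L,
                       ld_decay = 0.6,
                       maf_range = c(0.05, 0.5),
                       causal_index = 10L,
                       beta_protein = 1.0,
                       theta = -0.5,
                       n_exposure = 35000L,
                       n_outcome = 300000L,
                       case_fraction = 0.25,
                       outcome_type = c("binary", "quantitative"),
                       ld_structure = c("ar1", "two_block"),
                       platform_noise_sd = 0.05,
                       seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  ld_structure <- match.arg(ld_structure)
  stopifnot(n_variants >= 1,
            ld_decay >= 0, ld_decay < 1,
            length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_exposure >= 100, n_outcome >= 100,
            case_fraction > 0, case_fraction < 1,
            platform_noise_sd >= 0)
  if (!identical(causal_index, "none")) {
    causal_index <- as.integer(causal_index)
    if (is.na(causal_index) || causal_index < 1L || causal_index > n_variants)
      stop("causal_index out of range")
  }
  structure(list(n_variants = as.integer(n_variants), ld_decay = ld_decay,
                 maf_range = maf_range, causal_index = causal_index,
                 beta_protein = beta_protein, theta = theta,
                 n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 case_fraction = case_fraction, outcome_type = outcome_type,
                 ld_structure = ld_structure,
                 platform_noise_sd = platform_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

ar1_ld <- function(m, rho, structure = "ar1") {
  r <- rho ^ abs(outer(seq_len(m), seq_len(m), "-"))
  if (structure == "two_block") {
    half <- ceiling(m / 2)
    block <- c(rep(1L, half), rep(2L, m - half))
    r[outer(block, block, "!=")] <- 0
  }
  r
}

# draw one multivariate-normal vector given a pre-computed upper Cholesky
mvn_draw <- function(mu, chol_upper) {
  mu + drop(crossprod(chol_upper, stats::rnorm(length(mu))))
}

#' Simulate a cis region of GWAS summary statistics with known truth
#'
#' Generates exposure (protein) and outcome summary statistics for
#' `n_variants` in LD, under a single-causal-variant model: the causal
#' variant carries `beta_protein` s.d. protein per allele and every other
#' variant's marginal effect is that effect propagated through LD on the
#' standardized-genotype scale. Outcome marginal effects are `theta` times
#' the true exposure effects (the exclusion-restriction/no-pleiotropy
#' setting), with an optional distinct outcome-only causal variant for
#' colocalization scenarios. Sampling noise is multivariate normal with the
#' LD-induced correlation, i.e. the estimation error of neighbouring
#' variants is correlated exactly as in a real GWAS of one cohort; exposure
#' and outcome draws are independent (two-sample design, no overlap).
#'
#' Marginal standard errors are the standard analytic GWAS approximation
#' `se = sd_trait / sqrt(2 n maf (1 - maf))`, with
#' `sd_trait = 1/sqrt(cf (1 - cf))` on the log-OR scale for a binary
#' outcome with case fraction `cf`.
#'
#' @param config A [sim_config()].
#' @param outcome_causal_index Optional index of a distinct variant with a
#'   direct effect on the outcome only (replaces the mediated signal), for
#'   the "distinct causal variants" colocalization scenario.
#' @param beta_outcome_direct Per-allele direct outcome effect used with
#'   `outcome_causal_index` (default 0.3).
#' @return A list of class `sim_region`:
#'   `exposure`, `exposure2` (a second protein platform with
#'   `platform_noise_sd` discrepancy), `outcome` (record data frames in
#'   [read_sumstats()] layout), `ld` (an [ld_matrix()]), and `truth`
#'   (class `synthetic_truth`: the config plus per-variant true marginal
#'   effects `beta_exposure_true`, `beta_outcome_true`, the mafs and ses).
#' @examples
#' sim <- simulate_region(sim_config(seed = 7))
#' head(sim$exposure[, c("id", "beta", "se", "pvalue")])
#' @export
simulate_region <- function(config, outcome_causal_index = NULL,
                            beta_outcome_direct = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_variants
  ids <- sprintf("rs%04d", seq_len(m))
  pos <- 1000000L + seq_len(m) * 1000L
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  r <- ar1_ld(m, config$ld_decay, config$ld_structure)

  # true marginal effects on the standardized-genotype scale: the causal
  # standardized effect propagates through LD as r to the causal variant
  sd_geno <- sqrt(2 * maf * (1 - maf))
  beta_x_true <- rep(0, m)
  if (!identical(config$causal_index, "none")) {
    ci <- config$causal_index
    beta_std_causal <- config$beta_protein * sd_geno[ci]
    beta_x_true <- r[, ci] * beta_std_causal / sd_geno
  }
  beta_y_true <- config$theta * beta_x_true
  if (!is.null(outcome_causal_index)) {
    oc <- as.integer(outcome_causal_index)
    if (oc < 1L || oc > m) stop("outcome_causal_index out of range")
    beta_y_true <- r[, oc] * (beta_outcome_direct * sd_geno[oc]) / sd_geno
  }

  sd_outcome <- switch(config$outcome_type,
                       binary = 1 / sqrt(config$case_fraction *
                                           (1 - config$case_fraction)),
                       quantitative = 1)
  se_x <- 1 / sqrt(2 * config$n_exposure * maf * (1 - maf))
  se_y <- sd_outcome / sqrt(2 * config$n_outcome * maf * (1 - maf))

  ch <- chol(ld_matrix(ids, r)$r)   # conditioned, hence invertible
  beta_x_hat <- mvn_draw(beta_x_true, ch * rep(se_x, each = m))
  beta_x2_hat <- beta_x_hat + stats::rnorm(m, 0, config$platform_noise_sd)
  beta_y_hat <- mvn_draw(beta_y_true, ch * rep(se_y, each = m))

  mk <- function(beta, se, trait, n, unit, binary = FALSE) {
    df <- data.frame(
      id = ids, chrom = "1", pos = pos,
      effect_allele = "A", other_allele = "G", eaf = maf,
      beta = beta, se = se,
      pvalue = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
      n = n,
      ncase = if (binary) round(n * config$case_fraction) else NA_real_,
      ncontrol = if (binary) round(n * (1 - config$case_fraction)) else NA_real_,
      consequence = "", sift = "", polyphen = "", is_ptv = FALSE,
      unit = unit, trait = trait, stringsAsFactors = FALSE)
    class(df) <- c("dtmr_sumstats", "data.frame")
    df
  }
  truth <- structure(
    list(config = config, maf = maf,
         beta_exposure_true = beta_x_true, beta_outcome_true = beta_y_true,
         se_exposure = se_x, se_outcome = se_y,
         outcome_causal_index = outcome_causal_index),
    class = "synthetic_truth")
  structure(list(
    exposure = mk(beta_x_hat, se_x, "protein", config$n_exposure, "sd_protein"),
    exposure2 = mk(beta_x2_hat, se_x, "protein_platform2", config$n_exposure,
                   "sd_protein"),
    outcome = mk(beta_y_hat, se_y, "outcome", config$n_outcome,
                 if (config$outcome_type == "binary") "log_or" else "sd",
                 binary = config$outcome_type == "binary"),
    ld = ld_matrix(ids, r),
    truth = truth), class = "sim_region")
}

#' Simulate a pair of traits over one region for colocalization scenarios
#'
#' Thin wrapper around [simulate_region()] producing the four canonical
#' colocalization configurations: `"shared"` (one causal variant drives
#' both traits), `"distinct"` (each trait has its own causal variant, in
#' different zero-correlation LD blocks), `"trait1_only"` and `"null"`.
#'
#' @param config A [sim_config()]; for `"distinct"` the `two_block` LD
#'   structure is forced.
#' @param scenario One of `"shared"`, `"distinct"`, `"trait1_only"`,
#'   `"null"`.
#' @return List with `trait1`, `trait2` (record data frames), `ld`, `truth`.
#' @export
simulate_coloc_pair <- function(config,
                                scenario = c("shared", "distinct",
                                             "trait1_only", "null")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config, "sim_config"))
  if (scenario == "distinct") {
    config$ld_structure <- "two_block"
    half <- ceiling(config$n_variants / 2)
    if (config$causal_index == "none" || config$causal_index > half)
      config$causal_index <- max(1L, half %/% 2L)
    oc <- half + max(1L, (config$n_variants - half) %/% 2L)
    sim <- simulate_region(config, outcome_causal_index = oc,
                           beta_outcome_direct = 0.3)
  } else if (scenario == "trait1_only") {
    config$theta <- 0
    sim <- simulate_region(config)
  } else if (scenario == "null") {
    config$causal_index <- "none"
    sim <- simulate_region(config)
  } else {
    sim <- simulate_region(config)
  }
  list(trait1 = sim$exposure, trait2 = sim$outcome, ld = sim$ld,
       truth = sim$truth)
}

#' Simulate a protein-truncating-variant carrier study
#'
#' Emulates a sequencing-based case-control (or cohort) study of rare PTV
#' carriers: a 2x2 carriers/non-carriers by case/control table drawn
#' binomially under a per-allele odds ratio, plus a within-study estimate
#' of the carrier effect on plasma triglycerides. PTV carrier effects on
#' TG of the genes this emulates are large (around -0.8 mmol/L per
#' allele).
#'
#' @param n_carriers Number of PTV carriers (>= 10).
#' @param n_noncarriers Number of non-carriers.
#' @param tg_shift True carrier TG shift in mmol/L (default -0.81).
#' @param or_per_allele True per-allele odds ratio on the binary outcome.
#' @param baseline_risk Outcome risk in non-carriers (default 0.1).
#' @param tg_sd Individual-level TG s.d. in mmol/L (default 1).
#' @param label,ancestry,genotyping Study metadata carried through to the
#'   meta-analysis table (defaults "sim", "European", "sequencing").
#' @param seed Integer seed.
#' @return A one-row data frame of class `ptv_study` with the
#'   meta-analysis columns (`study`, `ancestry`, `genotyping`,
#'   `log_or_per_allele`, `se`, `tg_effect_per_allele`, `tg_se`, `ncase`,
#'   `ncontrol`), the realized 2x2 table in attribute `table`
#'   (rows carrier/non-carrier, columns case/control), and a
#'   `small_cells` flag set when any expected cell count is below 1.
#' @export
simulate_ptv_study <- function(n_carriers, n_noncarriers,
                               tg_shift = -0.81, or_per_allele = 0.6,
                               baseline_risk = 0.1, tg_sd = 1,
                               label = "sim", ancestry = "European",
                               genotyping = "sequencing", seed = 1L) {
  stopifnot(n_carriers >= 10, n_noncarriers >= 10,
            or_per_allele > 0, baseline_risk > 0, baseline_risk < 1)
  set.seed(seed)
  odds0 <- baseline_risk / (1 - baseline_risk)
  odds1 <- odds0 * or_per_allele
  p1 <- odds1 / (1 + odds1)
  expected <- c(n_carriers * p1, n_carriers * (1 - p1),
                n_noncarriers * baseline_risk,
                n_noncarriers * (1 - baseline_risk))
  small_cells <- any(expected < 1)
  if (small_cells)
    warning("expected cell count < 1; study flagged")
  a <- stats::rbinom(1L, n_carriers, p1)
  c_ <- stats::rbinom(1L, n_noncarriers, baseline_risk)
  tab <- matrix(c(a, n_carriers - a, c_, n_noncarriers - c_),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("carrier", "noncarrier"),
                                c("case", "control")))
  est <- carrier_log_or(tab)
  tg_se <- tg_sd * sqrt(1 / n_carriers + 1 / n_noncarriers)
  tg_hat <- stats::rnorm(1L, tg_shift, tg_se)
  out <- data.frame(study = label, ancestry = ancestry,
                    genotyping = genotyping,
                    log_or_per_allele = est[["log_or"]], se = est[["se"]],
                    tg_effect_per_allele = tg_hat, tg_se = tg_se,
                    ncase = a + c_,
                    ncontrol = n_carriers + n_noncarriers - a - c_,
                    stringsAsFactors = FALSE)
  attr(out, "table") <- tab
  attr(out, "small_cells") <- small_cells
  attr(out, "truth") <- list(tg_shift = tg_shift,
                             or_per_allele = or_per_allele,
                             baseline_risk = baseline_risk)
  class(out) <- c("ptv_study", "data.frame")
  out
}

#' Simulate a metabolite panel of paired effect profiles
#'
#' Emulates the genetic-mimicry setting: across a panel of metabolites, the
#' per-trait effects of a common-variant MR model and of a PTV collapsing
#' model share a latent profile with correlation `concordance_rho`;
#' measurement noise is added to both. Defaults describe a large NMR
#' metabolomics panel (167 traits) measured in biobank-scale samples:
#' effect spread 0.25 s.d. per unit exposure and standard errors of 0.02.
#'
#' @param n_traits Panel size (>= 3; default 167).
#' @param concordance_rho Latent correlation between the two effect
#'   profiles, in `[-1, 1]`.
#' @param effect_sd Spread of the true per-trait effects (default 0.25).
#' @param se_cv,se_ptv Measurement s.e. of each vector's entries
#'   (defaults 0.02).
#' @param seed Integer seed.
#' @return Data frame with `trait`, `beta_cv`, `se_cv`, `beta_ptv`,
#'   `se_ptv`, plus attribute `truth`.
#' @export
simulate_metabolite_panel <- function(n_traits = 167L, concordance_rho = 0.91,
                                      effect_sd = 0.25,
                                      se_cv = 0.02, se_ptv = 0.02,
                                      seed = 1L) {
  stopifnot(n_traits >= 3)
  if (abs(concordance_rho) > 1) stop("|concordance_rho| > 1")
  set.seed(seed)
  z1 <- stats::rnorm(n_traits)
  z2 <- concordance_rho * z1 +
    sqrt(1 - concordance_rho^2) * stats::rnorm(n_traits)
  true_cv <- effect_sd * z1
  true_ptv <- effect_sd * z2
  out <- data.frame(
    trait = sprintf("met%03d", seq_len(n_traits)),
    beta_cv = true_cv + stats::rnorm(n_traits, 0, se_cv),
    se_cv = se_cv,
    beta_ptv = true_ptv + stats::rnorm(n_traits, 0, se_ptv),
    se_ptv = se_ptv,
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(concordance_rho = concordance_rho,
                             effect_sd = effect_sd)
  out
}

#' Write a simulated region to disk
#'
#' Emits the exposure/outcome summary-statistic files and the LD matrix in
#' the package's delimited formats, plus a JSON "truth sidecar" holding the
#' generator's hidden parameters for recovery tests. Identical seeds give
#' byte-identical files.
#'
#' @param sim A `sim_region` from [simulate_region()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_region <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_region"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"),
             truth = file.path(dir, "truth.json"))
  write_sumstats(sim$exposure, paths[["exposure"]])
  write_sumstats(sim$outcome, paths[["outcome"]])
  write_ld(sim$ld, paths[["ld"]])
  tr <- sim$truth
  jsonlite::write_json(
    list(config = unclass(tr$config), maf = tr$maf,
         beta_exposure_true = tr$beta_exposure_true,
         beta_outcome_true = tr$beta_outcome_true,
         se_exposure = tr$se_exposure, se_outcome = tr$se_outcome),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
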