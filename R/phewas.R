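#' Bonferroni multiplicity schemes for the analysis families
#'
#' Each analysis family carries its own Bonferroni divisor `m =
#' n_outcomes * n_exposures + extra_models`; p-values are compared against
#' `alpha / m` and confidence intervals widened to the `1 - alpha / m`
#' level. The named schemes encode the families of a three-gene
#' (protein exposures) / four-gene (TG exposures) drug-target study:
#'
#' * `primary_disease`: 5 disease outcomes x (3 protein + 4 TG gene
#'   exposures) + 5 genome-wide TG models = 40;
#' * `risk_factor`: 15 outcomes x 3 genes = 45;
#' * `imaging`: 11 x 3 = 33;
#' * `blood_chemistry`: 43 x 3 = 129;
#' * `phenome_wide`: 694 outcomes x 3 genes = 2082;
#' * `none`: m = 1 (safety-signal scans where missing a true signal is
#'   costlier than a false positive).
#'
#' @param name One of the scheme names above.
#' @return A list of class `multiplicity_scheme` with `name`,
#'   `n_outcomes`, `n_exposures`, `extra_models`, `m`.
#' @examples
#' build_scheme("primary_disease")$m   # 40
#' build_scheme("phenome_wide")$m      # 2082
#' @export
build_scheme <- function(name) {
  spec <- switch(name,
    primary_disease = list(n_outcomes = 5L, n_exposures = 7L,
                           extra_models = 5L),
    risk_factor = list(n_outcomes = 15L, n_exposures = 3L,
                       extra_models = 0L),
    imaging = list(n_outcomes = 11L, n_exposures = 3L, extra_models = 0L),
    blood_chemistry = list(n_outcomes = 43L, n_exposures = 3L,
                           extra_models = 0L),
    phenome_wide = list(n_outcomes = 694L, n_exposures = 3L,
                        extra_models = 0L),
    none = list(n_outcomes = 1L, n_exposures = 1L, extra_models = 0L),
    stop("unknown multiplicity scheme: ", name))
  m <- spec$n_outcomes * spec$n_exposures + spec$extra_models
  structure(c(list(name = name), spec, list(m = m)),
            class = "multiplicity_scheme")
}

#' Phenome-wide single-variant MR scan
#'
#' Runs a Wald-ratio MR of one instrument variant against every outcome in
#' a phenome panel, applying the scheme's Bonferroni threshold
#' `alpha / m`. Outcomes in which the instrument was not measured are
#' reported as not testable (`pvalue` and `pass_threshold` set `NA`)
#' rather than assigned a null p-value — "zero SNPs" is a distinct state
#' from "no association".
#'
#' @param exposure_beta,exposure_se The instrument's effect on the exposure
#'   (e.g. s.d. protein per allele).
#' @param outcomes Data frame with one row per phenotype: columns `code`,
#'   `label`, `cohort`, `beta`, `se` (the instrument's per-allele
#'   association with that phenotype; `NA` beta marks the variant as
#'   absent from that outcome's data).
#' @param scheme A [build_scheme()] result (or scheme name).
#' @param alpha Family-wise error rate before division (default 0.05).
#' @return Data frame of class `phewas_rows` sorted by p-value: `code`,
#'   `label`, `cohort`, `estimate` (log-OR per exposure unit), `se`,
#'   `pvalue`, `pass_threshold`, `m`. Not-testable rows sort last.
#' @export
phewas_scan <- function(exposure_beta, exposure_se, outcomes,
                        scheme = build_scheme("phenome_wide"),
                        alpha = 0.05) {
  if (is.character(scheme)) scheme <- build_scheme(scheme)
  stopifnot(inherits(scheme, "multiplicity_scheme"),
            is.finite(exposure_beta), exposure_beta != 0,
            all(c("code", "beta", "se") %in% names(outcomes)))
  d <- as.data.frame(outcomes)
  testable <- is.finite(d$beta) & is.finite(d$se) & d$se > 0
  est <- ifelse(testable, d$beta / exposure_beta, NA_real_)
  se <- ifelse(testable, d$se / abs(exposure_beta), NA_real_)
  p <- ifelse(testable, 2 * stats::pnorm(-abs(est / se)), NA_real_)
  out <- data.frame(code = d$code,
                    label = d$label %||% d$code,
                    cohort = d$cohort %||% "A",
                    estimate = est, se = se, pvalue = p,
                    pass_threshold = p <= alpha / scheme$m,
                    m = scheme$m,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, method = "radix", na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "scheme") <- scheme$name
  attr(out, "not_testable") <- d$code[!testable]
  class(out) <- c("phewas_rows", "data.frame")
  out
}

#' Fixed-effect meta-analysis of one phenotype across two cohorts
#'
#' Pools the same phenotype's MR estimate from two cohorts by fixed-effect
#' inverse-variance weighting. Both rows must carry the same phenotype
#' code and be on the same scale.
#'
#' @param row_a,row_b Single rows of a [phewas_scan()] result (or any list
#'   with `code`, `estimate`, `se`, `m`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return A one-row data frame in the [phewas_scan()] layout with
#'   `cohort = "meta"`.
#' @export
two_cohort_meta <- function(row_a, row_b, alpha = 0.05) {
  if (row_a$code != row_b$code)
    stop("mismatched phenotype codes: ", row_a$code, " vs ", row_b$code)
  stopifnot(row_a$se > 0, row_b$se > 0)
  w <- c(1 / row_a$se^2, 1 / row_b$se^2)
  est <- (w[1] * row_a$estimate + w[2] * row_b$estimate) / sum(w)
  se <- sqrt(1 / sum(w))
  p <- 2 * stats::pnorm(-abs(est / se))
  m <- row_a$m %||% 1L
  data.frame(code = row_a$code,
             label = row_a$label %||% row_a$code,
             cohort = "meta",
             estimate = est, se = se, pvalue = p,
             pass_threshold = p <= alpha / m, m = m,
             stringsAsFactors = FALSE)
}
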