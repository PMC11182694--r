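#' Genetic-mimicry concordance between two effect profiles
#'
#' Quantifies how well the multi-trait effect profile of a common-variant
#' MR model mimics that of protein-truncating variants in the same gene.
#' The PTV (collapsing) estimates are first divided by `tg_sd_effect` — the
#' PTVs' 1-s.d. effect on plasma triglycerides — to put both profiles on a
#' comparable scale, then the PTV profile is regressed on the
#' common-variant profile by ordinary least squares with intercept, and the
#' concordance is reported as the coefficient of determination
#' `R^2 = 1 - SSres / SStot`.
#'
#' @param cv_effects Numeric vector of per-trait common-variant MR
#'   estimates.
#' @param ptv_effects Numeric vector of per-trait PTV collapsing estimates,
#'   same trait order.
#' @param tg_sd_effect Positive scale factor applied to `ptv_effects`
#'   (default 1 = already scaled).
#' @return A list of class `mimicry_result`: `r2`, `slope`, `intercept`,
#'   `n_traits`, `scale_factor`.
#' @export
mimicry <- function(cv_effects, ptv_effects, tg_sd_effect = 1) {
  stopifnot(length(cv_effects) == length(ptv_effects),
            tg_sd_effect > 0)
  ok <- is.finite(cv_effects) & is.finite(ptv_effects)
  cv <- cv_effects[ok]
  ptv <- ptv_effects[ok] / tg_sd_effect
  n <- length(cv)
  if (n < 3) stop("mimicry needs at least 3 traits")
  if (stats::var(cv) == 0) stop("zero variance in the common-variant vector")
  fit <- stats::lm(ptv ~ cv)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ptv - mean(ptv))^2)
  structure(list(r2 = r2,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_traits = n, scale_factor = tg_sd_effect),
            class = "mimicry_result")
}

#' @export
print.mimicry_result <- function(x, ...) {
  cat(sprintf("Genetic mimicry over %d traits: R2 = %.3f (slope %.3f, intercept %.3f)\n",
              x$n_traits, x$r2, x$slope, x$intercept))
  invisible(x)
}

#' Log odds ratio from a 2x2 carrier table
#'
#' Woolf estimator of the carrier log odds ratio from a 2x2 table of
#' carriers/non-carriers by case/control, with the Haldane-Anscombe
#' correction (0.5 added to every cell) applied when any cell is zero.
#' `se = sqrt(sum(1 / cell))` over the (possibly corrected) cells.
#'
#' @param table 2x2 numeric matrix: rows carrier/non-carrier, columns
#'   case/control. All margins must be positive.
#' @return Named vector `c(log_or, se)`.
#' @examples
#' carrier_log_or(matrix(c(5, 95, 10, 90), 2, byrow = TRUE))
#' @export
carrier_log_or <- function(table) {
  tab <- as.matrix(table)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  if (any(tab == 0)) tab <- tab + 0.5
  c(log_or = log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])),
    se = sqrt(sum(1 / tab)))
}

#' Fixed-effect IVW meta-analysis of PTV studies
#'
#' Pools study-level per-allele log odds ratios by fixed-effect
#' inverse-variance weighting, on either of two scales:
#' * `"per_allele"`: the log-ORs are pooled as reported;
#' * `"per_mmol_tg"`: each study's log-OR and SE are first divided by the
#'   absolute value of that study's per-allele triglyceride effect
#'   (mmol/L), expressing the association per mmol/L TG change. Studies
#'   lacking a within-study TG effect use the pooled IVW TG estimate
#'   across the studies that have one as the denominator.
#'
#' Only sequencing-genotyped studies are retained when
#' `sequencing_only = TRUE` (rare-variant calls from arrays are biased
#' toward the null). Heterogeneity is reported as Cochran's Q with
#' `k - 1` degrees of freedom on the pooled scale, plus the derived
#' `I^2 = max(0, (Q - df) / Q)`.
#'
#' The SE of a per-TG rescaled log-OR ignores the uncertainty of the TG
#' denominator (first-order), the standard approach.
#'
#' @param studies Data frame of study records with columns `study`,
#'   `log_or_per_allele`, `se`, and optionally `tg_effect_per_allele`,
#'   `tg_se`, `genotyping`, `ancestry`, `ncase`, `ncontrol`.
#' @param scale `"per_allele"` or `"per_mmol_tg"`.
#' @param sequencing_only Keep only `genotyping == "sequencing"` rows
#'   (default TRUE when the column is present).
#' @return A list of class `meta_result`: `estimate` (pooled log-OR), `se`,
#'   `pvalue`, `ci_low`, `ci_high`, `scale`, `q_stat`, `q_df`, `q_pvalue`,
#'   `i2`, `n_studies`, `tg_denominator_used` (mmol/L; `NA` on the
#'   per-allele scale) and `per_study` (the rescaled per-study inputs).
#' @export
meta_fixed <- function(studies, scale = c("per_allele", "per_mmol_tg"),
                       sequencing_only = TRUE) {
  scale <- match.arg(scale)
  d <- as.data.frame(studies)
  stopifnot(all(c("log_or_per_allele", "se") %in% names(d)),
            all(d$se > 0))
  if (sequencing_only && "genotyping" %in% names(d))
    d <- d[d$genotyping == "sequencing", , drop = FALSE]
  if (nrow(d) == 0L) stop("no studies left after the sequencing filter")
  tg_denominator <- NA_real_
  est_i <- d$log_or_per_allele
  se_i <- d$se
  if (scale == "per_mmol_tg") {
    has_tg <- "tg_effect_per_allele" %in% names(d) &&
      any(is.finite(d$tg_effect_per_allele))
    if (!has_tg)
      stop("per_mmol_tg scale requires at least one study with a TG effect")
    with_tg <- is.finite(d$tg_effect_per_allele)
    # pooled IVW TG estimate over studies that measured it, used as the
    # denominator for studies that did not
    tg_w <- 1 / d$tg_se[with_tg]^2
    pooled_tg <- sum(d$tg_effect_per_allele[with_tg] * tg_w) / sum(tg_w)
    tg_denominator <- abs(pooled_tg)
    denom <- ifelse(with_tg, abs(d$tg_effect_per_allele), tg_denominator)
    if (any(denom == 0)) stop("zero TG denominator")
    est_i <- est_i / denom
    se_i <- se_i / denom
  }
  w <- 1 / se_i^2
  est <- sum(w * est_i) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (est_i - est)^2)
  k <- nrow(d)
  q_df <- k - 1L
  per_study <- data.frame(study = d$study %||% paste0("study", seq_len(k)),
                          estimate = est_i, se = se_i,
                          weight = w / sum(w), stringsAsFactors = FALSE)
  structure(list(estimate = est, se = se,
                 ci_low = est - stats::qnorm(0.975) * se,
                 ci_high = est + stats::qnorm(0.975) * se,
                 pvalue = 2 * stats::pnorm(-abs(est / se)),
                 scale = scale,
                 q_stat = if (q_df > 0) q else NA_real_,
                 q_df = if (q_df > 0) q_df else NA_real_,
                 q_pvalue = if (q_df > 0)
                   stats::pchisq(q, q_df, lower.tail = FALSE) else NA_real_,
                 i2 = if (q_df > 0 && q > 0) max(0, (q - q_df) / q) else 0,
                 n_studies = k,
                 tg_denominator_used = tg_denominator,
                 per_study = per_study),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effect meta-analysis (%s): log-OR %.4f (OR %.3f), 95%% CI [%.3f, %.3f], p = %.3g\n",
              x$scale, x$estimate, exp(x$estimate), exp(x$ci_low),
              exp(x$ci_high), x$pvalue))
  cat(sprintf("  %d studies; Cochran Q = %.3g on %s df (p = %.3g), I2 = %.0f%%\n",
              x$n_studies, x$q_stat, format(x$q_df), x$q_pvalue, 100 * x$i2))
  if (is.finite(x$tg_denominator_used))
    cat(sprintf("  TG denominator used where missing: %.3f mmol/L\n",
                x$tg_denominator_used))
  invisible(x)
}
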