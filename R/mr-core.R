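new_mr_result <- function(estimate, se, n_snps, method,
                          q_stat = NA_real_, q_df = NA_real_,
                          m = 1L, extra = list()) {
  stopifnot(is.finite(estimate), is.finite(se), se > 0, m >= 1)
  level <- 1 - 0.05 / m
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- estimate / se
  out <- list(estimate = estimate, se = se,
              ci_low = estimate - zq * se, ci_high = estimate + zq * se,
              pvalue = 2 * stats::pnorm(-abs(z)),
              n_snps = as.integer(n_snps), method = method,
              q_stat = q_stat, q_df = q_df,
              q_pvalue = if (is.finite(q_stat) && is.finite(q_df) && q_df > 0)
                stats::pchisq(q_stat, q_df, lower.tail = FALSE) else NA_real_,
              multiplicity_m = as.integer(m))
  structure(c(out, extra), class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat(sprintf("MR (%s): estimate %.*g, se %.*g, %.1f%% CI [%.*g, %.*g], p = %.3g, n_snps = %d\n",
              x$method, digits, x$estimate, digits, x$se,
              100 * (1 - 0.05 / x$multiplicity_m),
              digits, x$ci_low, digits, x$ci_high, x$pvalue, x$n_snps))
  cat(sprintf("  OR scale (if log-OR): %.*g [%.*g, %.*g]\n",
              digits, exp(x$estimate), digits, exp(x$ci_low),
              digits, exp(x$ci_high)))
  if (is.finite(x$q_stat))
    cat(sprintf("  Cochran Q = %.3g on %d df, p = %.3g\n",
                x$q_stat, as.integer(x$q_df), x$q_pvalue))
  if (x$multiplicity_m > 1L)
    cat(sprintf("  Bonferroni divisor m = %d applied to CI and threshold\n",
                x$multiplicity_m))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             or = exp(x$estimate), or_ci_low = exp(x$ci_low),
             or_ci_high = exp(x$ci_high),
             n_snps = x$n_snps, q_stat = x$q_stat, q_df = x$q_df,
             q_pvalue = x$q_pvalue, multiplicity_m = x$multiplicity_m,
             stringsAsFactors = FALSE)
}

#' Wald-ratio causal estimate from a single instrument
#'
#' The single-variant MR estimator: the causal effect of the exposure on
#' the outcome is the ratio of the variant's outcome effect to its exposure
#' effect, `by / bx`, with first-order standard error `sy / |bx|` (the
#' exposure uncertainty `sx` is ignored at first order, which is accurate
#' and conservative for strong instruments; `sx` is accepted so callers
#' document it).
#'
#' @param bx,sx Exposure beta and its standard error.
#' @param by,sy Outcome beta and its standard error.
#' @param m Bonferroni divisor applied to the CI level (default 1).
#' @return An `mr_result`.
#' @examples
#' wald_ratio(bx = -2.19, sx = 0.09, by = -0.86, sy = 0.03)
#' @export
wald_ratio <- function(bx, sx, by, sy, m = 1L) {
  stopifnot(sy > 0)
  if (!is.finite(bx) || bx == 0)
    stop("weak/undefined instrument: exposure beta is zero")
  new_mr_result(estimate = by / bx, se = sy / abs(bx),
                n_snps = 1L, method = "wald_ratio", m = m)
}

extract_xy <- function(instruments) {
  if (inherits(instruments, "instrument_set")) {
    if (instruments$status != "ok")
      stop("no instruments in set")
    d <- instruments$data
  } else d <- as.data.frame(instruments)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!all(need %in% names(d)))
    stop("instruments must carry harmonized exposure and outcome effects (",
         paste(setdiff(need, names(d)), collapse = ", "), " missing)")
  if (any(!is.finite(d$beta_exposure)) || any(d$se_outcome <= 0))
    stop("non-finite betas or non-positive outcome SEs")
  d
}

#' Inverse-variance weighted MR estimate
#'
#' Combines per-variant Wald ratios by inverse-variance weighting,
#' equivalently the slope of the zero-intercept regression of outcome betas
#' on exposure betas weighted by `1/sy^2`:
#' `estimate = sum(bx by / sy^2) / sum(bx^2 / sy^2)`,
#' `se = sqrt(1 / sum(bx^2 / sy^2))`. Instruments are assumed independent
#' (clumped); use [gls_ivw()] when residual LD correlation remains.
#'
#' Heterogeneity is summarized by Cochran's Q over the per-variant ratios.
#' Under `effects_model = "random"` the standard error is inflated by the
#' multiplicative overdispersion factor `max(1, sqrt(Q / (k - 1)))` — the
#' usual convention in two-sample MR, which never shrinks the SE below the
#' fixed-effect value. With a single instrument, "random" falls back to
#' fixed with a warning.
#'
#' @param instruments An `instrument_set` (with outcome columns) or a data
#'   frame with `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`.
#' @param effects_model `"fixed"` or `"random"`.
#' @param m Bonferroni divisor for the CI (default 1).
#' @return An `mr_result` with `q_stat`, `q_df`, `q_pvalue`.
#' @export
ivw <- function(instruments, effects_model = c("fixed", "random"), m = 1L) {
  effects_model <- match.arg(effects_model)
  d <- extract_xy(instruments)
  k <- nrow(d)
  if (k < 1L) stop("no instruments")
  if (k == 1L) {
    if (effects_model == "random") {
      warning("single instrument: random-effects falls back to fixed")
      effects_model <- "fixed"
    }
    res <- wald_ratio(d$beta_exposure, d$se_exposure,
                      d$beta_outcome, d$se_outcome, m = m)
    res$method <- "ivw_fixed"
    return(res)
  }
  w <- d$beta_exposure^2 / d$se_outcome^2
  theta_i <- d$beta_outcome / d$beta_exposure
  est <- sum(w * theta_i) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (theta_i - est)^2)
  q_df <- k - 1L
  if (effects_model == "random")
    se <- se * max(1, sqrt(q / q_df))
  new_mr_result(est, se, k, paste0("ivw_", effects_model),
                q_stat = q, q_df = q_df, m = m)
}

#' GLS-IVW MR estimate for LD-correlated instruments
#'
#' When instruments lie in a single cis region they remain correlated even
#' after clumping, and the plain IVW standard error is anti-conservative.
#' The generalized-least-squares IVW estimator restores valid standard
#' errors by weighting with the LD-induced covariance of the outcome
#' effects: with `X` the exposure betas, `Y` the outcome betas and
#' `Omega[i, j] = sy_i sy_j r_ij`,
#' `estimate = (X' Omega^-1 X)^-1 X' Omega^-1 Y` and
#' `se = sqrt((X' Omega^-1 X)^-1)`. The exposure betas are treated as fixed
#' (outcome-SE-only covariance), the standard correlated-instrument IVW
#' convention. With an identity LD matrix this reduces exactly to
#' fixed-effect [ivw()].
#'
#' @param instruments An `instrument_set` carrying its LD matrix, or a data
#'   frame (then `ld` must be given).
#' @param ld An [ld_matrix()] covering the instruments, if not carried by
#'   `instruments`.
#' @param m Bonferroni divisor for the CI (default 1).
#' @param max_condition Maximum tolerated condition number of `Omega`;
#'   beyond it the estimator refuses and advises stricter clumping
#'   (default 1e8).
#' @return An `mr_result`; the condition number of `Omega` is attached as
#'   `$omega_condition`.
#' @export
gls_ivw <- function(instruments, ld = NULL, m = 1L, max_condition = 1e8) {
  d <- extract_xy(instruments)
  if (is.null(ld) && inherits(instruments, "instrument_set"))
    ld <- instruments$ld
  if (is.null(ld)) stop("gls_ivw requires an LD matrix")
  stopifnot(inherits(ld, "ld_matrix"))
  if (!all(d$id %in% ld$ids))
    stop("LD matrix does not cover all instruments")
  r <- ld$r[d$id, d$id, drop = FALSE]
  omega <- r * tcrossprod(d$se_outcome)
  kappa_o <- kappa(omega, exact = TRUE)
  if (kappa_o > max_condition)
    stop("Omega condition number ", format(kappa_o, digits = 3),
         " exceeds ", format(max_condition, digits = 3),
         "; clump instruments at a stricter r2 threshold")
  x <- d$beta_exposure
  y <- d$beta_outcome
  oi_x <- solve(omega, x)
  info <- drop(crossprod(x, oi_x))
  est <- drop(crossprod(oi_x, y)) / info
  se <- sqrt(1 / info)
  # heterogeneity on the whitened scale: generalized residual sum of squares
  resid <- y - est * x
  q <- drop(crossprod(resid, solve(omega, resid)))
  q_df <- nrow(d) - 1L
  new_mr_result(est, se, nrow(d), "gls_ivw",
                q_stat = if (q_df > 0) q else NA_real_,
                q_df = if (q_df > 0) q_df else NA_real_, m = m,
                extra = list(omega_condition = kappa_o))
}

#' Rescale a log-OR MR result to a different exposure change
#'
#' Translates an estimate expressed per one exposure unit to a different,
#' clinically meaningful exposure change (for example per 0.58 mmol/L
#' triglyceride reduction rather than per 1 mmol/L): estimate, SE and CI
#' bounds are multiplied by `factor` on the log scale, and the odds ratio
#' re-exponentiated. Composable: rescaling by `a` then `b` equals
#' rescaling by `a * b`.
#'
#' @param result An `mr_result` on the log-OR-per-exposure-unit scale.
#' @param factor Positive number of exposure units.
#' @return The rescaled `mr_result`.
#' @examples
#' # OR 0.43 per 1 mmol/L TG, re-expressed per a 0.58 mmol/L reduction:
#' r <- new_mr_result_from(estimate = log(0.43), se = 0.105)
#' exp(rescale_log_or(r, 0.58)$estimate)   # ~0.61
#' @export
rescale_log_or <- function(result, factor) {
  stopifnot(inherits(result, "mr_result"), factor > 0)
  result$estimate <- result$estimate * factor
  result$se <- result$se * factor
  result$ci_low <- result$ci_low * factor
  result$ci_high <- result$ci_high * factor
  result
}

#' Build an `mr_result` from a bare estimate and standard error
#'
#' Utility for wrapping published or externally computed estimates (for
#' example a printed odds ratio with its CI) so they can be passed through
#' [rescale_log_or()] and [orient_to_lowering()].
#'
#' @param estimate,se Point estimate and standard error (log-OR scale for
#'   binary outcomes).
#' @param n_snps Number of variants behind the estimate (default `NA`).
#' @param method Label (default `"external"`).
#' @param m Bonferroni divisor (default 1).
#' @return An `mr_result`.
#' @export
new_mr_result_from <- function(estimate, se, n_snps = NA_integer_,
                               method = "external", m = 1L) {
  new_mr_result(estimate, se, n_snps, method, m = m)
}

#' Report an MR effect per lowered exposure
#'
#' Forest plots of drug-target MR are conventionally reported per standard
#' deviation *lowered* protein (mimicking pharmacological inhibition).
#' With `flip = TRUE` the estimate is negated and the CI bounds swapped.
#'
#' @param result An `mr_result`.
#' @param flip Negate the effect direction (default TRUE).
#' @return The re-oriented `mr_result`.
#' @export
orient_to_lowering <- function(result, flip = TRUE) {
  stopifnot(inherits(result, "mr_result"))
  if (!flip) return(result)
  est <- -result$estimate
  lo <- -result$ci_high
  hi <- -result$ci_low
  result$estimate <- est
  result$ci_low <- lo
  result$ci_high <- hi
  result
}
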