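#' Wakefield approximate Bayes factor (log scale)
#'
#' Closed-form evidence for association of a single variant from its
#' estimated effect and standard error, under a Gaussian effect prior with
#' variance `W`: with `z = beta / se` and shrinkage `K = W / (W + se^2)`,
#' `ABF = sqrt(1 - K) * exp(K z^2 / 2)`. Returned on the log scale for
#' stable summation.
#'
#' @param beta,se Estimated effect and its standard error.
#' @param W Prior variance of the true effect (default `0.15^2`,
#'   the standard choice for quantitative traits; use `0.2^2` on the
#'   log-OR scale for case-control traits).
#' @return log ABF (numeric vector).
#' @export
log_abf <- function(beta, se, W = 0.15^2) {
  stopifnot(all(se > 0))
  z <- beta / se
  K <- W / (W + se^2)
  0.5 * (log1p(-K) + K * z^2)
}

#' Bayesian colocalization of two traits over a gene region
#'
#' Tests whether the association signals of two traits in one region are
#' consistent with a single shared causal variant, under the standard
#' single-causal-variant-per-trait model. Each variant's evidence is its
#' Wakefield log-ABF; the five hypotheses are scored by summing over causal
#' configurations (all sums in log space):
#' * H0: no association with either trait;
#' * H1/H2: association with trait 1 / trait 2 only;
#' * H3: both traits, distinct causal variants;
#' * H4: both traits, one shared causal variant.
#'
#' Posterior probabilities are the prior-weighted configuration sums,
#' normalized to 1.
#'
#' @param trait1,trait2 Record data frames with `id`, `beta`, `se` (and
#'   `chrom`, `pos` when `region` is given). Rows with `se <= 0` are
#'   dropped with a log entry.
#' @param region Optional [gene_region()]; restricts to the window
#'   `[start - coloc_pad, end + coloc_pad]` (default padding 250 kb either
#'   side, a 500 kb region).
#' @param priors Numeric vector `(p1, p2, p12)`: per-variant prior
#'   probabilities of association with trait 1 only, trait 2 only, and
#'   both. Defaults `1e-4, 1e-4, 1e-5` (the field-standard values).
#' @param W1,W2 Prior effect variances for the two traits (defaults
#'   `0.15^2`; use `0.2^2` for a binary trait on the log-OR scale).
#' @return An object of class `coloc_result`: list with `pp` (named
#'   `PP.H0`..`PP.H4`, summing to 1), `argmax` (`"H0"`..`"H4"`),
#'   `n_variants`, `priors`, `h4_weights` (per-variant posterior weight of
#'   being the shared causal variant, given H4) and `log` (dropped rows).
#' @export
colocalize <- function(trait1, trait2, region = NULL,
                       priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                       W1 = 0.15^2, W2 = 0.15^2) {
  stopifnot(length(priors) == 3, all(priors > 0), sum(priors) < 1)
  t1 <- as.data.frame(trait1)
  t2 <- as.data.frame(trait2)
  drop_log <- character(0)
  if (!is.null(region)) {
    lo <- region$start - region$coloc_pad
    hi <- region$end + region$coloc_pad
    in_win <- function(d) !is.na(d$pos) & d$chrom == region$chrom &
      d$pos >= lo & d$pos <= hi
    t1 <- t1[in_win(t1), , drop = FALSE]
    t2 <- t2[in_win(t2), , drop = FALSE]
  }
  bad1 <- !is.finite(t1$se) | t1$se <= 0
  bad2 <- !is.finite(t2$se) | t2$se <= 0
  if (any(bad1)) drop_log <- c(drop_log,
                               paste0("trait1 se<=0: ", t1$id[bad1]))
  if (any(bad2)) drop_log <- c(drop_log,
                               paste0("trait2 se<=0: ", t2$id[bad2]))
  t1 <- t1[!bad1, , drop = FALSE]
  t2 <- t2[!bad2, , drop = FALSE]
  shared <- intersect(t1$id, t2$id)
  if (length(shared) == 0L)
    stop("zero shared variants in the colocalization region")
  t1 <- t1[match(shared, t1$id), ]
  t2 <- t2[match(shared, t2$id), ]

  l1 <- log_abf(t1$beta, t1$se, W1)
  l2 <- log_abf(t2$beta, t2$se, W2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)

  lh <- c(H0 = 0,
          H1 = log(priors[[1]]) + s1,
          H2 = log(priors[[2]]) + s2,
          H3 = log(priors[[1]]) + log(priors[[2]]) + logdiff(s1 + s2, s12),
          H4 = log(priors[[3]]) + s12)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP.", names(lh))
  h4_w <- exp(l1 + l2 - s12)
  structure(list(pp = pp, argmax = names(lh)[which.max(lh)],
                 n_variants = length(shared),
                 priors = c(p1 = priors[[1]], p2 = priors[[2]],
                            p12 = priors[[3]]),
                 h4_weights = stats::setNames(h4_w, shared),
                 log = drop_log),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization over", x$n_variants, "variants: argmax", x$argmax, "\n")
  print(round(x$pp, 4))
  invisible(x)
}
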