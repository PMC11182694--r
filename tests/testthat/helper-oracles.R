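# Shared fixtures and independent oracles for the test suite.

# quick association-record data frame in the read_sumstats() layout
make_records <- function(id, beta, se, pvalue = 2 * pnorm(-abs(beta / se)),
                         pos = seq_along(id) * 1000 + 1e6, chrom = "1",
                         ea = "A", oa = "G", eaf = 0.3, trait = "t",
                         n = 1e5, consequence = "", sift = "",
                         polyphen = "") {
  k <- length(id)
  df <- data.frame(id = id, chrom = chrom, pos = pos,
                   effect_allele = rep_len(ea, k),
                   other_allele = rep_len(oa, k),
                   eaf = rep_len(eaf, k),
                   beta = beta, se = se, pvalue = pvalue,
                   n = n, ncase = NA_real_, ncontrol = NA_real_,
                   consequence = rep_len(consequence, k),
                   sift = rep_len(sift, k),
                   polyphen = rep_len(polyphen, k),
                   is_ptv = FALSE, unit = NA_character_, trait = trait,
                   stringsAsFactors = FALSE)
  class(df) <- c("dtmr_sumstats", "data.frame")
  df
}

write_sumstats_fixture <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Clumping oracle: the greedy p-ordered clump equals the lexicographically
# smallest (by the (p, pos, id) ranking) maximal pairwise-compatible subset.
# Enumerates all 2^k subsets, so only usable for small k.
clump_oracle <- function(ids, pvalue, pos, r2, threshold) {
  k <- length(ids)
  stopifnot(k <= 12)
  rank_key <- order(pvalue, pos, ids)        # rank_key[r] = index with rank r
  rk <- match(seq_len(k), rank_key)          # rk[i] = rank of variant i
  conflict <- r2 >= threshold
  diag(conflict) <- FALSE
  lex_less <- function(a, b) {
    d <- which(a != b)
    length(d) > 0 && a[d[1]] < b[d[1]]
  }
  best <- NULL
  best_key <- NULL
  for (mask in 1:(2^k - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(s) > 1 && any(conflict[s, s])) next
    out <- setdiff(seq_len(k), s)
    if (length(out) > 0 &&
        !all(vapply(out, function(v) any(conflict[v, s]), logical(1))))
      next                                    # not maximal
    key <- c(sort(rk[s]), rep(k + 1, k - length(s)))
    if (is.null(best_key) || lex_less(key, best_key)) {
      best <- s
      best_key <- key
    }
  }
  sort(ids[best])
}

# direct (non-log) colocalization enumeration over causal configurations,
# valid when the Bayes factors are small enough not to overflow
coloc_enum_oracle <- function(b1, s1, b2, s2, p1, p2, p12, W = 0.15^2) {
  abf <- function(b, s) {
    K <- W / (W + s^2)
    sqrt(1 - K) * exp(K * (b / s)^2 / 2)
  }
  a1 <- abf(b1, s1)
  a2 <- abf(b2, s2)
  h0 <- 1
  h1 <- p1 * sum(a1)
  h2 <- p2 * sum(a2)
  h3 <- p1 * p2 * (sum(outer(a1, a2)) - sum(a1 * a2))
  h4 <- p12 * sum(a1 * a2)
  pp <- c(h0, h1, h2, h3, h4)
  pp / sum(pp)
}
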