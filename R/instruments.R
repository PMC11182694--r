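#' Define a target-gene region
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive gene coordinates (`start <= end`).
#' @param cis_pad Padding for cis-instrument selection, in bp
#'   (default 2500: instruments lie within 2.5 kb of the gene).
#' @param coloc_pad Padding for colocalization, in bp (default 250000:
#'   a 500 kb region centred on the gene).
#' @return A list of class `gene_region`.
#' @export
gene_region <- function(gene, chrom, start, end,
                        cis_pad = 2500L, coloc_pad = 250000L) {
  stopifnot(start <= end, cis_pad >= 0, coloc_pad >= 0, start >= 1)
  structure(list(gene = gene, chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 cis_pad = as.numeric(cis_pad),
                 coloc_pad = as.numeric(coloc_pad)),
            class = "gene_region")
}

#' Instrument-selection parameters
#'
#' @param p_threshold Significance threshold on the exposure association
#'   (default 5e-8, genome-wide significance).
#' @param clump_r2 LD-pruning threshold: any candidate with `r^2 >=
#'   clump_r2` to an already-accepted variant is removed (default 0.10,
#'   chosen to avoid GLS multicollinearity).
#' @param clump_window_bp Positional clumping window. `NULL` (default) in
#'   cis mode, where the cis window itself bounds the search; in
#'   genome-wide mode candidates within this distance of an accepted
#'   variant on the same chromosome are removed (default there 500000).
#' @param mode `"cis"` or `"genome_wide"`.
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(p_threshold = 5e-8, clump_r2 = 0.10,
                             clump_window_bp = NULL,
                             mode = c("cis", "genome_wide")) {
  mode <- match.arg(mode)
  stopifnot(p_threshold > 0, p_threshold <= 1,
            clump_r2 > 0, clump_r2 <= 1)
  if (is.null(clump_window_bp) && mode == "genome_wide")
    clump_window_bp <- 500000
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_bp = clump_window_bp, mode = mode),
            class = "selection_params")
}

# greedy p-value-ordered clumping; ties in p break by position then id
clump_greedy <- function(ids, pvalue, pos, chrom, r2_to, params) {
  ord <- order(pvalue, pos, ids)
  accepted <- integer(0)
  dropped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  removed <- rep(FALSE, length(ids))
  for (i in ord) {
    if (removed[i]) next
    accepted <- c(accepted, i)
    for (j in ord) {
      if (removed[j] || j %in% accepted) next
      r2 <- r2_to(i, j)
      if (!is.na(r2) && r2 >= params$clump_r2) {
        removed[j] <- TRUE
        dropped <- rbind(dropped, data.frame(
          id = ids[j],
          reason = sprintf("clumped: r2 = %.4f to %s", r2, ids[i]),
          stringsAsFactors = FALSE))
      } else if (!is.null(params$clump_window_bp) &&
                 !is.na(pos[j]) && !is.na(pos[i]) &&
                 chrom[j] == chrom[i] &&
                 abs(pos[j] - pos[i]) <= params$clump_window_bp &&
                 params$mode == "genome_wide") {
        removed[j] <- TRUE
        dropped <- rbind(dropped, data.frame(
          id = ids[j],
          reason = sprintf("clumped: within %d bp of %s",
                           as.integer(params$clump_window_bp), ids[i]),
          stringsAsFactors = FALSE))
      }
    }
  }
  list(accepted = sort(accepted), dropped = dropped)
}

#' Select cis instruments for a target gene
#'
#' Implements the cis-pQTL instrument-selection rule: keep variants lying
#' within `cis_pad` of the gene body whose exposure p-value reaches
#' `p_threshold`, then greedily LD-clump them — variants are visited in
#' order of ascending p-value; each accepted variant removes all remaining
#' candidates with `r^2 >= clump_r2` to it. Every exclusion is recorded
#' with its reason in the provenance log. In `genome_wide` mode the
#' positional restriction to the gene region is skipped and the clumping
#' window applies between accepted variants.
#'
#' An empty result is not an error: it returns a zero-row instrument set
#' with `status = "no instruments"`, the analogue of a "zero SNPs" row in a
#' results table.
#'
#' @param records Exposure records ([read_sumstats()]) or a harmonized data
#'   frame ([harmonize()]); the latter carries outcome effects into the
#'   instrument set, ready for [ivw()]/[gls_ivw()].
#' @param region A [gene_region()], or `NULL` in genome-wide mode.
#' @param ld An [ld_matrix()] covering the candidate variants. Pairs absent
#'   from the matrix are treated as unlinked.
#' @param params A [selection_params()].
#' @return An object of class `instrument_set`: list with `data` (rows of
#'   the retained variants, including `beta_exposure`, `se_exposure`,
#'   `pvalue_exposure` and, when available, `beta_outcome`, `se_outcome`),
#'   `ld` (restricted to the retained set), `params`, `region`, `status`
#'   (`"ok"` or `"no instruments"`), `exposure_trait` and a `provenance`
#'   data frame listing every dropped variant with its reason.
#' @export
select_cis <- function(records, region = NULL, ld = NULL,
                       params = selection_params()) {
  stopifnot(inherits(params, "selection_params"))
  df <- as.data.frame(records)
  if ("beta_exposure" %in% names(df)) {
    pvals <- df$pvalue_exposure
  } else {
    pvals <- df$pvalue
    names(df)[names(df) == "beta"] <- "beta_exposure"
    names(df)[names(df) == "se"] <- "se_exposure"
    names(df)[names(df) == "pvalue"] <- "pvalue_exposure"
  }
  prov <- data.frame(id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(df))
  if (params$mode == "cis") {
    if (is.null(region)) stop("cis mode requires a gene_region")
    lo <- region$start - region$cis_pad
    hi <- region$end + region$cis_pad
    out_win <- is.na(df$pos) | df$chrom != region$chrom |
      df$pos < lo | df$pos > hi
    prov <- rbind(prov, data.frame(id = df$id[keep & out_win],
                                   reason = rep("outside cis window",
                                                sum(keep & out_win)),
                                   stringsAsFactors = FALSE))
    keep <- keep & !out_win
  }
  weak <- is.na(pvals) | pvals > params$p_threshold
  prov <- rbind(prov, data.frame(id = df$id[keep & weak],
                                 reason = rep(sprintf("p > %g",
                                                      params$p_threshold),
                                              sum(keep & weak)),
                                 stringsAsFactors = FALSE))
  keep <- keep & !weak

  cand <- df[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(structure(list(data = cand, ld = NULL, params = params,
                          region = region, status = "no instruments",
                          exposure_trait = attr(records, "exposure_trait") %||%
                            df$trait[1] %||% NA_character_,
                          provenance = prov),
                     class = "instrument_set"))
  }
  r2_to <- function(i, j) {
    if (is.null(ld)) return(NA_real_)
    a <- cand$id[i]; b <- cand$id[j]
    if (!(a %in% ld$ids) || !(b %in% ld$ids)) return(NA_real_)
    ld$r[a, b]^2
  }
  cl <- clump_greedy(cand$id, cand$pvalue_exposure, cand$pos, cand$chrom,
                     r2_to, params)
  prov <- rbind(prov, cl$dropped)
  sel <- cand[cl$accepted, , drop = FALSE]
  rownames(sel) <- NULL
  ld_sel <- if (!is.null(ld) && all(sel$id %in% ld$ids))
    ld_subset(ld, sel$id) else NULL
  structure(list(data = sel, ld = ld_sel, params = params, region = region,
                 status = "ok",
                 exposure_trait = attr(records, "exposure_trait") %||%
                   sel$trait[1] %||% NA_character_,
                 provenance = prov),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  if (x$status == "no instruments") {
    cat("Instrument set: zero SNPs (no instruments)\n")
  } else {
    cat("Instrument set:", nrow(x$data), "variant(s):",
        paste(x$data$id, collapse = ", "), "\n")
  }
  invisible(x)
}

functional_consequences <- c(
  "5_prime_utr", "3_prime_utr",
  "splice_region", "splice_donor", "splice_acceptor",
  "stop_gained", "frameshift")

#' Filter records to functional variants
#'
#' Sensitivity-analysis instrument filter: restricts to variants with a
#' plausibly functional consequence, at a relaxed significance threshold.
#' Retained are variants with `p <= p_relaxed` that are either (a) missense
#' with a SIFT "deleterious" or PolyPhen "probably/possibly damaging"
#' annotation, or (b) in the 5'/3' UTR, a splice region/donor/acceptor,
#' stop-gained or frameshift. Non-coding variants outside those classes,
#' and missense variants lacking a damaging annotation, are removed.
#'
#' Consequence labels are matched case-insensitively on VEP-style
#' vocabulary (e.g. `"missense_variant"`, `"5_prime_UTR_variant"`,
#' `"splice_donor_variant"`).
#'
#' @param records Record data frame with populated `consequence`, `sift`,
#'   `polyphen` columns.
#' @param p_relaxed Significance threshold (default 0.01).
#' @return The retained rows.
#' @export
filter_functional_variants <- function(records, p_relaxed = 0.01) {
  df <- as.data.frame(records)
  if (!"consequence" %in% names(df) || all(is.na(df$consequence)) ||
      all(df$consequence == ""))
    stop("consequence annotation column absent or empty")
  csq <- tolower(df$consequence)
  sift <- tolower(df$sift %||% "")
  poly <- tolower(df$polyphen %||% "")
  pv <- if ("pvalue" %in% names(df)) df$pvalue else df$pvalue_exposure
  damaging_missense <- grepl("missense", csq) &
    (grepl("deleterious", sift) & !grepl("deleterious_low_confidence", sift) |
       grepl("probably_damaging|possibly_damaging", poly))
  coding_adjacent <- vapply(functional_consequences,
                            function(k) grepl(k, csq, fixed = TRUE),
                            logical(nrow(df)))
  if (is.null(dim(coding_adjacent)))
    coding_adjacent <- matrix(coding_adjacent, nrow = 1)
  keep <- !is.na(pv) & pv <= p_relaxed &
    (damaging_missense | rowSums(coding_adjacent) > 0)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

ptv_consequences <- c("stop_gained", "frameshift", "splice_donor",
                      "splice_acceptor")

#' Flag protein-truncating variants
#'
#' Sets `is_ptv` to `TRUE` for variants whose consequence is stop-gained,
#' frameshift, splice-donor or splice-acceptor and whose effect-allele
#' frequency is below `af_max`.
#'
#' @param records Record data frame with populated `consequence`.
#' @param af_max Allele-frequency ceiling (default 0.05).
#' @return `records` with `is_ptv` recomputed.
#' @export
flag_ptv <- function(records, af_max = 0.05) {
  df <- as.data.frame(records)
  csq <- tolower(df$consequence %||% "")
  truncating <- Reduce(`|`, lapply(ptv_consequences,
                                   function(k) grepl(k, csq, fixed = TRUE)))
  df$is_ptv <- truncating & !is.na(df$eaf) & df$eaf < af_max
  df
}
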