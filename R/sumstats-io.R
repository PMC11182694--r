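#' Read GWAS summary statistics from a delimited text file
#'
#' Parses a tab- or comma-delimited file of per-variant association
#' statistics into a validated data frame of association records. The
#' delimiter is auto-detected from the header line. Rows violating basic
#' invariants (non-numeric or non-positive `se`, p-value outside (0, 1],
#' non-finite `beta`, identical alleles, `eaf` outside [0, 1]) are rejected
#' rather than silently kept; the rejections are returned as a line-numbered
#' report in the `"rejects"` attribute.
#'
#' @param path Path to the summary-statistics file. Mandatory columns:
#'   `id`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`.
#'   Recognised optional columns: `chrom`, `pos`, `eaf`, `n`, `ncase`,
#'   `ncontrol`, `consequence`, `sift`, `polyphen`, `is_ptv`, `unit`.
#' @param trait Trait label attached to every record.
#' @return A data frame of association records (one row per variant) with
#'   alleles upper-cased, a `trait` column, and attribute `rejects`: a data
#'   frame with columns `line` and `reason` (zero rows if all parsed).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("id\teffect_allele\tother_allele\tbeta\tse\tpvalue",
#'              "rs1\ta\tG\t0.1\t0.02\t1e-6"), f)
#' read_sumstats(f, trait = "TG")
#' @export
read_sumstats <- function(path, trait) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = TRUE,
                           stringsAsFactors = FALSE)
  mandatory <- c("id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  n_raw <- nrow(raw)
  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(
    id            = raw$id,
    chrom         = if ("chrom" %in% names(raw)) raw$chrom else NA_character_,
    pos           = if ("pos" %in% names(raw)) num(raw$pos) else NA_real_,
    effect_allele = toupper(raw$effect_allele),
    other_allele  = toupper(raw$other_allele),
    eaf           = if ("eaf" %in% names(raw)) num(raw$eaf) else NA_real_,
    beta          = num(raw$beta),
    se            = num(raw$se),
    pvalue        = num(raw$pvalue),
    n             = if ("n" %in% names(raw)) num(raw$n) else NA_real_,
    ncase         = if ("ncase" %in% names(raw)) num(raw$ncase) else NA_real_,
    ncontrol      = if ("ncontrol" %in% names(raw)) num(raw$ncontrol) else NA_real_,
    consequence   = if ("consequence" %in% names(raw)) raw$consequence else "",
    sift          = if ("sift" %in% names(raw)) raw$sift else "",
    polyphen      = if ("polyphen" %in% names(raw)) raw$polyphen else "",
    is_ptv        = if ("is_ptv" %in% names(raw))
                      as.logical(raw$is_ptv) else FALSE,
    unit          = if ("unit" %in% names(raw)) raw$unit else NA_character_,
    trait         = trait,
    stringsAsFactors = FALSE
  )
  rec$is_ptv[is.na(rec$is_ptv)] <- FALSE

  reason <- rep(NA_character_, n_raw)
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  flag(!is.finite(rec$beta), "non-numeric or non-finite beta")
  flag(!is.finite(rec$se) | rec$se <= 0, "se missing, non-numeric or <= 0")
  flag(!is.finite(rec$pvalue) | rec$pvalue <= 0 | rec$pvalue > 1,
       "pvalue outside (0, 1]")
  flag(rec$effect_allele == rec$other_allele, "effect and other allele identical")
  flag(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1), "eaf outside [0, 1]")
  flag(!is.na(rec$pos) & rec$pos < 1, "pos < 1 (coordinates are 1-based)")
  # multi-allelic / malformed allele strings are rejected, not guessed at
  flag(!grepl("^[ACGT]+$", rec$effect_allele) |
         !grepl("^[ACGT]+$", rec$other_allele),
       "allele not a plain ACGT string (multi-allelic sites are rejected)")

  bad <- !is.na(reason)
  rejects <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                        id = rec$id[bad],
                        reason = reason[bad],
                        stringsAsFactors = FALSE)
  out <- rec[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  class(out) <- c("dtmr_sumstats", "data.frame")
  out
}

#' Write summary statistics to a tab-delimited file
#'
#' Numeric fields are written with 15 significant digits so that
#' `read_sumstats(write_sumstats(x))` round-trips them to at least 12
#' significant digits.
#'
#' @param records Data frame as returned by [read_sumstats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  cols <- c("id", "chrom", "pos", "effect_allele", "other_allele", "eaf",
            "beta", "se", "pvalue", "n", "ncase", "ncontrol",
            "consequence", "sift", "polyphen", "is_ptv")
  df <- as.data.frame(records)[, intersect(cols, names(records)), drop = FALSE]
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- formatC(df[[nm]], digits = 15,
                                                  format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a validated LD matrix
#'
#' Stores the signed pairwise correlation `r` between variants (the square
#' `r^2` is derived where clumping needs it). Validation enforces symmetry,
#' `|r| <= 1`, and a unit diagonal. Because downstream GLS needs an
#' invertible covariance, matrices that are not positive semi-definite are
#' conditioned by clipping eigenvalues at a small floor and re-normalizing
#' the diagonal to exactly 1.
#'
#' @param ids Character vector of variant ids (column order of `r`).
#' @param r Square numeric matrix of signed correlations.
#' @param condition Apply eigenvalue-clipping PSD conditioning (default TRUE).
#' @param tol Asymmetry / bound tolerance on input (default 1e-8).
#' @return An object of class `ld_matrix`: list with `ids` and `r`.
#' @export
ld_matrix <- function(ids, r, condition = TRUE, tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (length(ids) != nrow(r)) stop("ids length must match matrix dimension")
  if (anyDuplicated(ids)) stop("duplicate variant ids in LD matrix")
  if (any(!is.finite(r))) stop("LD matrix contains NaN or non-finite cells")
  if (max(abs(r - t(r))) > tol) stop("LD matrix asymmetric beyond tolerance")
  if (max(abs(r)) > 1 + tol) stop("LD |r| exceeds 1")
  if (max(abs(diag(r) - 1)) > tol) stop("LD diagonal must be 1")
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  if (condition) {
    ev <- eigen(r, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      vals <- pmax(ev$values, 1e-8)
      r <- ev$vectors %*% (vals * t(ev$vectors))
      # clipping perturbs the diagonal; rescale back to a correlation matrix
      d <- sqrt(diag(r))
      r <- r / tcrossprod(d)
      diag(r) <- 1
    }
  }
  dimnames(r) <- list(ids, ids)
  structure(list(ids = as.character(ids), r = r), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("LD matrix:", length(x$ids), "variants; mean |r| (off-diagonal) =",
      format(mean(abs(x$r[upper.tri(x$r)])), digits = 3), "\n")
  invisible(x)
}

#' Subset an LD matrix to a set of variant ids
#' @param ld An `ld_matrix`.
#' @param ids Ids to keep (order preserved as given).
#' @return An `ld_matrix` over `ids`.
#' @export
ld_subset <- function(ld, ids) {
  stopifnot(inherits(ld, "ld_matrix"))
  missing_ids <- setdiff(ids, ld$ids)
  if (length(missing_ids) > 0L)
    stop("ids absent from LD matrix: ", paste(missing_ids, collapse = ", "))
  ld_matrix(ids, ld$r[ids, ids, drop = FALSE], condition = FALSE)
}

#' Read an LD matrix from delimited text
#'
#' Expects a square numeric matrix whose first row and first column hold the
#' variant ids. Asymmetry beyond 1e-8, `|r| > 1 + 1e-8`, NaN cells or a
#' non-square body are hard errors. The matrix is PSD-conditioned on read
#' (see [ld_matrix()]).
#'
#' @param path Path to the LD file (tab- or comma-delimited).
#' @return An `ld_matrix`.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           quote = "", comment.char = "", check.names = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("LD matrix body must be numeric")
  if (nrow(m) != ncol(m)) stop("LD matrix must be square")
  if (!identical(rownames(m), colnames(m)))
    stop("LD row and column ids disagree")
  ld_matrix(colnames(m), m)
}

#' Write an LD matrix to tab-delimited text
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  m <- formatC(ld$r, digits = 15, format = "g")
  df <- data.frame(id = ld$ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", ld$ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effects to the exposure's effect-allele orientation,
#' the standard preliminary to two-sample MR. For each variant shared
#' between the two sets:
#' * same allele pair, same orientation: kept as is;
#' * alleles swapped (outcome effect allele = exposure other allele): the
#'   outcome beta is negated and its eaf complemented;
#' * palindromic variants (A/T or C/G) whose exposure or outcome eaf lies
#'   within `palindrome_eaf_window` of 0.5 are dropped (strand cannot be
#'   resolved from frequency);
#' * incompatible allele pairs are dropped.
#'
#' @param exposure,outcome Record data frames (see [read_sumstats()]).
#' @param palindrome_eaf_window Half-width `w` of the ambiguity window:
#'   palindromic variants with eaf in `[0.5 - w, 0.5 + w]` are dropped.
#'   Default 0.08.
#' @return A data frame with one row per retained variant: variant columns
#'   from the exposure plus `beta_exposure`, `se_exposure`,
#'   `pvalue_exposure`, `n_exposure`, `beta_outcome`, `se_outcome`,
#'   `pvalue_outcome`, `n_outcome`, `eaf_outcome`. Attribute `log` is a data
#'   frame recording the action taken for every shared variant.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(palindrome_eaf_window >= 0, palindrome_eaf_window < 0.5)
  shared <- intersect(exposure$id, outcome$id)
  if (length(shared) == 0L)
    stop("no shared variants between exposure and outcome")
  ex <- exposure[match(shared, exposure$id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$id), , drop = FALSE]

  action <- character(length(shared))
  beta_o <- ou$beta
  eaf_o <- ou$eaf
  same <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swap <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  action[same] <- "kept"
  action[swap] <- "flipped"
  beta_o[swap] <- -beta_o[swap]
  eaf_o[swap] <- 1 - eaf_o[swap]
  action[!same & !swap] <- "dropped: incompatible alleles"

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  w <- palindrome_eaf_window
  ambiguous <- function(f) !is.na(f) & f >= 0.5 - w & f <= 0.5 + w
  # a palindromic variant with no eaf at all is unresolvable too
  amb <- pal & (ambiguous(ex$eaf) | ambiguous(eaf_o) |
                  (is.na(ex$eaf) & is.na(eaf_o)))
  action[(same | swap) & amb] <- "dropped: palindromic, ambiguous eaf"

  keep <- action %in% c("kept", "flipped")
  out <- data.frame(
    id = ex$id[keep], chrom = ex$chrom[keep], pos = ex$pos[keep],
    effect_allele = ex$effect_allele[keep], other_allele = ex$other_allele[keep],
    eaf = ex$eaf[keep],
    consequence = ex$consequence[keep], sift = ex$sift[keep],
    polyphen = ex$polyphen[keep], is_ptv = ex$is_ptv[keep],
    beta_exposure = ex$beta[keep], se_exposure = ex$se[keep],
    pvalue_exposure = ex$pvalue[keep], n_exposure = ex$n[keep],
    beta_outcome = beta_o[keep], se_outcome = ou$se[keep],
    pvalue_outcome = ou$pvalue[keep], n_outcome = ou$n[keep],
    eaf_outcome = eaf_o[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "log") <- data.frame(id = shared, action = action,
                                 stringsAsFactors = FALSE)
  attr(out, "exposure_trait") <- ex$trait[1]
  attr(out, "outcome_trait") <- ou$trait[1]
  class(out) <- c("dtmr_harmonized", "data.frame")
  out
}
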