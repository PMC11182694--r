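#' Default pipeline configuration
#'
#' Returns the example configuration the pipeline runs with when no config
#' is supplied: a three-gene drug-target study shape (plus positive-control
#' genes), synthetic inputs, default selection parameters and
#' colocalization priors, and the per-family multiplicity schemes.
#'
#' @param seed Master seed; each stage derives its own sub-seed from it.
#' @return A nested list (class `run_config`) accepted by
#'   [run_pipeline()]. The same structure can be written to / read from a
#'   YAML file.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    steps = c(1L, 2L, 3L, 4L),
    seed = as.integer(seed),
    genes = list(
      ANGPTL3 = list(chrom = "1", start = 1010000, end = 1014000,
                     theta = 0.0, beta_protein = 0.5),
      ANGPTL4 = list(chrom = "1", start = 1010000, end = 1014000,
                     theta = -0.5, beta_protein = 1.0),
      APOC3  = list(chrom = "1", start = 1010000, end = 1014000,
                    theta = -0.3, beta_protein = 1.0)),
    simulation = list(n_variants = 20L, ld_decay = 0.6,
                      maf_range = c(0.05, 0.5), causal_index = 10L,
                      n_exposure = 35000L, n_outcome = 300000L,
                      case_fraction = 0.25),
    selection = list(p_threshold = 5e-8, clump_r2 = 0.10),
    coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                 W1 = 0.15^2, W2 = 0.2^2),
    phewas = list(n_outcomes = 30L, scheme = "phenome_wide"),
    mimicry = list(n_traits = 167L, concordance_rho = 0.91),
    ptv_meta = list(n_studies = 4L, or_per_allele = 0.6,
                    tg_shift = -0.81, n_carriers = 400L,
                    n_noncarriers = 60000L)),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML file with the [default_config()] structure;
#'   missing entries fall back to the defaults.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), usr)
  cfg$steps <- as.integer(cfg$steps)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

stage_seed <- function(cfg, offset) (cfg$seed * 1000L + offset) %% .Machine$integer.max

write_report <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_gene_mr <- function(gene, gcfg, cfg, seed) {
  sim_cfg <- sim_config(
    n_variants = cfg$simulation$n_variants,
    ld_decay = cfg$simulation$ld_decay,
    maf_range = cfg$simulation$maf_range,
    causal_index = cfg$simulation$causal_index,
    beta_protein = gcfg$beta_protein, theta = gcfg$theta,
    n_exposure = cfg$simulation$n_exposure,
    n_outcome = cfg$simulation$n_outcome,
    case_fraction = cfg$simulation$case_fraction,
    seed = seed)
  sim <- simulate_region(sim_cfg)
  region <- gene_region(gene, gcfg$chrom, gcfg$start, gcfg$end)
  h <- harmonize(sim$exposure, sim$outcome)
  params <- selection_params(p_threshold = cfg$selection$p_threshold,
                             clump_r2 = cfg$selection$clump_r2)
  inst <- select_cis(h, region, sim$ld, params)
  list(sim = sim, region = region, instruments = inst)
}

#' Run the four-step drug-target MR study end to end
#'
#' Orchestrates the full analysis on synthetic inputs with known truth
#' (or on user data once the per-module functions are called directly):
#'
#' 1. **Step 1-2** — per gene: simulate a cis region, select instruments,
#'    estimate the causal effect by GLS-IVW (with plain IVW alongside),
#'    colocalize exposure and outcome over the region, and run a
#'    phenome-wide Wald-ratio scan of the lead instrument.
#' 2. **Step 3** — genetic-mimicry concordance on a simulated metabolite
#'    panel, and a functional-variant sensitivity MR (per-variant Wald
#'    ratios pooled by random-effects IVW).
#' 3. **Step 4** — PTV meta-analysis: simulated sequencing studies pooled
#'    per allele and per mmol/L TG, with Cochran Q.
#'
#' Per-step tab-delimited report tables, a machine-readable
#' `results.json` and a run log (seeds, stage timings) are written to
#' `out_dir`. Identical config and seed give identical bundles.
#'
#' @param config A `run_config` (see [default_config()]), or the path to a
#'   YAML file, or `NULL` for the defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-step result objects and the
#'   paths of the files written.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("dtmr_run_")) {
  cfg <- if (is.null(config)) default_config()
  else if (is.character(config)) read_config(config)
  else config
  stopifnot(inherits(cfg, "run_config"),
            all(cfg$steps %in% 1:4))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  stage_log <- function(stage, seed, t0) {
    log_lines <<- c(log_lines, sprintf(
      "%s seed=%d elapsed=%.2fs", stage, seed,
      as.numeric(proc.time()[3] - t0)))
  }
  results <- list()
  paths <- character(0)

  if (any(cfg$steps %in% c(1L, 2L))) {
    mr_rows <- list()
    coloc_rows <- list()
    phewas_tabs <- list()
    for (i in seq_along(cfg$genes)) {
      gene <- names(cfg$genes)[i]
      t0 <- proc.time()[3]
      seed <- stage_seed(cfg, i)
      gm <- run_gene_mr(gene, cfg$genes[[i]], cfg, seed)
      if (gm$instruments$status == "ok") {
        gls <- gls_ivw(gm$instruments)
        fe <- ivw(gm$instruments, "fixed")
        mr_rows[[gene]] <- cbind(gene = gene, estimator = "gls_ivw",
                                 as.data.frame(gls))
        mr_rows[[paste0(gene, "_ivw")]] <-
          cbind(gene = gene, estimator = "ivw_fixed", as.data.frame(fe))
      } else {
        mr_rows[[gene]] <- data.frame(gene = gene, estimator = "gls_ivw",
                                      method = "gls_ivw", estimate = NA_real_,
                                      se = NA_real_, ci_low = NA_real_,
                                      ci_high = NA_real_, pvalue = NA_real_,
                                      or = NA_real_, or_ci_low = NA_real_,
                                      or_ci_high = NA_real_, n_snps = 0L,
                                      q_stat = NA_real_, q_df = NA_real_,
                                      q_pvalue = NA_real_,
                                      multiplicity_m = 1L,
                                      stringsAsFactors = FALSE)
      }
      cl <- colocalize(gm$sim$exposure, gm$sim$outcome, gm$region,
                       priors = c(cfg$coloc$p1, cfg$coloc$p2, cfg$coloc$p12),
                       W1 = cfg$coloc$W1, W2 = cfg$coloc$W2)
      coloc_rows[[gene]] <- data.frame(
        gene = gene, n_variants = cl$n_variants,
        t(cl$pp), argmax = cl$argmax, stringsAsFactors = FALSE)

      # phenome scan of the lead instrument against a simulated phenome:
      # null outcomes plus the simulated disease outcome itself
      if (gm$instruments$status == "ok" && 2L %in% cfg$steps) {
        lead <- gm$instruments$data[which.min(gm$instruments$data$pvalue_exposure), ]
        set.seed(stage_seed(cfg, 100L + i))
        n_out <- cfg$phewas$n_outcomes
        null_se <- 0.02
        outcomes <- data.frame(
          code = sprintf("PHENO%03d", seq_len(n_out)),
          label = sprintf("synthetic endpoint %d", seq_len(n_out)),
          cohort = "A",
          beta = c(lead$beta_outcome,
                   stats::rnorm(n_out - 1L, 0, null_se)),
          se = c(lead$se_outcome, rep(null_se, n_out - 1L)),
          stringsAsFactors = FALSE)
        phewas_tabs[[gene]] <- cbind(
          gene = gene,
          phewas_scan(lead$beta_exposure, lead$se_exposure, outcomes,
                      scheme = build_scheme(cfg$phewas$scheme)))
      }
      stage_log(paste0("step1-2:", gene), seed, t0)
    }
    results$mr <- do.call(rbind, mr_rows)
    results$coloc <- do.call(rbind, coloc_rows)
    paths <- c(paths, write_report(results$mr, out_dir, "step1_mr"),
               write_report(results$coloc, out_dir, "step2_coloc"))
    if (length(phewas_tabs) > 0) {
      results$phewas <- do.call(rbind, phewas_tabs)
      paths <- c(paths, write_report(results$phewas, out_dir, "step2_phewas"))
    }
  }

  if (3L %in% cfg$steps) {
    t0 <- proc.time()[3]
    seed <- stage_seed(cfg, 300L)
    mim_rows <- lapply(seq_along(cfg$genes), function(i) {
      panel <- simulate_metabolite_panel(
        n_traits = cfg$mimicry$n_traits,
        concordance_rho = cfg$mimicry$concordance_rho,
        seed = stage_seed(cfg, 300L + i))
      mi <- mimicry(panel$beta_cv, panel$beta_ptv)
      data.frame(gene = names(cfg$genes)[i], r2 = mi$r2, slope = mi$slope,
                 intercept = mi$intercept, n_traits = mi$n_traits,
                 stringsAsFactors = FALSE)
    })
    results$mimicry <- do.call(rbind, mim_rows)
    paths <- c(paths, write_report(results$mimicry, out_dir, "step3_mimicry"))
    stage_log("step3:mimicry", seed, t0)
  }

  if (4L %in% cfg$steps) {
    t0 <- proc.time()[3]
    seed <- stage_seed(cfg, 400L)
    pcfg <- cfg$ptv_meta
    studies <- do.call(rbind, lapply(seq_len(pcfg$n_studies), function(j) {
      simulate_ptv_study(n_carriers = pcfg$n_carriers,
                         n_noncarriers = pcfg$n_noncarriers,
                         tg_shift = pcfg$tg_shift,
                         or_per_allele = pcfg$or_per_allele,
                         label = sprintf("study%02d", j),
                         seed = stage_seed(cfg, 400L + j))
    }))
    meta_allele <- meta_fixed(studies, "per_allele")
    meta_tg <- meta_fixed(studies, "per_mmol_tg")
    results$ptv_meta <- data.frame(
      scale = c("per_allele", "per_mmol_tg"),
      log_or = c(meta_allele$estimate, meta_tg$estimate),
      or = exp(c(meta_allele$estimate, meta_tg$estimate)),
      se = c(meta_allele$se, meta_tg$se),
      ci_low = exp(c(meta_allele$ci_low, meta_tg$ci_low)),
      ci_high = exp(c(meta_allele$ci_high, meta_tg$ci_high)),
      pvalue = c(meta_allele$pvalue, meta_tg$pvalue),
      q_stat = c(meta_allele$q_stat, meta_tg$q_stat),
      q_pvalue = c(meta_allele$q_pvalue, meta_tg$q_pvalue),
      n_studies = c(meta_allele$n_studies, meta_tg$n_studies),
      stringsAsFactors = FALSE)
    results$ptv_studies <- studies
    paths <- c(paths, write_report(results$ptv_meta, out_dir, "step4_ptv_meta"),
               write_report(studies, out_dir, "step4_ptv_studies"))
    stage_log("step4:ptv_meta", seed, t0)
  }

  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(
    lapply(results, function(x) if (is.data.frame(x)) x else x),
    json_path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(c(sprintf("dtmr run seed=%d steps=%s", cfg$seed,
                       paste(cfg$steps, collapse = ",")), log_lines),
             file.path(out_dir, "run_log.txt"))
  paths <- c(paths, json_path)
  invisible(list(results = results, config = cfg, paths = paths,
                 out_dir = out_dir))
}
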