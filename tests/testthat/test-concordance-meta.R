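test_that("proportional effect profiles give R2 = 1 with zero intercept", {
  cv <- c(0.1, -0.2, 0.3, 0.05, -0.4)
  res <- mimicry(cv, 2 * cv)
  expect_equal(res$r2, 1, tolerance = 1e-12)
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  expect_equal(res$slope, 2, tolerance = 1e-12)
})

test_that("the TG scale factor divides the collapsing estimates", {
  cv <- c(0.1, -0.2, 0.3)
  res <- mimicry(cv, 4 * cv, tg_sd_effect = 2)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$scale_factor, 2)
})

test_that("mimicry R2 is invariant to a common positive rescaling", {
  set.seed(19)
  cv <- rnorm(30)
  ptv <- 0.8 * cv + rnorm(30, 0, 0.3)
  expect_equal(mimicry(cv, ptv)$r2, mimicry(7 * cv, 7 * ptv)$r2,
               tolerance = 1e-12)
})

test_that("degenerate mimicry inputs are rejected", {
  expect_error(mimicry(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(mimicry(c(1, 2), c(1, 2)), "at least 3")
})

test_that("panels at high latent concordance land near the published R2 range", {
  r2s <- vapply(1:100, function(s) {
    p <- simulate_metabolite_panel(167, concordance_rho = 0.91,
                                   seed = 7000 + s)
    mimicry(p$beta_cv, p$beta_ptv)$r2
  }, numeric(1))
  expect_gt(median(r2s), 0.78)
  expect_lt(median(r2s), 0.88)
})

test_that("the Woolf 2x2 estimator matches closed forms", {
  sym <- carrier_log_or(matrix(c(10, 90, 10, 90), 2, byrow = TRUE))
  expect_equal(unname(sym["log_or"]), 0)
  expect_equal(unname(sym["se"]), sqrt(2 * (1 / 10 + 1 / 90)))
  asym <- carrier_log_or(matrix(c(5, 95, 10, 90), 2, byrow = TRUE))
  expect_equal(unname(exp(asym["log_or"])), (5 * 90) / (95 * 10),
               tolerance = 1e-12)
  expect_error(carrier_log_or(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

test_that("zero cells use Haldane-Anscombe and stay close to the exact conditional estimate", {
  tab <- matrix(c(0, 20, 8, 12), 2, byrow = TRUE)
  est <- carrier_log_or(tab)
  expect_true(is.finite(est["log_or"]))
  expect_lt(unname(est["log_or"]), 0)
  # exact conditional MLE from the hypergeometric enumeration is 0 here,
  # i.e. log-OR -> -Inf: the corrected estimate must agree in sign
  fish <- fisher.test(tab)
  expect_lt(log(fish$estimate), 0)
  # on tiny tables without zeros the Woolf estimate tracks the exact
  # conditional MLE within a bounded gap
  for (tab2 in list(matrix(c(2, 8, 6, 4), 2, byrow = TRUE),
                    matrix(c(3, 17, 9, 11), 2, byrow = TRUE))) {
    woolf <- unname(carrier_log_or(tab2)["log_or"])
    cond <- unname(log(fisher.test(tab2)$estimate))
    expect_equal(sign(woolf), sign(cond))
    expect_lt(abs(woolf - cond), 0.5)
  }
})

test_that("identical studies pool to the common estimate with se/sqrt(k)", {
  studies <- data.frame(study = c("s1", "s2"),
                        log_or_per_allele = c(-0.5, -0.5),
                        se = c(0.1, 0.1), genotyping = "sequencing")
  res <- meta_fixed(studies, "per_allele")
  expect_equal(res$estimate, -0.5)
  expect_equal(res$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(res$q_stat, 0)
  k <- 5
  studies_k <- data.frame(study = paste0("s", 1:k),
                          log_or_per_allele = rep(-0.5, k),
                          se = rep(0.1, k), genotyping = "sequencing")
  expect_equal(meta_fixed(studies_k)$se, 0.1 / sqrt(k), tolerance = 1e-12)
})

test_that("a single study passes through unchanged on the per-allele scale", {
  s <- data.frame(study = "s1", log_or_per_allele = -0.44, se = 0.21,
                  genotyping = "sequencing")
  res <- meta_fixed(s)
  expect_equal(res$estimate, -0.44)
  expect_equal(res$se, 0.21)
  expect_equal(res$n_studies, 1L)
})

test_that("per-TG rescaling follows the log-linear rule", {
  # OR 0.64 per allele with a -0.5 mmol/L TG effect: per-TG OR = 0.64^(1/0.5)
  s <- data.frame(study = "s1", log_or_per_allele = log(0.64), se = 0.1,
                  tg_effect_per_allele = -0.5, tg_se = 0.05,
                  genotyping = "sequencing")
  res <- meta_fixed(s, "per_mmol_tg")
  expect_equal(exp(res$estimate), 0.64^(1 / 0.5), tolerance = 1e-12)
  expect_equal(exp(res$estimate), 0.4096, tolerance = 1e-10)
})

test_that("per-allele and per-TG pooled estimates satisfy the denominator identity", {
  studies <- data.frame(study = c("s1", "s2", "s3"),
                        log_or_per_allele = c(-0.5, -0.4, -0.6),
                        se = c(0.1, 0.15, 0.2),
                        tg_effect_per_allele = rep(-0.7, 3),
                        tg_se = rep(0.05, 3),
                        genotyping = "sequencing")
  pa <- meta_fixed(studies, "per_allele")
  pt <- meta_fixed(studies, "per_mmol_tg")
  expect_equal(pa$estimate, pt$estimate * pt$tg_denominator_used,
               tolerance = 1e-10)
})

test_that("studies lacking a TG effect use the pooled TG denominator", {
  studies <- data.frame(study = c("s1", "s2"),
                        log_or_per_allele = c(-0.5, -0.5),
                        se = c(0.1, 0.1),
                        tg_effect_per_allele = c(-0.8, NA),
                        tg_se = c(0.05, NA),
                        genotyping = "sequencing")
  res <- meta_fixed(studies, "per_mmol_tg")
  expect_equal(res$tg_denominator_used, 0.8)
  expect_equal(res$estimate, -0.5 / 0.8, tolerance = 1e-12)
  no_tg <- data.frame(study = "s1", log_or_per_allele = -0.5, se = 0.1,
                      genotyping = "sequencing")
  expect_error(meta_fixed(no_tg, "per_mmol_tg"), "TG")
})

test_that("array-genotyped studies are excluded before pooling", {
  studies <- data.frame(study = c("seq1", "arr1"),
                        log_or_per_allele = c(-0.5, 5),
                        se = c(0.1, 0.1),
                        genotyping = c("sequencing", "array"))
  res <- meta_fixed(studies)
  expect_equal(res$n_studies, 1L)
  expect_equal(res$estimate, -0.5)
})

test_that("pooling and Q agree with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  set.seed(23)
  yi <- rnorm(6, -0.4, 0.2)
  sei <- runif(6, 0.05, 0.3)
  studies <- data.frame(study = paste0("s", 1:6), log_or_per_allele = yi,
                        se = sei, genotyping = "sequencing")
  ours <- meta_fixed(studies)
  ref <- metafor::rma(yi = yi, sei = sei, method = "FE")
  expect_equal(ours$estimate, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$se, ref$se, tolerance = 1e-10)
  expect_equal(ours$q_stat, ref$QE, tolerance = 1e-10)
})
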