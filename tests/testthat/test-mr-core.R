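test_that("the Wald ratio is by/bx with first-order SE sy/|bx|", {
  r <- wald_ratio(bx = -0.5, sx = 0.05, by = -0.2, sy = 0.05)
  expect_equal(r$estimate, 0.4)
  expect_equal(r$se, 0.1)
  expect_equal(r$n_snps, 1L)
  expect_error(wald_ratio(0, 0.1, 0.2, 0.1), "weak")
})

test_that("the splice-donor instrument's TG-per-s.d.-protein ratio matches the published effects", {
  # protein -2.19 s.d./allele, TG -0.86 mmol/L/allele => 0.3927 mmol/L TG
  # per s.d. protein
  r <- wald_ratio(bx = -2.19, sx = 0.088, by = -0.86, sy = 0.032)
  expect_equal(r$estimate, 0.86 / 2.19, tolerance = 1e-12)
  expect_equal(round(r$estimate, 4), 0.3927)
})

test_that("a zero outcome effect gives a null estimate with p = 1", {
  r <- wald_ratio(bx = 0.5, sx = 0.05, by = 0, sy = 0.1)
  expect_equal(r$estimate, 0)
  expect_equal(r$pvalue, 1)
})

test_that("IVW with one instrument equals the Wald ratio", {
  d <- data.frame(beta_exposure = -0.5, se_exposure = 0.05,
                  beta_outcome = -0.2, se_outcome = 0.05)
  expect_equal(ivw(d)$estimate, wald_ratio(-0.5, 0.05, -0.2, 0.05)$estimate,
               tolerance = 1e-12)
  expect_equal(ivw(d)$se, wald_ratio(-0.5, 0.05, -0.2, 0.05)$se,
               tolerance = 1e-12)
  expect_warning(ivw(d, "random"), "falls back")
})

test_that("identical ratios with equal weights give that ratio and Q = 0", {
  d <- data.frame(beta_exposure = c(0.5, 0.5), se_exposure = 0.05,
                  beta_outcome = c(0.25, 0.25), se_outcome = 0.1)
  r <- ivw(d)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$q_stat, 0)
  expect_equal(r$q_df, 1L)
})

test_that("IVW equals the zero-intercept weighted-least-squares oracle", {
  set.seed(101)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    d <- data.frame(beta_exposure = rnorm(k, 0, 0.5),
                    se_exposure = runif(k, 0.01, 0.1),
                    beta_outcome = rnorm(k, 0, 0.3),
                    se_outcome = runif(k, 0.01, 0.2))
    fit <- lm(beta_outcome ~ 0 + beta_exposure, data = d,
              weights = 1 / d$se_outcome^2)
    expect_equal(ivw(d)$estimate, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("random-effects SE is fixed SE inflated by max(1, sqrt(Q/df))", {
  set.seed(5)
  d <- data.frame(beta_exposure = runif(6, 0.2, 1),
                  se_exposure = 0.02,
                  beta_outcome = rnorm(6, 0, 0.3),
                  se_outcome = runif(6, 0.02, 0.05))
  fe <- ivw(d, "fixed")
  re <- ivw(d, "random")
  expect_equal(re$se, fe$se * max(1, sqrt(fe$q_stat / fe$q_df)),
               tolerance = 1e-12)
  expect_gte(re$se, fe$se)
  expect_equal(re$estimate, fe$estimate)
})

test_that("GLS-IVW with identity LD reduces to fixed-effect IVW", {
  set.seed(9)
  k <- 6
  ids <- sprintf("v%d", 1:k)
  d <- data.frame(id = ids,
                  beta_exposure = runif(k, 0.2, 1), se_exposure = 0.02,
                  beta_outcome = rnorm(k, -0.2, 0.1),
                  se_outcome = runif(k, 0.02, 0.08))
  ld <- ld_matrix(ids, diag(k))
  g <- gls_ivw(d, ld = ld)
  f <- ivw(d, "fixed")
  expect_equal(g$estimate, f$estimate, tolerance = 1e-10)
  expect_equal(g$se, f$se, tolerance = 1e-10)
  expect_equal(g$q_stat, f$q_stat, tolerance = 1e-8)
})

test_that("near-duplicate instruments do not double the GLS information", {
  d <- data.frame(id = c("a", "b"),
                  beta_exposure = c(0.5, 0.5), se_exposure = 0.02,
                  beta_outcome = c(0.25, 0.25), se_outcome = c(0.1, 0.1))
  rho <- 0.999
  ld <- ld_matrix(c("a", "b"), matrix(c(1, rho, rho, 1), 2))
  g <- gls_ivw(d, ld = ld)
  single <- wald_ratio(0.5, 0.02, 0.25, 0.1)
  # closed form for an equicorrelated pair: se = single * sqrt((1+rho)/2)
  expect_equal(g$se, single$se * sqrt((1 + rho) / 2), tolerance = 1e-10)
  expect_equal(g$se / single$se, 1, tolerance = 1e-3)
})

test_that("GLS matches a whitened-regression oracle on random instances", {
  set.seed(202)
  for (i in 1:20) {
    k <- sample(3:10, 1)
    ids <- sprintf("v%d", 1:k)
    r <- ld_matrix(ids, 0.7^abs(outer(1:k, 1:k, "-")))
    d <- data.frame(id = ids, beta_exposure = rnorm(k, 0.5, 0.2),
                    se_exposure = 0.02,
                    beta_outcome = rnorm(k, -0.25, 0.1),
                    se_outcome = runif(k, 0.02, 0.1))
    omega <- r$r * tcrossprod(d$se_outcome)
    li <- solve(t(chol(omega)))
    fit <- lm(drop(li %*% d$beta_outcome) ~ 0 + drop(li %*% d$beta_exposure))
    g <- gls_ivw(d, ld = r)
    expect_equal(g$estimate, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("an ill-conditioned Omega is refused with clumping advice", {
  d <- data.frame(id = c("a", "b"),
                  beta_exposure = c(0.5, 0.5), se_exposure = 0.02,
                  beta_outcome = c(0.25, 0.25), se_outcome = 0.1)
  r <- matrix(c(1, 1 - 1e-12, 1 - 1e-12, 1), 2)
  ld <- ld_matrix(c("a", "b"), r, condition = FALSE)
  expect_error(gls_ivw(d, ld = ld), "clump")
})

test_that("log-OR rescaling is log-linear and composable", {
  r <- new_mr_result_from(log(0.5), 0.1)
  expect_equal(exp(rescale_log_or(r, 2)$estimate), 0.25)
  expect_equal(rescale_log_or(r, 1)$estimate, r$estimate)
  ab <- rescale_log_or(r, 0.3 * 1.7)
  a_then_b <- rescale_log_or(rescale_log_or(r, 0.3), 1.7)
  expect_equal(ab$estimate, a_then_b$estimate, tolerance = 1e-12)
  expect_equal(ab$se, a_then_b$se, tolerance = 1e-12)
  expect_equal(ab$ci_low, a_then_b$ci_low, tolerance = 1e-12)
})

test_that("orientation to lowered exposure negates and swaps the CI", {
  r <- new_mr_result_from(0.3, 0.102)
  r$ci_low <- 0.1
  r$ci_high <- 0.5
  f <- orient_to_lowering(r)
  expect_equal(f$estimate, -0.3)
  expect_equal(c(f$ci_low, f$ci_high), c(-0.5, -0.1))
  expect_equal(orient_to_lowering(f)$estimate, 0.3)
  z <- new_mr_result_from(0, 1)
  expect_equal(orient_to_lowering(z)$estimate, 0)
})

test_that("a Bonferroni divisor widens the CI to the 1 - 0.05/m level", {
  r1 <- new_mr_result_from(0.3, 0.1, m = 1L)
  r40 <- new_mr_result_from(0.3, 0.1, m = 40L)
  expect_equal(r1$ci_high - r1$ci_low, 2 * qnorm(0.975) * 0.1)
  expect_equal(r40$ci_high - r40$ci_low,
               2 * qnorm(1 - 0.05 / 40 / 2) * 0.1)
  expect_gt(r40$ci_high, r1$ci_high)
})
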