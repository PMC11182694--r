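test_that("well-formed files parse completely and carry the trait label", {
  f <- write_sumstats_fixture(c(
    "id\teffect_allele\tother_allele\tbeta\tse\tpvalue",
    "rs1\ta\tG\t0.10\t0.02\t1e-6",
    "rs2\tC\tT\t-0.05\t0.01\t1e-3",
    "rs3\tG\tA\t0.00\t0.05\t0.99"))
  rec <- read_sumstats(f, trait = "TG")
  expect_equal(nrow(rec), 3L)
  expect_equal(nrow(attr(rec, "rejects")), 0L)
  expect_equal(rec$effect_allele, c("A", "C", "G"))  # upper-cased
  expect_true(all(rec$trait == "TG"))
})

test_that("comma-delimited input is auto-detected", {
  f <- write_sumstats_fixture(c(
    "id,effect_allele,other_allele,beta,se,pvalue",
    "rs1,A,G,0.1,0.02,1e-6"), ext = ".csv")
  expect_equal(nrow(read_sumstats(f, "x")), 1L)
})

test_that("invariant-violating rows are rejected with line numbers", {
  f <- write_sumstats_fixture(c(
    "id\teffect_allele\tother_allele\tbeta\tse\tpvalue",
    "rs1\tA\tG\t0.1\t0.02\t1e-6",
    "rs2\tA\tG\t0.1\t0\t1e-6",          # se = 0
    "rs3\tA\tG\tnope\t0.02\t1e-6",      # non-numeric beta
    "rs4\tA\tA\t0.1\t0.02\t1e-6",       # identical alleles
    "rs5\tA\tAG\t0.1\t0.02\t1e-6"))     # indel-style allele accepted
  rec <- read_sumstats(f, "x")
  rej <- attr(rec, "rejects")
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$id, c("rs1", "rs5"))
  expect_setequal(rej$line, c(3L, 4L, 5L))
  expect_match(rej$reason[rej$id == "rs2"], "se")
  expect_match(rej$reason[rej$id == "rs3"], "beta")
})

test_that("a missing mandatory column is a hard error naming the column", {
  f <- write_sumstats_fixture(c("id\teffect_allele\tother_allele\tbeta\tse",
                                "rs1\tA\tG\t0.1\t0.02"))
  expect_error(read_sumstats(f, "x"), "pvalue")
})

test_that("a fixture of published instrument rows parses to the printed values", {
  # splice-donor loss-of-function and missense pQTL instruments as printed
  f <- write_sumstats_fixture(c(
    "id\tchrom\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue\tconsequence",
    "rs116843064\t19\t8364439\tA\tG\t0.024\t-0.21\t0.0088\t3.2e-127\tmissense_variant",
    "rs138326449\t11\t116830638\tA\tG\t0.002\t-0.86\t0.0322\t3.4e-157\tsplice_donor_variant"))
  rec <- read_sumstats(f, "TG")
  expect_equal(rec$beta[rec$id == "rs116843064"], -0.21)
  expect_equal(rec$pvalue[rec$id == "rs116843064"], 3.2e-127)
  expect_equal(rec$beta[rec$id == "rs138326449"], -0.86)
  expect_equal(rec$pos[rec$id == "rs138326449"], 116830638)
})

test_that("write/read round-trips numeric fields to 12 significant digits", {
  rec <- make_records(c("rs1", "rs2"), beta = c(0.123456789012345, -1e-7),
                      se = c(0.0123456789012, 2), pvalue = c(1e-200, 0.5))
  f <- tempfile(fileext = ".tsv")
  write_sumstats(rec, f)
  back <- read_sumstats(f, "t")
  for (col in c("beta", "se", "pvalue", "eaf", "pos"))
    expect_equal(back[[col]], rec[[col]], tolerance = 1e-12)
})

test_that("harmonization flips swapped alleles and negates the outcome beta", {
  ex <- make_records("rs1", beta = 0.5, se = 0.1, ea = "A", oa = "G")
  ou <- make_records("rs1", beta = -0.3, se = 0.1, ea = "G", oa = "A",
                     eaf = 0.7, trait = "out")
  h <- harmonize(ex, ou)
  expect_equal(h$beta_outcome, 0.3)
  expect_equal(h$eaf_outcome, 0.3)
  expect_equal(attr(h, "log")$action, "flipped")
})

test_that("ambiguous palindromic variants are dropped inside the eaf window", {
  ex <- make_records(c("rs1", "rs2"), beta = c(0.5, 0.5), se = 0.1,
                     ea = "A", oa = "T", eaf = c(0.50, 0.10))
  ou <- make_records(c("rs1", "rs2"), beta = c(0.3, 0.3), se = 0.1,
                     ea = "A", oa = "T", eaf = c(0.50, 0.10), trait = "out")
  h <- harmonize(ex, ou, palindrome_eaf_window = 0.08)
  expect_equal(h$id, "rs2")   # eaf 0.10 is resolvable, 0.50 is not
  lg <- attr(h, "log")
  expect_match(lg$action[lg$id == "rs1"], "palindromic")
})

test_that("incompatible allele pairs are dropped and zero overlap errors", {
  ex <- make_records(c("rs1", "rs2"), beta = c(0.5, 0.4), se = 0.1,
                     ea = "A", oa = "G")
  ou <- make_records(c("rs1", "rs2"), beta = c(0.3, 0.2), se = 0.1,
                     ea = c("A", "C"), oa = c("G", "T"), trait = "out")
  h <- harmonize(ex, ou)
  expect_equal(h$id, "rs1")
  ou2 <- make_records("rs9", beta = 0.3, se = 0.1, trait = "out")
  expect_error(harmonize(ex, ou2), "shared")
})

test_that("harmonization is idempotent: re-harmonizing an aligned outcome is a no-op", {
  set.seed(42)
  ids <- sprintf("rs%d", 1:8)
  ex <- make_records(ids, beta = rnorm(8), se = runif(8, 0.05, 0.2),
                     ea = "A", oa = "G", eaf = runif(8, 0.05, 0.95))
  flip <- rep(c(TRUE, FALSE), 4)
  ou <- make_records(ids, beta = rnorm(8), se = runif(8, 0.05, 0.2),
                     ea = ifelse(flip, "G", "A"),
                     oa = ifelse(flip, "A", "G"),
                     eaf = runif(8, 0.05, 0.95), trait = "out")
  h1 <- harmonize(ex, ou)
  aligned <- make_records(h1$id, beta = h1$beta_outcome, se = h1$se_outcome,
                          ea = h1$effect_allele, oa = h1$other_allele,
                          eaf = h1$eaf_outcome, trait = "out")
  h2 <- harmonize(ex[match(h1$id, ex$id), ], aligned)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
  expect_true(all(attr(h2, "log")$action == "kept"))
})

test_that("LD matrices validate symmetry, bounds and diagonal", {
  expect_silent(ld_matrix(c("a", "b"), matrix(c(1, 0.7, 0.7, 1), 2)))
  expect_error(ld_matrix(c("a", "b"), matrix(c(1, 1.2, 1.2, 1), 2)), "exceeds")
  expect_error(ld_matrix(c("a", "b"), matrix(c(1, 0.2, 0.7, 1), 2)),
               "asymmetric")
  expect_error(ld_matrix(c("a", "b"), matrix(c(1, NA, NA, 1), 2)), "NaN")
})

test_that("non-PSD input is conditioned to an invertible correlation matrix", {
  # three mutually high correlations that violate PSD
  r <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  ld <- ld_matrix(c("a", "b", "c"), r)
  ev <- eigen(ld$r, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(diag(ld$r), c(a = 1, b = 1, c = 1))
  expect_equal(ld$r, t(ld$r))
})

test_that("read_ld / write_ld round-trip conditioned matrices", {
  r <- 0.8^abs(outer(1:4, 1:4, "-"))
  ld <- ld_matrix(sprintf("v%d", 1:4), r)
  f <- tempfile(fileext = ".tsv")
  write_ld(ld, f)
  back <- read_ld(f)
  expect_equal(back$ids, ld$ids)
  expect_equal(back$r, ld$r, tolerance = 1e-12)
})

test_that("malformed LD files are hard errors", {
  f <- tempfile()
  writeLines(c("id\tv1\tv2", "v1\t1\t1.2", "v2\t1.2\t1"), f)
  expect_error(read_ld(f), "exceeds")
  writeLines(c("id\tv1\tv2", "v1\t1\t0.5", "v2\t0.5\tNaN"), f)
  expect_error(read_ld(f))
})
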