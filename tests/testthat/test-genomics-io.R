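test_that("a toy VCF reads back into the expected genotype matrix", {
  dir <- withr::local_tempdir()
  geno <- matrix(c(0L, 1L, 2L, 0L,
                   1L, 0L, 0L, 2L,
                   0L, 0L, 1L, 1L), 3, 4, byrow = TRUE)
  samples <- c("case1", "case2", "ctrl1", "ctrl2")
  vcf <- write_toy_vcf(dir, geno, samples)
  anno <- write_toy_anno(dir, sprintf("rs%03d", 1:3))
  lv <- load_vcf(vcf, anno)
  expect_equal(dim(lv$gm), c(3L, 4L))
  expect_equal(sum(!is.na(lv$gm$geno)), 12L)
  expect_equal(unname(lv$gm$geno), unname(geno))
  expect_equal(lv$gm$is_case, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(lv$sites$variant_id, sprintf("rs%03d", 1:3))
})

test_that("missing annotations drop variants with a warning", {
  dir <- withr::local_tempdir()
  geno <- matrix(0:1, 2, 2)
  vcf <- write_toy_vcf(dir, geno, c("case1", "ctrl1"))
  anno <- write_toy_anno(dir, "rs001")   # rs002 unannotated
  expect_warning(lv <- load_vcf(vcf, anno), "without annotation")
  expect_equal(nrow(lv$gm$geno), 1L)
})

test_that("a VCF without GQ skips quality masking with a warning", {
  dir <- withr::local_tempdir()
  geno <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  dp <- matrix(c(30L, 30L, 2L, 30L), 2, 2)   # one low-depth call
  vcf <- write_toy_vcf(dir, geno, c("case1", "ctrl1"), dp = dp)
  anno <- write_toy_anno(dir, sprintf("rs%03d", 1:2))
  lv <- load_vcf(vcf, anno)
  expect_warning(
    f <- qc_filter(lv$gm, lv$sites, missing_max = 0.6),
    "GQ.*skipped")
  expect_true(is.na(f$gm$geno[1, 2]))        # the DP=2 call is masked
  expect_false(anyNA(f$gm$geno[, 1]))
})

test_that("simulator-written cohorts round-trip through the VCF reader", {
  dir <- withr::local_tempdir()
  co <- simulate_background(n_samples = 40, n_genes = 6, seed = 123)
  paths <- write_cohort(co, dir)
  back <- load_cohort(paths["vcf"], paths["anno"], paths["features"],
                      paths["pairs"])
  expect_equal(unname(back$gm$geno), unname(co$gm$geno))
  expect_equal(back$gm$is_case, co$gm$is_case)
  expect_equal(back$sites$reference_MAF, co$sites$reference_MAF)
  expect_equal(back$sites$score, co$sites$score)
  expect_equal(as.data.frame(back$features), as.data.frame(co$features))
  expect_equal(back$pairs$pair_score, co$pairs$pair_score)
})

test_that("genotypes are oriented to the reference minor allele", {
  dir <- withr::local_tempdir()
  geno <- matrix(c(2L, 2L, 1L, 2L), 2, 2)
  vcf <- write_toy_vcf(dir, geno, c("case1", "ctrl1"))
  anno <- write_toy_anno(dir, sprintf("rs%03d", 1:2),
                         ref_maf = c(0.999, 0.001))
  expect_message(lv <- load_vcf(vcf, anno), "re-oriented")
  expect_equal(unname(lv$gm$geno[1, ]), c(0L, 1L))  # 2 - g at each call
  expect_equal(unname(lv$gm$geno[2, ]), c(2L, 2L))  # untouched
  expect_equal(lv$sites$reference_MAF[1], 0.001)
})

test_that("HWE exact test matches binom-enumeration oracle and boundary rule", {
  # enumeration oracle for a tiny site
  oracle <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb; nm <- 2 * n_bb + n_ab
    hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
    pr <- vapply(hets, function(h) {
      hom_min <- (nm - h) / 2
      exp(lfactorial(n) - lfactorial(h) - lfactorial(hom_min) -
            lfactorial(n - h - hom_min) + h * log(2) +
            lfactorial(nm) + lfactorial(2 * n - nm) - lfactorial(2 * n))
    }, numeric(1))
    obs <- pr[match(n_ab, hets)]
    sum(pr[pr <= obs + 1e-12])
  }
  for (cfg in list(c(80, 15, 5), c(50, 40, 10), c(95, 0, 5), c(10, 10, 10))) {
    expect_equal(hwe_exact_p(cfg[1], cfg[2], cfg[3]),
                 oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-10,
                 info = paste(cfg, collapse = ","))
  }
})

test_that("QC applies the filters in order with correct boundaries", {
  set.seed(60)
  n <- 10
  geno <- matrix(0L, 3, n)
  geno[1, 1:2] <- 1L
  geno[2, ] <- c(2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)  # HWE-violating
  geno[3, 1:2] <- 1L
  gm <- genotype_matrix(geno, rep(c(TRUE, FALSE), 5))
  sites <- data.table::data.table(
    variant_id = paste0("v", 1:3), gene_id = "G1",
    score = 0.5, reference_MAF = 0.001, consequence = "missense",
    sample_MAF = 0, hwe_p = NA_real_, missing_rate = 0)

  # removal of a het-deficient site is consistent with its exact p-value
  f <- suppressWarnings(qc_filter(gm, sites, hwe_samples = "all"))
  expect_equal("v2" %in% f$sites$variant_id, hwe_exact_p(7, 0, 3) > 1e-5)
  f2s <- suppressWarnings(qc_filter(gm, sites, hwe_threshold = 0.05,
                                    hwe_samples = "all"))
  expect_equal("v2" %in% f2s$sites$variant_id, hwe_exact_p(7, 0, 3) > 0.05)

  # threshold is <=: a site at exactly the threshold is removed
  gm1 <- genotype_matrix(matrix(c(1L, 0L), 1, 2), c(TRUE, FALSE))
  s1 <- sites[1]
  f2 <- suppressWarnings(qc_filter(gm1, s1, hwe_threshold = 1,
                                   hwe_samples = "all"))
  expect_equal(nrow(f2$sites), 0L)

  # DP/GQ boundary: calls at exactly dp_min / gq_min are retained
  dp <- matrix(c(8, 7), 1, 2); gq <- matrix(c(20, 19), 1, 2)
  gmb <- genotype_matrix(matrix(c(1L, 1L), 1, 2), c(TRUE, FALSE),
                         dp = dp, gq = gq)
  fb <- qc_filter(gmb, s1, missing_max = 0.9, hwe_samples = "all")
  expect_false(is.na(fb$gm$geno[1, 1]))
  expect_true(is.na(fb$gm$geno[1, 2]))

  # missingness: 3 masked of 10 (30%) exceeds the 20% cap
  dp10 <- matrix(30, 1, 10); dp10[1, 1:3] <- 5
  gms <- genotype_matrix(matrix(1L, 1, 10), rep(c(TRUE, FALSE), 5),
                         dp = dp10, gq = matrix(30, 1, 10))
  s2 <- sites[1]
  fm <- qc_filter(gms, s2, hwe_threshold = 0, hwe_samples = "all")  # has DP/GQ
  expect_equal(nrow(fm$sites), 0L)
})

test_that("QC is idempotent", {
  set.seed(61)
  co <- simulate_background(n_samples = 60, n_genes = 5, seed = 8)
  f1 <- suppressWarnings(qc_filter(co$gm, co$sites))
  f2 <- suppressWarnings(qc_filter(f1$gm, f1$sites))
  expect_equal(f2$gm$geno, f1$gm$geno)
  expect_equal(f2$sites$variant_id, f1$sites$variant_id)
})

test_that("rare-variant filter honors the strict cutoff and consequences", {
  sites <- data.table::data.table(
    variant_id = paste0("v", 1:4), gene_id = "G",
    score = 0.5,
    reference_MAF = c(0.01, 0.0099, 0.001, 0.001),
    consequence = c("missense", "missense", "synonymous", "stop-gain"),
    sample_MAF = c(0.01, 0.0099, 0.001, 0.001))
  keep <- filter_rare(sites, 0.01)
  expect_equal(keep, c(FALSE, TRUE, FALSE, TRUE))
  # nested cutoffs: the looser filter keeps a superset
  k_loose <- filter_rare(sites, 0.05)
  expect_true(all(k_loose[keep]))
  expect_error(filter_rare(sites, 0), class = "eb_config_error")
  expect_error(filter_rare(sites, 0.7), class = "eb_config_error")
})

test_that("accumulated MAF sums qualifying reference frequencies per gene", {
  sites <- data.table::data.table(
    variant_id = paste0("v", 1:3),
    gene_id = c("A", "A", "B"),
    reference_MAF = c(0.001, 0.004, 0.002),
    sample_MAF = c(0.002, 0.003, 0.004))
  x2 <- accumulated_maf(sites)
  expect_equal(unname(x2), c(0.005, 0.002))
  expect_equal(unname(accumulated_maf(sites, genes = c("A", "B", "C"))),
               c(0.005, 0.002, 0))
  # brute-force summation oracle on a simulated gene
  set.seed(12)
  m <- runif(50, 1e-4, 0.01)
  s50 <- data.table::data.table(variant_id = paste0("x", 1:50),
                                gene_id = "Z", reference_MAF = m,
                                sample_MAF = m)
  expect_equal(unname(accumulated_maf(s50)), sum(m))
})

test_that("pair selection canonicalizes, deduplicates and excludes", {
  features <- data.table::data.table(
    gene_id = c("A", "B", "C", "TTN"), cds_length = 1000,
    accumulated_maf = 0.01, cds_times_maf = 10, oe_mis = 1, oe_lof = 1,
    gc_content = 0.5)
  pairs <- data.frame(
    gene_i = c("B", "A", "A", "TTN", "A"),
    gene_j = c("A", "B", "C", "C", "C"),
    pair_score = c(0.9, 0.9, 0.85, 0.95, 0.85))
  got <- select_pairs(pairs, 0.8, features,
                      genes_with_variants = c("A", "B", "C", "TTN"))
  expect_equal(nrow(got), 2L)              # (A,B) deduped, (C,TTN) excluded
  expect_true(all(got$gene_i < got$gene_j))
  # threshold is strict: a pair scoring exactly the threshold is dropped
  strict <- select_pairs(pairs, 0.85, features,
                         genes_with_variants = c("A", "B", "C"))
  expect_equal(strict$pair_score, 0.9)
  # conflicting duplicate scores raise
  bad <- pairs; bad$pair_score[1] <- 0.5
  expect_error(select_pairs(bad, 0.1, features,
                            genes_with_variants = c("A", "B", "C")),
               "conflicting")
  expect_error(select_pairs(data.frame(gene_i = "A", gene_j = "A",
                                       pair_score = 1),
                            0.5, features, "A"), "self-pairs")
})

test_that("pair predictors are feature products with optional control burden", {
  ft <- data.table::data.table(
    gene_id = c("A", "B"), cds_length = c(100, 200),
    accumulated_maf = c(0.01, 0.02), cds_times_maf = c(1, 4),
    oe_mis = c(0.5, 0.8), oe_lof = c(0.3, 0.6), gc_content = c(0.4, 0.5))
  x <- pair_predictors(ft[1], ft[2])
  expect_equal(unname(x), c(20000, 2e-4, 4, 0.4, 0.18, 0.2))
  expect_length(x, 6L)
  x7 <- pair_predictors(ft[1], ft[2], x7 = 3L)
  expect_length(x7, 7L)
  expect_equal(unname(x7[["X7"]]), 3)
  expect_error(pair_predictors(ft[1], ft[1]), "itself")
})
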