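test_that("odds multipliers reproduce the three model tables cell by cell", {
  th <- function(gA, gB) odds_multiplier("threshold", gA, gB, 0.7)
  # threshold: flat baseline unless both loci carry a risk allele
  expect_equal(sapply(0:2, function(a) sapply(0:2, function(b) th(a, b))),
               matrix(c(1, 1, 1,  1, 1.7, 1.7,  1, 1.7, 1.7), 3, 3))
  mu <- function(gA, gB) odds_multiplier("multiplicative", gA, gB, 0.5)
  expect_equal(sapply(0:2, function(a) sapply(0:2, function(b) mu(a, b))),
               matrix(c(1, 1, 1,
                        1, 1.5, 1.5^2,
                        1, 1.5^2, 1.5^4), 3, 3))
  cl <- function(gA, gB) odds_multiplier("classic", gA, gB, 0.25)
  expect_equal(sapply(0:2, function(a) sapply(0:2, function(b) cl(a, b))),
               matrix(c(1, 1, 2,      # AA: BB, Bb, bb
                        1, 1.5, 1,    # Aa
                        2, 1, 1), 3, 3))
  expect_error(odds_multiplier("nope", 1, 1, 0.5))
})

test_that("alpha/theta solution hits the prevalence and the closed form", {
  # no effect: closed form alpha = prev / (1 - prev)
  m0 <- solve_alpha_theta("threshold", 0.01, 0.1, 1)
  expect_equal(m0$theta_eff, 0)
  expect_equal(m0$alpha, 0.01 / 0.99, tolerance = 1e-9)
  # round trip over a grid of settings and kinds
  for (kind in c("threshold", "multiplicative", "classic")) {
    for (or in c(5, 10, 20)) for (maf in c(0.005, 0.01, 0.02)) {
      m <- solve_alpha_theta(kind, 0.01, maf, or)
      expect_lt(abs(model_prevalence(m) - 0.01), 1e-10)
    }
  }
  # effect sizes invert each kind's maximal multiplier
  expect_equal(solve_alpha_theta("threshold", 0.01, 0.01, 20)$theta_eff, 19)
  expect_equal(solve_alpha_theta("multiplicative", 0.01, 0.01, 16)$theta_eff, 1)
  expect_equal(solve_alpha_theta("classic", 0.01, 0.01, 21)$theta_eff, 5)
  # brute-force 1-D grid/bisection oracle on alpha for a fixed scenario
  m <- solve_alpha_theta("classic", 0.01, 0.01, 20)
  f <- function(a) {
    g <- expand.grid(gA = 0:2, gB = 0:2)
    hw <- function(x, fq) c((1 - fq)^2, 2 * fq * (1 - fq), fq^2)[x + 1]
    pg <- hw(g$gA, 0.01) * hw(g$gB, 0.01)
    mm <- odds_multiplier("classic", g$gA, g$gB, m$theta_eff)
    sum(pg * a * mm / (1 + a * mm)) - 0.01
  }
  lo <- 1e-6; hi <- 1
  for (i in 1:60) { mid <- (lo + hi) / 2; if (f(mid) < 0) lo <- mid else hi <- mid }
  expect_equal(m$alpha, (lo + hi) / 2, tolerance = 1e-8)
})

test_that("the background generator is reproducible and calibrated", {
  co1 <- simulate_background(n_samples = 200, n_genes = 10, seed = 55)
  co2 <- simulate_background(n_samples = 200, n_genes = 10, seed = 55)
  expect_identical(co1$gm$geno, co2$gm$geno)
  expect_identical(co1$features, co2$features)
  co3 <- simulate_background(n_samples = 200, n_genes = 10, seed = 56)
  expect_false(identical(co1$gm$geno, co3$gm$geno))
  # sample allele frequencies match the generating MAFs (binomial error)
  co <- simulate_background(n_samples = 4000, n_genes = 20, seed = 77)
  af <- co$sites$sample_MAF
  maf <- co$sites$reference_MAF
  se <- sqrt(maf * (1 - maf) / (2 * 4000))
  z <- (af - maf) / pmax(se, 1e-12)
  expect_lt(mean(abs(z) > 3.5), 0.01)
  # feature table covers every gene with a variant; X3 consistency
  expect_true(all(co$sites$gene_id %in% co$features$gene_id))
  expect_equal(co$features$cds_times_maf,
               co$features$cds_length * co$features$accumulated_maf)
  # X2 equals the per-gene sum of reference MAFs
  expect_equal(co$features$accumulated_maf,
               unname(accumulated_maf(co$sites, genes = co$features$gene_id)))
})

test_that("stratified controls diverge from the case pool", {
  co_n <- simulate_background(n_samples = 600, n_genes = 15, seed = 42)
  co_s <- simulate_background(n_samples = 600, n_genes = 15, seed = 42,
                              stratification = TRUE)
  div <- function(co) {
    ca <- sample_maf(co$gm$geno[, co$gm$is_case, drop = FALSE])
    ct <- sample_maf(co$gm$geno[, !co$gm$is_case, drop = FALSE])
    mean(abs(ca - ct))
  }
  expect_gt(div(co_s), div(co_n))
  expect_length(co_s$truth$stratified_controls, 150L)
})

test_that("causal insertion enriches doubly-mutated genotypes in cases", {
  model <- solve_alpha_theta("threshold", 0.01, 0.05, 20)
  co <- simulate_background(n_samples = 4000, n_genes = 8, seed = 13)
  tg <- co$features$gene_id[1:2]
  co2 <- insert_causal_pair(co, model, target = tg, seed = 14)
  expect_equal(co2$truth$causal_pair, sort(tg))
  # target genes carry exactly one (causal) variant each
  expect_equal(sum(co2$sites$gene_id %in% tg), 2L)
  expect_true(all(co2$sites$reference_MAF[co2$sites$gene_id %in% tg] == 0))
  ci <- co2$gm$geno[startsWith(rownames(co2$gm$geno), "causal_"), ]
  both <- colSums(ci >= 1) == 2
  f_case <- mean(both[co2$gm$is_case])
  f_ctrl <- mean(both[!co2$gm$is_case])
  expect_gt(f_case, f_ctrl * 3)
  # under the null the enrichment disappears
  m0 <- solve_alpha_theta("threshold", 0.01, 0.05, 1)
  co0 <- insert_causal_pair(co, m0, target = tg, seed = 15)
  ci0 <- co0$gm$geno[startsWith(rownames(co0$gm$geno), "causal_"), ]
  b0 <- colSums(ci0 >= 1) == 2
  expect_lt(abs(mean(b0[co0$gm$is_case]) - mean(b0[!co0$gm$is_case])), 0.02)
})

test_that("unascertained disease draws match the model prevalence", {
  model <- solve_alpha_theta("multiplicative", 0.01, 0.02, 10)
  set.seed(99)
  n <- 2e5
  gA <- rbinom(n, 2, model$maf); gB <- rbinom(n, 2, model$maf)
  m <- odds_multiplier(model$kind, gA, gB, model$theta_eff)
  pd <- model$alpha * m / (1 + model$alpha * m)
  prev <- mean(runif(n) < pd)
  expect_lt(abs(prev - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})

test_that("clopper-pearson intervals are exact", {
  expect_equal(unname(clopper_pearson(91, 100)), c(0.8360, 0.9580),
               tolerance = 5e-5)
  expect_equal(unname(clopper_pearson(100, 100))[1], 0.9638, tolerance = 5e-5)
  expect_equal(unname(clopper_pearson(100, 100))[2], 1)
  expect_equal(unname(clopper_pearson(83, 100)), c(0.7418, 0.8977),
               tolerance = 5e-5)
  expect_equal(unname(clopper_pearson(0, 10))[1], 0)
  # independent oracle: binom.test's exact interval
  for (x in c(0, 3, 7, 10)) {
    bt <- binom.test(x, 10)$conf.int
    expect_equal(unname(clopper_pearson(x, 10)), as.numeric(bt),
                 tolerance = 1e-9)
  }
  expect_error(clopper_pearson(1, 0), "positive")
  expect_error(clopper_pearson(5, 3))
})
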