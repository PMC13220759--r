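#' Odds multiplier of a two-locus disease genotype
#'
#' The three built-in epistasis models specify, for each combination of
#' risk-allele counts at loci A and B, the disease odds as the baseline
#' odds `alpha` times a multiplier:
#' * `threshold` - 1 unless both loci carry at least one risk allele,
#'   then `1 + theta`; extra copies add nothing.
#' * `multiplicative` - `(1 + theta)^(gA * gB)`: every additional copy at
#'   either locus multiplies the odds again, up to `(1 + theta)^4`.
#' * `classic` - a checkerboard in which one locus's effect is masked by
#'   the other: homozygous-risk at exactly one locus gives `1 + 4 theta`,
#'   double heterozygotes `1 + 2 theta`, every other cell 1.
#'
#' @param kind `"threshold"`, `"multiplicative"` or `"classic"`.
#' @param gA,gB risk-allele copy numbers (0, 1 or 2); vectorized.
#' @param theta_eff effect size (nonnegative).
#' @return odds multipliers (baseline cell = 1).
#' @export
odds_multiplier <- function(kind, gA, gB, theta_eff) {
  stopifnot(all(gA %in% 0:2), all(gB %in% 0:2), theta_eff >= 0)
  switch(match.arg(kind, c("threshold", "multiplicative", "classic")),
    threshold = ifelse(gA >= 1 & gB >= 1, 1 + theta_eff, 1),
    multiplicative = (1 + theta_eff)^(gA * gB),
    classic = {
      m <- rep(1, length(gA))
      m[gA == 1 & gB == 1] <- 1 + 2 * theta_eff
      m[(gA == 2 & gB == 0) | (gA == 0 & gB == 2)] <- 1 + 4 * theta_eff
      m
    })
}

#' Solve the baseline odds and effect size of a two-locus model
#'
#' Given the disease prevalence, the causal-allele frequency and the
#' target genotype odds ratio, the effect size is fixed so that the
#' model's maximal-risk genotype has odds `or_target` times the baseline
#' (threshold: `1 + theta = OR`; multiplicative: `(1 + theta)^4 = OR`;
#' classic: `1 + 4 theta = OR`), and the baseline odds `alpha` is then
#' obtained by one-dimensional root finding so that the population
#' prevalence under Hardy-Weinberg genotype frequencies equals `Pr(D)`.
#'
#' @param kind disease model kind.
#' @param prevalence population disease probability `Pr(D)` in `(0,1)`.
#' @param maf causal (risk) allele frequency at both loci, in `(0, 0.5)`.
#' @param or_target genotype odds ratio of the maximal-risk cell versus
#'   the double-baseline genotype (`>= 1`).
#' @return an object of class `two_locus_model` with fields `kind`,
#'   `alpha`, `theta_eff`, `maf`, `or`, `prevalence`.
#' @export
solve_alpha_theta <- function(kind, prevalence, maf, or_target) {
  kind <- match.arg(kind, c("threshold", "multiplicative", "classic"))
  stopifnot(prevalence > 0, prevalence < 1, maf > 0, maf < 0.5,
            or_target >= 1)
  theta_eff <- switch(kind,
    threshold = or_target - 1,
    multiplicative = or_target^(1 / 4) - 1,
    classic = (or_target - 1) / 4)

  g <- expand.grid(gA = 0:2, gB = 0:2)
  hw <- function(x, f) c((1 - f)^2, 2 * f * (1 - f), f^2)[x + 1L]
  pg <- hw(g$gA, maf) * hw(g$gB, maf)
  m <- odds_multiplier(kind, g$gA, g$gB, theta_eff)

  prev_at <- function(log_alpha) {
    a <- exp(log_alpha)
    sum(pg * a * m / (1 + a * m)) - prevalence
  }
  root <- uniroot(prev_at, lower = log(1e-12), upper = log(1e6),
                  tol = 1e-14, extendInt = "upX")
  structure(list(kind = kind, alpha = exp(root$root),
                 theta_eff = theta_eff, maf = maf, or = or_target,
                 prevalence = prevalence),
            class = "two_locus_model")
}

#' Population prevalence implied by a two-locus model
#'
#' @param model a [solve_alpha_theta()] model.
#' @return `sum_g P_HWE(g) * alpha m(g) / (1 + alpha m(g))`.
#' @export
model_prevalence <- function(model) {
  g <- expand.grid(gA = 0:2, gB = 0:2)
  hw <- function(x, f) c((1 - f)^2, 2 * f * (1 - f), f^2)[x + 1L]
  pg <- hw(g$gA, model$maf) * hw(g$gB, model$maf)
  m <- odds_multiplier(model$kind, g$gA, g$gB, model$theta_eff)
  sum(pg * model$alpha * m / (1 + model$alpha * m))
}

# Independent Hardy-Weinberg genotypes for nv variants x n samples,
# exploiting rarity: draw per-variant het / hom-alt carrier counts, then
# place the carriers, instead of nv * n bernoulli pairs.
hwe_genotypes <- function(nv, n, maf) {
  p_het <- 2 * maf * (1 - maf)
  p_hom <- maf^2
  n_het <- rbinom(nv, n, p_het)
  n_hom <- rbinom(nv, n - n_het, p_hom / (1 - p_het))
  geno <- matrix(0L, nv, n)
  tot <- n_het + n_hom
  rows <- which(tot > 0L)
  for (i in rows) {
    cols <- sample.int(n, tot[i])
    if (n_het[i]) geno[i, cols[seq_len(n_het[i])]] <- 1L
    if (n_hom[i]) geno[i, cols[n_het[i] + seq_len(n_hom[i])]] <- 2L
  }
  geno
}

#' Simulate a null background cohort
#'
#' Generates a synthetic case-control cohort with the statistical
#' structure the interaction-burden test assumes: genes with a
#' rare-variant spectrum, per-variant functional scores, a gene feature
#' table whose CDS length and accumulated MAF genuinely drive the
#' expected burden (longer genes carry more rare variants), and a
#' candidate pair list with interaction-prediction scores. Genotypes are
#' independent Hardy-Weinberg draws per variant, so the cohort carries no
#' true interaction signal; phenotype labels are assigned at random to
#' half the samples.
#'
#' With `stratification = TRUE` a fraction of the controls is drawn from
#' a diverged allele-frequency pool (Balding-Nichols beta draws around
#' each variant's frequency), emulating ancestrally mixed controls.
#'
#' @param n_samples total samples (balanced cases/controls).
#' @param n_genes number of background genes; all pairs of these genes
#'   become candidates.
#' @param mean_variants mean rare-variant count of an average-length gene.
#' @param maf_shape1,maf_shape2 beta parameters of the rare-skewed MAF
#'   distribution, rescaled to `(0, maf_max)`.
#' @param maf_max upper bound of generated reference MAFs; keep below the
#'   analysis cutoff so the generated spectrum is genuinely rare.
#' @param score_shape1,score_shape2 beta parameters of the functional-score
#'   distribution. The default is right-skewed (mean about 0.26):
#'   pathogenicity predictors rate most rare missense variants as benign,
#'   with a tail of high-scoring variants.
#' @param stratification draw part of the controls from a diverged pool?
#' @param strat_fraction fraction of controls that is diverged.
#' @param fst divergence of the second pool.
#' @param seed RNG seed; the cohort is reproducible given the seed.
#' @return an `eb_cohort` list: `gm`, `sites`, `features`, `pairs`, and
#'   `truth` (generator bookkeeping).
#' @export
simulate_background <- function(n_samples, n_genes = 112L,
                                mean_variants = 22, maf_shape1 = 0.8,
                                maf_shape2 = 3, maf_max = 0.0099,
                                score_shape1 = 1.2, score_shape2 = 3.5,
                                stratification = FALSE,
                                strat_fraction = 0.5, fst = 0.05,
                                seed = 1L) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  cds <- pmax(round(rlnorm(n_genes, log(1500), 0.35)), 150)
  # variant count scales with coding length
  n_var <- pmax(rpois(n_genes, mean_variants * cds / 1500), 1L)
  gene_id <- rep(genes, n_var)
  nv <- sum(n_var)
  ref_maf <- pmax(maf_max * rbeta(nv, maf_shape1, maf_shape2), 1e-5)
  score <- rbeta(nv, score_shape1, score_shape2)
  consequence <- sample(NONSYN_CONSEQUENCES, nv, replace = TRUE,
                        prob = c(0.72, 0.01, 0.01, 0.06, 0.08, 0.08, 0.04))

  is_case <- rep(FALSE, n_samples)
  is_case[sample.int(n_samples, floor(n_samples / 2))] <- TRUE

  if (stratification) {
    ctrl_idx <- which(!is_case)
    n_str <- floor(length(ctrl_idx) * strat_fraction)
    strat <- sample(ctrl_idx, n_str)
    main <- setdiff(seq_len(n_samples), strat)
    a <- ref_maf * (1 - fst) / fst
    b <- (1 - ref_maf) * (1 - fst) / fst
    maf2 <- pmin(pmax(rbeta(nv, a, b), 1e-6), 0.5)
    geno <- matrix(0L, nv, n_samples)
    geno[, main] <- hwe_genotypes(nv, length(main), ref_maf)
    geno[, strat] <- hwe_genotypes(nv, n_str, maf2)
  } else {
    strat <- integer()
    geno <- hwe_genotypes(nv, n_samples, ref_maf)
  }
  vid <- sprintf("var%05d", seq_len(nv))
  rownames(geno) <- vid
  colnames(geno) <- ifelse(is_case,
                           sprintf("case%05d", cumsum(is_case)),
                           sprintf("ctrl%05d", cumsum(!is_case)))

  sites <- data.table::data.table(
    variant_id = vid, gene_id = gene_id, score = score,
    reference_MAF = ref_maf, consequence = consequence)
  sites$sample_MAF <- sample_maf(geno)
  sites$hwe_p <- NA_real_
  sites$missing_rate <- 0

  x2 <- accumulated_maf(sites, genes = genes)
  features <- data.table::data.table(
    gene_id = genes,
    cds_length = cds,
    accumulated_maf = as.numeric(x2),
    cds_times_maf = cds * as.numeric(x2),
    oe_mis = runif(n_genes, 0.4, 1.1),
    oe_lof = runif(n_genes, 0.2, 1.2),
    gc_content = runif(n_genes, 0.35, 0.6))

  cmb <- utils::combn(genes, 2L)
  pairs <- data.table::data.table(gene_i = cmb[1L, ], gene_j = cmb[2L, ],
                                  pair_score = runif(ncol(cmb), 0.5, 1))

  gm <- genotype_matrix(geno, is_case)
  structure(list(gm = gm, sites = sites, features = features, pairs = pairs,
                 truth = list(seed = seed, stratified_controls = strat,
                              causal_pair = NULL)),
            class = "eb_cohort")
}

#' Insert a causal variant pair under a two-locus disease model
#'
#' Emulates a semi-simulation: two target genes are cleared of background
#' variants and each receives a single causal variant; two-locus causal
#' genotypes are drawn under Hardy-Weinberg at the model's allele
#' frequency, disease status follows the model odds
#' `alpha m(g) / (1 + alpha m(g))`, and draws are rejection-sampled in
#' batches until the cohort's case and control quotas are filled. Cases
#' and controls then receive causal genotypes from the respective
#' accepted draws, while all background genotypes remain untouched (and
#' hence null). The inserted variants are treated as absent from the
#' reference panel (`reference_MAF = 0`), as inserted artificial alleles
#' are, so the rare-variant filter retains them regardless of the
#' generating frequency. Gene features are left untouched: they stand in
#' for external annotation databases, which do not change when sample
#' variants do.
#'
#' @param cohort a cohort from [simulate_background()].
#' @param model a [solve_alpha_theta()] two-locus model.
#' @param target character vector of two gene ids; defaults to the first
#'   two genes.
#' @param causal_score functional scores for the two inserted variants;
#'   by default drawn from a high-but-imperfect predictor distribution
#'   (beta with mean 0.7), reflecting that pathogenicity predictors rate
#'   true causal variants highly on average but with real spread.
#' @param seed RNG seed for the causal draw.
#' @param max_draws rejection-sampling cap.
#' @return the modified cohort, with `truth$causal_pair` set.
#' @export
insert_causal_pair <- function(cohort, model, target = NULL,
                               causal_score = NULL, seed = 1L,
                               max_draws = 1e7) {
  set.seed(seed)
  genes <- cohort$features$gene_id
  target <- target %||% genes[1:2]
  stopifnot(length(target) == 2L, all(target %in% genes))
  gm <- cohort$gm
  n_cases <- sum(gm$is_case); n_ctrl <- sum(!gm$is_case)

  # draw two-locus genotypes and disease status until both quotas fill
  need_case <- n_cases; need_ctrl <- n_ctrl
  acc_case <- acc_ctrl <- matrix(integer(), 0L, 2L)
  drawn <- 0L
  batch <- max(2e4, ceiling(need_case / model$prevalence))
  while ((need_case > 0L || need_ctrl > 0L) && drawn < max_draws) {
    nb <- min(batch, max_draws - drawn)
    gA <- rbinom(nb, 2L, model$maf); gB <- rbinom(nb, 2L, model$maf)
    m <- odds_multiplier(model$kind, gA, gB, model$theta_eff)
    pd <- model$alpha * m / (1 + model$alpha * m)
    D <- runif(nb) < pd
    drawn <- drawn + nb
    if (need_case > 0L) {
      i <- which(D)[seq_len(min(need_case, sum(D)))]
      acc_case <- rbind(acc_case, cbind(gA[i], gB[i]))
      need_case <- n_cases - nrow(acc_case)
    }
    if (need_ctrl > 0L) {
      i <- which(!D)[seq_len(min(need_ctrl, sum(!D)))]
      acc_ctrl <- rbind(acc_ctrl, cbind(gA[i], gB[i]))
      need_ctrl <- n_ctrl - nrow(acc_ctrl)
    }
  }
  if (need_case > 0L || need_ctrl > 0L)
    stop("rejection sampling exhausted ", max_draws,
         " draws before filling the case/control quotas; ",
         "prevalence may be too low for the requested sample size")

  # clear the target genes' background variants
  drop <- cohort$sites$gene_id %in% target
  gm <- subset_variants(gm, !drop)
  sites <- cohort$sites[!drop, ]

  cg <- matrix(0L, 2L, ncol(gm$geno))
  cg[, gm$is_case] <- t(acc_case)
  cg[, !gm$is_case] <- t(acc_ctrl)
  rownames(cg) <- paste0("causal_", target)
  colnames(cg) <- colnames(gm$geno)

  score <- causal_score %||% rbeta(2L, 3.5, 1.5)
  new_sites <- data.table::data.table(
    variant_id = rownames(cg), gene_id = target, score = score,
    reference_MAF = 0, consequence = "missense",
    sample_MAF = sample_maf(cg), hwe_p = NA_real_, missing_rate = 0)

  geno <- rbind(gm$geno, cg)
  gm2 <- genotype_matrix(geno, gm$is_case)
  sites <- rbind(sites, new_sites)

  # gene features mirror external annotation databases and are not
  # recomputed when sample variants are cleared or inserted
  cohort$gm <- gm2
  cohort$sites <- sites
  cohort$truth$causal_pair <- sort(target)
  cohort$truth$model <- model
  cohort
}
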