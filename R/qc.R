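#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic site: given the observed minor
#' allele count, the probability of each possible heterozygote count is
#' computed under HWE and the p-value is the summed probability of all
#' configurations no more likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom).
#' @return two-sided exact p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  n_minor <- 2L * n_bb + n_ab
  if (n_minor > n) {           # orient to the rarer allele
    n_minor <- 2L * n - n_minor
    tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp
  }
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log P(het = h | allele count) up to a constant
  lp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) %/% 2L
    hom_maj <- n - h - hom_min
    h * log(2) - lfactorial(h) - lfactorial(hom_min) - lfactorial(hom_maj)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs + 1e-12])
}

#' Genotype and site quality control
#'
#' Applies standard sequencing QC in three passes:
#' 1. drop sites with Hardy-Weinberg p-value at or below `hwe_threshold`
#'    (exact test on the chosen sample stratum) or with more than
#'    `max_alleles` observed alleles;
#' 2. mask individual calls with read depth below `dp_min` or genotype
#'    quality below `gq_min` to no-calls (skipped with a warning when the
#'    VCF lacks the field);
#' 3. drop sites whose post-masking missing rate exceeds `missing_max`.
#'
#' The operation is idempotent: re-applying it to its own output changes
#' nothing.
#'
#' @param gm an `eb_genotypes` object.
#' @param sites per-variant annotation table aligned with `gm`.
#' @param hwe_threshold sites with HWE p `<=` this are removed.
#' @param dp_min,gq_min calls with DP `<` `dp_min` or GQ `<` `gq_min`
#'   become no-calls (boundary values are retained).
#' @param missing_max maximum tolerated fraction of missing calls.
#' @param max_alleles maximum number of distinct alleles at a site.
#' @param hwe_samples compute the HWE test on `"controls"` (default; cases
#'   may deviate under genuine association) or on `"all"` samples.
#' @return list with filtered `gm` and `sites` (with `hwe_p` and
#'   `missing_rate` refreshed).
#' @export
qc_filter <- function(gm, sites, hwe_threshold = 1e-5, dp_min = 8,
                      gq_min = 20, missing_max = 0.20, max_alleles = 4,
                      hwe_samples = c("controls", "all")) {
  hwe_samples <- match.arg(hwe_samples)
  stopifnot(nrow(gm$geno) == nrow(sites))
  use <- if (hwe_samples == "controls" && any(!gm$is_case)) !gm$is_case
         else rep(TRUE, ncol(gm$geno))

  g_hwe <- gm$geno[, use, drop = FALSE]
  hwe_p <- vapply(seq_len(nrow(g_hwe)), function(i) {
    g <- g_hwe[i, ]
    hwe_exact_p(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
  sites$hwe_p <- hwe_p

  keep <- hwe_p > hwe_threshold & gm$n_alleles <= max_alleles
  gm <- subset_variants(gm, keep)
  sites <- sites[keep, ]

  if (!is.null(gm$dp)) {
    gm$geno[!is.na(gm$dp) & gm$dp < dp_min] <- NA_integer_
  } else if (dp_min > 0) {
    warning("no per-call DP available; depth masking skipped")
  }
  if (!is.null(gm$gq)) {
    gm$geno[!is.na(gm$gq) & gm$gq < gq_min] <- NA_integer_
  } else if (gq_min > 0) {
    warning("no per-call GQ available; genotype-quality masking skipped")
  }

  miss <- rowMeans(is.na(gm$geno))
  sites$missing_rate <- miss
  keep2 <- miss <= missing_max
  gm <- subset_variants(gm, keep2)
  sites <- sites[keep2, ]
  sites$sample_MAF <- sample_maf(gm$geno)
  list(gm = gm, sites = sites)
}

#' Rare-variant and consequence filter
#'
#' Keeps variants whose minor allele frequency is strictly below
#' `maf_cutoff` (reference-panel frequency by default, in-sample frequency
#' otherwise) and whose consequence belongs to the non-synonymous
#' categories under study.
#'
#' @param sites variant annotation table.
#' @param maf_cutoff frequency cutoff in `(0, 0.5]`; the comparison is
#'   strict (`MAF < cutoff`).
#' @param use_reference use `reference_MAF` (default) or `sample_MAF`.
#' @param consequences retained consequence categories.
#' @return logical vector marking retained sites (same length as `sites`
#'   rows); apply to both `sites` and the genotype matrix.
#' @export
filter_rare <- function(sites, maf_cutoff = 0.01, use_reference = TRUE,
                        consequences = NONSYN_CONSEQUENCES) {
  if (maf_cutoff <= 0 || maf_cutoff > 0.5)
    stop_config("maf_cutoff must lie in (0, 0.5]")
  maf <- if (use_reference) sites$reference_MAF else sites$sample_MAF
  if (use_reference && anyNA(maf))
    stop("reference_MAF missing; set use_reference = FALSE or annotate")
  maf < maf_cutoff & sites$consequence %in% consequences
}
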