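#' Construct a genotype matrix object
#'
#' Container for per-sample minor-allele copy numbers of the retained
#' variants, together with case/control labels and (optionally) per-call
#' read depth and genotype quality used by [qc_filter()].
#'
#' @param geno integer matrix, variants x samples; entries 0/1/2 or `NA`
#'   (missing call). Row names are variant ids, column names sample ids.
#' @param is_case logical vector, one entry per sample; `TRUE` marks a case.
#' @param dp,gq optional numeric matrices of the same shape as `geno` with
#'   per-call read depth and Phred genotype quality.
#' @param n_alleles integer vector, number of distinct alleles observed at
#'   each site (1 + number of ALT alleles); defaults to 2 (biallelic).
#'
#' @return An object of class `eb_genotypes`.
#' @export
genotype_matrix <- function(geno, is_case, dp = NULL, gq = NULL,
                            n_alleles = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (length(is_case) != ncol(geno))
    stop("is_case must have one entry per sample column")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype entries must be 0, 1, 2 or NA")
  for (m in list(dp, gq))
    if (!is.null(m) && !all(dim(m) == dim(geno)))
      stop("dp/gq matrices must match the genotype matrix dimensions")
  structure(list(
    geno = geno,
    is_case = as.logical(is_case),
    dp = dp, gq = gq,
    n_alleles = as.integer(n_alleles %||% rep(2L, nrow(geno))),
    variant_id = rownames(geno) %||% paste0("v", seq_len(nrow(geno))),
    samples = colnames(geno) %||% paste0("s", seq_len(ncol(geno)))
  ), class = "eb_genotypes")
}

#' @export
print.eb_genotypes <- function(x, ...) {
  cat(sprintf("<eb_genotypes> %d variants x %d samples (%d cases, %d controls)\n",
              nrow(x$geno), ncol(x$geno), sum(x$is_case), sum(!x$is_case)))
  if (!is.null(x$dp)) cat("  per-call DP available\n")
  if (!is.null(x$gq)) cat("  per-call GQ available\n")
  invisible(x)
}

#' @export
dim.eb_genotypes <- function(x) dim(x$geno)

# Subset variants (rows) of a genotype matrix, keeping metadata aligned.
subset_variants <- function(gm, keep) {
  gm$geno <- gm$geno[keep, , drop = FALSE]
  if (!is.null(gm$dp)) gm$dp <- gm$dp[keep, , drop = FALSE]
  if (!is.null(gm$gq)) gm$gq <- gm$gq[keep, , drop = FALSE]
  gm$n_alleles <- gm$n_alleles[keep]
  gm$variant_id <- gm$variant_id[keep]
  gm
}
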