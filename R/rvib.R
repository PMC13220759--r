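#' Integer functional weight of a variant
#'
#' Converts a pathogenicity score `s` in `[0,1]` into an integer weight by
#' the ceiling function `ceiling(s / b)`, where `b` is the score bin
#' length. A score of exactly 0 gives weight 0, removing the variant from
#' the weighted burden.
#'
#' @param s numeric vector of functional scores in `[0,1]`.
#' @param b score bin length in `(0,1]`.
#' @return integer vector of weights.
#' @export
integer_weight <- function(s, b) {
  if (!is.numeric(b) || length(b) != 1L || b <= 0 || b > 1)
    stop_config("score bin length b must lie in (0, 1]")
  if (any(s < 0 | s > 1)) stop("functional scores must lie in [0, 1]")
  as.integer(ceiling(s / b))
}

#' Basic rare-variant interaction burden of a gene pair
#'
#' For each case, the maximum over all cross-gene variant pairs of the
#' product of minor-allele copy numbers; the burden is the sum of these
#' maxima over cases. Only individuals carrying at least one copy at a
#' variant of each gene contribute (the product is otherwise 0). Missing
#' genotypes count as 0 copies.
#'
#' @param gi,gj genotype matrices (variants x cases) for genes i and j,
#'   entries 0/1/2 or `NA`, with identical case columns.
#' @return nonnegative integer burden.
#' @export
rvib_basic <- function(gi, gj) {
  rvib_weighted(gi, gj, rep(1L, nrow(gi)), rep(1L, nrow(gj)))
}

#' Functionally weighted rare-variant interaction burden
#'
#' As [rvib_basic()], with each copy number scaled by its variant's
#' integer functional weight before the product and maximum. Because all
#' terms are nonnegative, the per-case maximum over cross-gene products
#' factorizes into the product of per-gene maxima, which is how the
#' burden is evaluated; equivalence with the exhaustive double loop over
#' variant pairs is exercised in the test suite.
#'
#' @param gi,gj genotype matrices (variants x cases) for the two genes.
#' @param wi,wj integer weight vectors, one entry per variant row.
#' @return nonnegative integer burden.
#' @export
rvib_weighted <- function(gi, gj, wi, wj) {
  if (length(wi) != nrow(gi) || length(wj) != nrow(gj))
    stop("weight vector length must match the number of variants")
  if (nrow(gi) == 0L || nrow(gj) == 0L) return(0L)
  if (ncol(gi) != ncol(gj)) stop("genotype matrices must share samples")
  mi <- gene_max_scores(gi, wi)
  mj <- gene_max_scores(gj, wj)
  as.integer(sum(mi * mj))
}

#' Control-cohort interaction burden (X7)
#'
#' The weighted interaction burden of a gene pair computed on control
#' samples with the same variant weights; used as the seventh regression
#' predictor when enough controls are available.
#'
#' @inheritParams rvib_weighted
#' @return integer burden, or `NA` when there are no control samples (the
#'   caller must then drop the X7 predictor).
#' @export
control_rvib <- function(gi, gj, wi, wj) {
  if (ncol(gi) == 0L) return(NA_integer_)
  rvib_weighted(gi, gj, wi, wj)
}

# Per-sample maximum of weight * copy-number over a gene's variants.
gene_max_scores <- function(g, w) {
  g <- g * as.numeric(w)
  g[is.na(g)] <- 0
  if (nrow(g) == 1L) as.numeric(g) else do.call(pmax, asplit(g, 1L))
}

#' Per-gene burden score matrix
#'
#' For every gene and sample, the maximum of weight x copy-number over the
#' gene's variants. The interaction burden of any gene pair is then the
#' sum over (case) samples of the product of the two gene rows, so all
#' candidate pairs can be scored from this one matrix.
#'
#' @param geno genotype matrix, variants x samples (`NA` treated as 0).
#' @param gene_id gene assignment of each variant row.
#' @param weights integer weight per variant row.
#' @return numeric matrix, genes x samples.
#' @export
gene_burden_matrix <- function(geno, gene_id, weights) {
  genes <- sort(unique(gene_id))
  M <- matrix(0, length(genes), ncol(geno),
              dimnames = list(genes, colnames(geno)))
  # rare genotypes make weights * geno sparse: aggregate nonzero entries
  nz <- which(!is.na(geno) & geno > 0L, arr.ind = TRUE, useNames = FALSE)
  if (nrow(nz) == 0L) return(M)
  val <- as.numeric(weights[nz[, 1L]]) * as.numeric(geno[nz])
  gi <- match(gene_id[nz[, 1L]], genes)
  cell <- (nz[, 2L] - 1L) * length(genes) + gi  # linear index into M
  agg <- tapply(val, cell, max)
  M[as.integer(names(agg))] <- agg
  M
}

# Burdens for a pair table from per-gene score matrices restricted to one
# sample stratum: Y_ij = sum_k M[i,k] * M[j,k], i.e. one entry of the
# gene-by-gene cross-product, computed for all pairs in a single BLAS call.
pair_burdens_from_matrix <- function(M, pairs) {
  G <- tcrossprod(M)
  i <- match(pairs$gene_i, rownames(M))
  j <- match(pairs$gene_j, rownames(M))
  as.integer(round(G[cbind(i, j)]))
}
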