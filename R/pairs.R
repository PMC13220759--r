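#' Accumulated minor allele frequency per gene
#'
#' Sums the reference-panel (or in-sample) MAFs of a gene's qualifying
#' rare variants; this is the X2 genomic feature of the baseline-burden
#' regression. Genes with no qualifying variant get 0.
#'
#' @param sites variant annotation table already restricted to qualifying
#'   rare variants (see [filter_rare()]).
#' @param genes optional character vector fixing the output genes (and
#'   order); defaults to the genes present in `sites`.
#' @param use_reference sum `reference_MAF` (default) or `sample_MAF`.
#' @return named numeric vector of accumulated MAF per gene.
#' @export
accumulated_maf <- function(sites, genes = NULL, use_reference = TRUE) {
  maf <- if (use_reference) sites$reference_MAF else sites$sample_MAF
  acc <- tapply(maf, sites$gene_id, sum)
  genes <- genes %||% sort(names(acc))
  out <- setNames(numeric(length(genes)), genes)
  hit <- intersect(genes, names(acc))
  out[hit] <- acc[hit]
  out
}

#' Select candidate gene pairs
#'
#' Filters a three-column pair table (gene, gene, interaction-prediction
#' score) down to testable candidates: score strictly above the threshold,
#' both genes present in the feature table and carrying at least one
#' retained rare variant, neither gene excluded. Unordered pairs are
#' canonicalized (lexicographic order) and de-duplicated; the same pair
#' listed twice with conflicting scores is an error.
#'
#' @param pairs `data.table`/data.frame with columns `gene_i`, `gene_j`,
#'   `pair_score` (header optional in the file representation).
#' @param score_threshold keep pairs with `pair_score >` this value.
#' @param features gene feature table (see [read_gene_features()]).
#' @param genes_with_variants character vector of genes carrying at least
#'   one retained rare variant.
#' @param exclude_genes genes removed from consideration; defaults to a
#'   standard list of extremely long genes whose burden dominates.
#' @return `data.table` of candidates with canonical `gene_i < gene_j`.
#' @export
select_pairs <- function(pairs, score_threshold, features,
                         genes_with_variants,
                         exclude_genes = LONG_GENE_EXCLUSIONS) {
  pr <- data.table::as.data.table(pairs)[, 1:3]
  data.table::setnames(pr, c("gene_i", "gene_j", "pair_score"))
  if (any(pr$gene_i == pr$gene_j))
    stop("self-pairs (gene_i == gene_j) are not allowed")
  swap <- pr$gene_i > pr$gene_j
  tmp <- pr$gene_i[swap]
  pr$gene_i[swap] <- pr$gene_j[swap]
  pr$gene_j[swap] <- tmp

  key <- paste(pr$gene_i, pr$gene_j, sep = "\r")
  sc_range <- tapply(pr$pair_score, key, function(s) diff(range(s)))
  conflict <- names(sc_range)[sc_range > 0]
  if (length(conflict))
    stop("conflicting scores for duplicated pair(s): ",
         paste(gsub("\r", "-", conflict), collapse = ", "))
  pr <- pr[!duplicated(key), ]

  ok_genes <- setdiff(intersect(features$gene_id, genes_with_variants),
                      exclude_genes)
  pr <- pr[pr$pair_score > score_threshold &
             pr$gene_i %in% ok_genes & pr$gene_j %in% ok_genes, ]
  pr[order(pr$gene_i, pr$gene_j), ]
}

#' Per-pair regression predictors
#'
#' The baseline-burden regression uses, for each gene pair, the products of
#' the six gene-level genomic features (CDS length, accumulated MAF, their
#' product, oe_mis, oe_lof, GC content) of the two genes, optionally
#' followed by the control-cohort interaction burden X7.
#'
#' @param fi,fj single-row gene feature records.
#' @param x7 control burden for the pair (ignored unless `include_x7`).
#' @param include_x7 append the control-burden predictor?
#' @return named numeric vector of length 6 or 7.
#' @export
pair_predictors <- function(fi, fj, x7 = NULL, include_x7 = !is.null(x7)) {
  if (identical(fi$gene_id, fj$gene_id))
    stop("a gene cannot be paired with itself")
  cols <- c("cds_length", "accumulated_maf", "cds_times_maf",
            "oe_mis", "oe_lof", "gc_content")
  x <- as.numeric(fi[, cols, with = FALSE]) * as.numeric(fj[, cols, with = FALSE])
  if (x[1] <= 0) stop("nonpositive CDS-length product: degenerate gene")
  names(x) <- paste0("X", 1:6)
  if (include_x7) {
    if (is.null(x7) || is.na(x7)) stop("include_x7 = TRUE but x7 missing")
    x <- c(x, X7 = as.numeric(x7))
  }
  x
}

# Vectorized predictor matrix for a pair table: products of feature columns.
pair_predictor_matrix <- function(pairs, features, x7 = NULL) {
  cols <- c("cds_length", "accumulated_maf", "cds_times_maf",
            "oe_mis", "oe_lof", "gc_content")
  fi <- as.matrix(features[match(pairs$gene_i, features$gene_id), cols, with = FALSE])
  fj <- as.matrix(features[match(pairs$gene_j, features$gene_id), cols, with = FALSE])
  X <- fi * fj
  colnames(X) <- paste0("X", 1:6)
  if (!is.null(x7)) X <- cbind(X, X7 = as.numeric(x7))
  X
}
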