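#' Load genotypes and variant annotations from a VCF plus TSV sidecar
#'
#' Reads a diploid VCF (GT and, where present, DP/GQ per call) and joins a
#' variant annotation table keyed on the VCF ID column. Genotypes are
#' oriented to the minor allele of the reference panel: at sites where the
#' annotated reference-panel MAF exceeds 0.5 the copy numbers are flipped
#' (`2 - g`) and the frequency complemented, and the number of flipped sites
#' is reported. Calls carrying an ALT allele other than the first are set to
#' missing; the allele count of each site is kept for downstream QC.
#'
#' Case/control labels are taken from `phenotype` when given, otherwise
#' inferred from sample-name prefixes (`case...` vs anything else).
#'
#' @param path path to a VCF (v4.x) file, plain text or bgzipped.
#' @param annotations path to a TSV with columns `variant_id`, `gene_id`,
#'   `score` (functional score in `[0,1]`), `reference_MAF`, `consequence`.
#'   Variants without an annotation row are dropped with a warning.
#' @param phenotype optional; either a logical vector named by sample id
#'   (`TRUE` = case) or a two-column TSV (`sample_id`, `status` with status
#'   `case`/`control`).
#'
#' @return list with `gm` (an [genotype_matrix()] object) and `sites`
#'   (a `data.table` of per-variant annotations: `variant_id`, `gene_id`,
#'   `score`, `reference_MAF`, `sample_MAF`, `consequence`, plus `hwe_p`
#'   and `missing_rate` columns filled by [qc_filter()]).
#' @export
load_vcf <- function(path, annotations, phenotype = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("VCF contains no variant records: ", path)
  ids <- v@fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste(v@fix[noid, "CHROM"], v@fix[noid, "POS"],
                     v@fix[noid, "REF"], v@fix[noid, "ALT"], sep = ":")
  n_alleles <- 1L + lengths(strsplit(v@fix[, "ALT"], ",", fixed = TRUE))

  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- gt_to_counts(gt)
  rownames(geno) <- ids

  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  gq <- tryCatch(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(dp) && all(is.na(dp))) dp <- NULL
  if (!is.null(gq) && all(is.na(gq))) gq <- NULL

  anno <- data.table::fread(annotations, colClasses = list(character = "variant_id"))
  req <- c("variant_id", "gene_id", "score", "reference_MAF", "consequence")
  if (!all(req %in% names(anno)))
    stop("annotation TSV must have columns: ", paste(req, collapse = ", "))

  keep <- ids %in% anno$variant_id
  if (any(!keep))
    warning(sum(!keep), " variant(s) without annotation dropped")
  geno <- geno[keep, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[keep, , drop = FALSE]
  if (!is.null(gq)) gq <- gq[keep, , drop = FALSE]
  n_alleles <- n_alleles[keep]
  ids <- ids[keep]

  sites <- anno[match(ids, anno$variant_id), ]

  # orient to the reference panel's minor allele
  flip <- which(sites$reference_MAF > 0.5)
  if (length(flip)) {
    geno[flip, ] <- 2L - geno[flip, ]
    sites$reference_MAF[flip] <- 1 - sites$reference_MAF[flip]
    message(length(flip), " site(s) re-oriented to the reference minor allele")
  }

  if (is.null(phenotype)) {
    is_case <- startsWith(tolower(colnames(geno)), "case")
  } else if (is.character(phenotype) && length(phenotype) == 1L) {
    ph <- data.table::fread(phenotype)
    is_case <- tolower(ph$status)[match(colnames(geno), ph$sample_id)] == "case"
  } else {
    is_case <- as.logical(phenotype[colnames(geno)])
  }
  if (anyNA(is_case)) stop("phenotype missing for some samples")

  gm <- genotype_matrix(geno, is_case, dp = dp, gq = gq, n_alleles = n_alleles)
  sites$sample_MAF <- sample_maf(gm$geno)
  sites$hwe_p <- NA_real_
  sites$missing_rate <- rowMeans(is.na(geno))
  list(gm = gm, sites = sites)
}

# "0/1", "1|1", "./." etc -> copy number of allele 1; other ALT indices -> NA
gt_to_counts <- function(gt) {
  u <- unique(as.vector(gt))
  val <- vapply(u, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a) || any(a > 1L)) return(NA_integer_)  # non-first ALT -> no call
    sum(a)
  }, integer(1))
  m <- matrix(val[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

# in-sample allele frequency of the counted allele, ignoring missing calls
sample_maf <- function(geno) {
  rowSums(geno, na.rm = TRUE) / (2 * rowSums(!is.na(geno)))
}

#' Read a gene feature table
#'
#' Seven-column TSV: `gene_id`, `cds_length` (X1), `accumulated_maf` (X2),
#' `cds_times_maf` (X3), `oe_mis` (X4), `oe_lof` (X5), `gc_content` (X6).
#' Validates that X1 is positive, X3 = X1 * X2 and X6 lies in `[0,1]`.
#'
#' @param path TSV path.
#' @return `data.table` of gene feature records.
#' @export
read_gene_features <- function(path) {
  ft <- data.table::fread(path)
  req <- c("gene_id", "cds_length", "accumulated_maf", "cds_times_maf",
           "oe_mis", "oe_lof", "gc_content")
  if (!all(req %in% names(ft)))
    stop("feature TSV must have columns: ", paste(req, collapse = ", "))
  if (any(ft$cds_length <= 0)) stop("cds_length must be positive")
  rel <- abs(ft$cds_times_maf - ft$cds_length * ft$accumulated_maf) /
    pmax(abs(ft$cds_times_maf), 1e-300)
  if (any(ft$cds_times_maf != 0 & rel > 1e-9))
    stop("cds_times_maf must equal cds_length * accumulated_maf")
  if (any(ft$gc_content < 0 | ft$gc_content > 1))
    stop("gc_content must lie in [0, 1]")
  ft
}

#' Write a synthetic cohort to disk as VCF plus TSV sidecars
#'
#' Emits an uncompressed VCF v4.2 (GT only; the simulator produces clean
#' calls without DP/GQ) and the three annotation tables consumed by
#' [load_cohort()]: per-variant annotations, gene features and candidate
#' pair scores. Case status is encoded in the sample names so the files
#' round-trip without an extra phenotype sidecar.
#'
#' @param cohort a cohort object from [simulate_background()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- cohort$gm
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  nv <- nrow(gm$geno)
  samp <- ifelse(gm$is_case,
                 sprintf("case%05d", cumsum(gm$is_case)),
                 sprintf("ctrl%05d", cumsum(!gm$is_case)))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L],
                   nrow = nv)
  gt_str[is.na(gm$geno)] <- "./."
  body <- paste("1", seq_len(nv), gm$variant_id, "A", "G", ".", "PASS", ".",
                "GT", apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samp), collapse = "\t"))
  writeLines(c(header, body), vcf_path)

  anno_path <- file.path(dir, paste0(prefix, ".anno.tsv"))
  feat_path <- file.path(dir, paste0(prefix, ".features.tsv"))
  pair_path <- file.path(dir, paste0(prefix, ".pairs.tsv"))
  data.table::fwrite(cohort$sites[, c("variant_id", "gene_id", "score",
                                      "reference_MAF", "consequence")],
                     anno_path, sep = "\t")
  data.table::fwrite(cohort$features, feat_path, sep = "\t")
  data.table::fwrite(cohort$pairs[, c("gene_i", "gene_j", "pair_score")],
                     pair_path, sep = "\t")
  invisible(c(vcf = vcf_path, anno = anno_path,
              features = feat_path, pairs = pair_path))
}

#' Load a cohort from VCF plus sidecars
#'
#' Inverse of [write_cohort()]: assembles the in-memory cohort object the
#' analysis pipeline consumes from the on-disk representation.
#'
#' @param vcf,annotations,features,pairs file paths.
#' @param phenotype see [load_vcf()].
#' @return cohort list with `gm`, `sites`, `features`, `pairs`.
#' @export
load_cohort <- function(vcf, annotations, features, pairs, phenotype = NULL) {
  lv <- load_vcf(vcf, annotations, phenotype)
  pr <- data.table::fread(pairs)
  if (ncol(pr) < 3L) stop("pair file must have three columns")
  data.table::setnames(pr, 1:3, c("gene_i", "gene_j", "pair_score"))
  structure(list(gm = lv$gm, sites = lv$sites,
                 features = read_gene_features(features), pairs = pr),
            class = "eb_cohort")
}
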