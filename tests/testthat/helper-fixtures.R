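# Write a small VCF (optionally with DP/GQ) and matching annotation TSV.
write_toy_vcf <- function(dir, geno, samples, dp = NULL, gq = NULL,
                          ids = NULL, alt = NULL) {
  nv <- nrow(geno)
  ids <- ids %||% sprintf("rs%03d", seq_len(nv))
  alt <- alt %||% rep("G", nv)
  fmt <- "GT"
  if (!is.null(dp)) fmt <- paste0(fmt, ":DP")
  if (!is.null(gq)) fmt <- paste0(fmt, ":GQ")
  cell <- function(i, j) {
    g <- geno[i, j]
    s <- if (is.na(g)) "./." else c("0/0", "0/1", "1/1")[g + 1]
    if (!is.null(dp)) s <- paste0(s, ":", dp[i, j])
    if (!is.null(gq)) s <- paste0(s, ":", gq[i, j])
    s
  }
  body <- vapply(seq_len(nv), function(i) {
    paste(c("1", i, ids[i], "A", alt[i], ".", "PASS", ".", fmt,
            vapply(seq_along(samples), function(j) cell(i, j), character(1))),
          collapse = "\t")
  }, character(1))
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=1>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  path <- file.path(dir, "toy.vcf")
  writeLines(c(hdr, body), path)
  path
}

write_toy_anno <- function(dir, ids, gene = NULL, score = NULL,
                           ref_maf = NULL, consequence = NULL) {
  df <- data.frame(
    variant_id = ids,
    gene_id = gene %||% rep("GENEA", length(ids)),
    score = score %||% rep(0.5, length(ids)),
    reference_MAF = ref_maf %||% rep(0.001, length(ids)),
    consequence = consequence %||% rep("missense", length(ids)))
  path <- file.path(dir, "toy.anno.tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
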