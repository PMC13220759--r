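#' @importFrom stats optim optimize optimHess pnorm qbeta rbeta rbinom
#'   rlnorm rpois runif sd setNames uniroot var p.adjust dnbinom pnbinom
#' @importFrom data.table data.table as.data.table fread fwrite setnames CJ
NULL

.datatable.aware <- TRUE

#' Default gene exclusion list
#'
#' Genes with extremely long coding sequences whose rare-variant burden
#' dominates pair statistics; excluded from pair testing by default.
#' @export
LONG_GENE_EXCLUSIONS <- c("TTN", "MUC16", "OBSCN", "NEB",
                          "MUC19", "MUC4", "DST", "DNAH14")

#' Non-synonymous consequence categories
#'
#' The consequence classes retained by the rare-variant filter by default.
#' @export
NONSYN_CONSEQUENCES <- c("missense", "start-loss", "stop-loss", "stop-gain",
                         "splicing", "frameshift", "non-frameshift")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("eb_config_error", "error")))
}

# Derive independent per-replicate seeds (< 2^31) from one master seed.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
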