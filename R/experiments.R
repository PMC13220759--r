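#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta quantiles: the lower bound is
#' `qbeta(a/2, x, n - x + 1)` (0 when `x = 0`) and the upper bound
#' `qbeta(1 - a/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes,trials binomial outcome.
#' @param level confidence level.
#' @return numeric `c(low, high)`.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials <= 0) stop("trials must be positive")
  if (successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]")
  a <- 1 - level
  low <- if (successes == 0) 0 else qbeta(a / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1 else qbeta(1 - a / 2, successes + 1, trials - successes)
  c(low = low, high = high)
}

#' Type-I-error experiment on null cohorts
#'
#' Runs the full pipeline on independently simulated null cohorts and
#' summarizes calibration: the pooled fraction of background p-values
#' below each significance level, and the per-replicate mean log fold
#' change of the chosen cell's background p-values.
#'
#' @param n_samples cohort size per replicate.
#' @param n_reps number of replicates.
#' @param alphas significance levels for the empirical rates.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param b_grid,t_grid grid explored by [run_pipeline()]; the default is
#'   a reduced desk-scale grid.
#' @param ... further arguments passed to [simulate_background()] and
#'   [run_pipeline()] (matched by name against each).
#' @return list of class `eb_experiment`: `type1_rates`, `mlfc_mean`,
#'   `mlfc_sd`, `mlfc` (per replicate), `n_pairs_tested`, and the pooled
#'   background p-value count.
#' @export
type1_experiment <- function(n_samples, n_reps = 50L,
                             alphas = c(1e-3, 1e-4, 1e-5), seed = 1L,
                             b_grid = c(0.05, 0.1, 0.2), t_grid = 0:1,
                             ...) {
  dots <- list(...)
  sim_args <- dots[names(dots) %in% names(formals(simulate_background))]
  run_args <- c(list(b_grid = b_grid, t_grid = t_grid),
                dots[names(dots) %in% names(formals(run_pipeline))])
  seeds <- derive_seeds(seed, n_reps)
  mlfc_rep <- numeric(n_reps)
  n_pairs <- integer(n_reps)
  pooled <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    co <- do.call(simulate_background,
                  c(list(n_samples = n_samples, seed = seeds[r]), sim_args))
    run <- do.call(run_pipeline, c(list(cohort = co, qc = FALSE), run_args))
    bgp <- run$results$p_value[run$results$background]
    mlfc_rep[r] <- mlfc(bgp)
    pooled[[r]] <- run$results$p_value
    n_pairs[r] <- nrow(run$results)
  }
  pvals <- unlist(pooled)
  rates <- vapply(alphas, function(a) mean(pvals < a), numeric(1))
  structure(list(
    type1_rates = setNames(rates, format(alphas, scientific = TRUE)),
    alphas = alphas,
    mlfc = mlfc_rep, mlfc_mean = mean(mlfc_rep), mlfc_sd = sd(mlfc_rep),
    n_pairs_tested = n_pairs, n_pvalues = length(pvals),
    n_reps = n_reps, seed = seed
  ), class = "eb_experiment")
}

#' Power experiment for a planted causal gene pair
#'
#' For each replicate: simulate a null background cohort, plant one
#' causal variant pair in a target gene pair under a two-locus disease
#' model, run the full pipeline, and record the target pair's p-value.
#' Power is the fraction of replicates with p below `sig_level`, with a
#' Clopper-Pearson exact confidence interval.
#'
#' The background emulates an exome-scale candidate set (sparser
#' rare-variant spectrum over more genes than the type-I configuration,
#' keeping the background-fit floor satisfied through pair count). The
#' target pair emulates the compact interacting genes classically used in
#' recessive-parkinsonism digenic analyses (PARK7-like and PINK1-like
#' coding lengths of roughly 0.57 kb and 1.74 kb): the two background
#' genes with the closest CDS lengths are designated, cleared, and given
#' the causal variants.
#'
#' @param kind disease model (`"threshold"`, `"multiplicative"`,
#'   `"classic"`).
#' @param or genotype odds ratio of the maximal-risk genotype.
#' @param maf causal allele frequency.
#' @param n_samples total cohort size (balanced design).
#' @param prevalence disease prevalence `Pr(D)`.
#' @param n_reps replicates.
#' @param sig_level detection threshold on the target pair's p-value.
#' @param seed master seed.
#' @param n_genes,mean_variants background configuration (see
#'   [simulate_background()]).
#' @param target_cds CDS lengths (bp) the two target genes should
#'   approximate.
#' @param b_grid,t_grid grid explored by [run_pipeline()]; the default is
#'   a reduced desk-scale grid.
#' @param ... passed on to [simulate_background()] / [run_pipeline()].
#' @return list of class `eb_experiment`: `power`, `ci_low`, `ci_high`,
#'   per-replicate `p_target`, and the experiment settings.
#' @export
power_experiment <- function(kind, or, maf, n_samples,
                             prevalence = 0.01, n_reps = 50L,
                             sig_level = 0.05, seed = 1L,
                             n_genes = 212L, mean_variants = 5,
                             target_cds = c(570, 1743),
                             b_grid = c(0.05, 0.2), t_grid = 0:1,
                             ...) {
  dots <- list(...)
  sim_args <- dots[names(dots) %in% names(formals(simulate_background))]
  run_args <- c(list(b_grid = b_grid, t_grid = t_grid),
                dots[names(dots) %in% names(formals(run_pipeline))])
  model <- solve_alpha_theta(kind, prevalence, maf, or)
  seeds <- derive_seeds(seed, 2L * n_reps)
  p_target <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    co <- do.call(simulate_background,
                  c(list(n_samples = n_samples, seed = seeds[r],
                         n_genes = n_genes, mean_variants = mean_variants),
                    sim_args))
    ft <- co$features
    g1 <- ft$gene_id[which.min(abs(ft$cds_length - target_cds[1]))]
    g2 <- setdiff(ft$gene_id[order(abs(ft$cds_length - target_cds[2]))], g1)[1]
    target <- c(g1, g2)
    co <- insert_causal_pair(co, model, target = target,
                             seed = seeds[n_reps + r])
    run <- do.call(run_pipeline, c(list(cohort = co, qc = FALSE), run_args))
    hit <- run$results$gene_i == min(target) & run$results$gene_j == max(target)
    p_target[r] <- if (any(hit)) run$results$p_value[hit] else 1
  }
  n_detect <- sum(p_target < sig_level)
  ci <- clopper_pearson(n_detect, n_reps)
  structure(list(
    power = n_detect / n_reps, ci_low = ci[["low"]], ci_high = ci[["high"]],
    p_target = p_target, n_detected = n_detect,
    model = model, n_samples = n_samples, n_reps = n_reps,
    sig_level = sig_level, seed = seed
  ), class = "eb_experiment")
}

#' @export
print.eb_experiment <- function(x, ...) {
  if (!is.null(x$power)) {
    cat(sprintf("<eb_experiment> power %.1f%% (95%% CI %.2f%%-%.2f%%) over %d replicates\n",
                100 * x$power, 100 * x$ci_low, 100 * x$ci_high, x$n_reps))
  } else {
    cat(sprintf("<eb_experiment> type I error over %d replicates (%d pooled p-values)\n",
                x$n_reps, x$n_pvalues))
    print(signif(x$type1_rates, 3))
    cat(sprintf("  MLFC %.3f +/- %.3f\n", x$mlfc_mean, x$mlfc_sd))
  }
  invisible(x)
}
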