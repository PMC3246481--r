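#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Closed-form beta-quantile bounds: with `x` successes in `n` trials and
#' confidence `level`, the lower bound is `qbeta(a/2, x, n - x + 1)` (0 when
#' `x = 0`) and the upper `qbeta(1 - a/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes number of successes.
#' @param trials number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' round(binomial_ci(10, 100), 2)  # 0.05, 0.18
#' @export
binomial_ci <- function(successes, trials, level = 0.95) {
  stopifnot(trials >= 1, successes >= 0, successes <= trials,
            level > 0, level < 1)
  a <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(a / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - a / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Probability that a random gene set contains an associated gene
#'
#' With `n_associated` truly associated genes among `n_genome` genes, the
#' probability that a random set of `set_size` genes contains at least one of
#' them. The `"independent"` method uses the independent-draw approximation
#' `1 - (1 - n_associated / n_genome)^set_size`; the `"hypergeometric"`
#' method computes the exact without-replacement probability.
#'
#' @param n_genome genome-wide number of genes (default 20000).
#' @param n_associated number of associated genes (default 24).
#' @param set_size genes per random set (default 43).
#' @param method `"independent"` (default) or `"hypergeometric"`.
#' @return probability in `[0, 1]`.
#' @examples
#' prob_random_set_contains_associated()  # about 0.05
#' @export
prob_random_set_contains_associated <- function(n_genome = 20000,
                                                n_associated = 24,
                                                set_size = 43,
                                                method = c("independent",
                                                           "hypergeometric")) {
  method <- match.arg(method)
  stopifnot(n_associated >= 0, n_associated <= n_genome,
            set_size >= 0, set_size <= n_genome)
  if (n_associated == 0 || set_size == 0) return(0)
  if (method == "independent") {
    1 - (1 - n_associated / n_genome)^set_size
  } else {
    1 - exp(lchoose(n_genome - n_associated, set_size) -
              lchoose(n_genome, set_size))
  }
}

#' Type-I calibration of the pathway test on random gene sets
#'
#' Samples `n_sets` random gene sets (without replacement within a set, with
#' replacement across sets) from a gene universe, runs the full pathway
#' permutation test on each through the region-building path — so genes
#' containing no panel SNPs shrink the effective set size, exactly as they do
#' in practice — and reports the fraction of sets reaching nominal
#' significance together with its exact binomial confidence interval.
#'
#' @param panel a quality-controlled [genotype_panel()].
#' @param universe_genes data.frame of candidate genes (`gene`, `chrom`,
#'   `start`, `end`).
#' @param n_sets number of random sets (default 100).
#' @param genes_per_set genes sampled per set (default 43).
#' @param alpha nominal significance level applied to the empirical p-values
#'   (default 0.05; sets count when `p_emp < alpha`).
#' @param n_perm permutations per set (default 200).
#' @param seed RNG seed.
#' @param flank_bp flank used when building the sampled regions
#'   (default 100000).
#' @param statistic which set statistic to calibrate, `"SUMSTAT"` or
#'   `"SUMSQ"`.
#' @param mode gene scoring mode (see [run_pathway_test()]).
#' @param level confidence level of the interval (default 0.95).
#' @return object of class `calibration_result`: list with `n_sets`,
#'   `n_significant`, `rate`, `ci_lower`, `ci_upper`, `alpha`, `p_values`
#'   (per-set empirical p, `NA` for sets with no mapped SNP) and `k` (per-set
#'   effective number of scored regions).
#' @export
random_set_calibration <- function(panel, universe_genes, n_sets = 100,
                                   genes_per_set = 43, alpha = 0.05,
                                   n_perm = 200, seed = NULL,
                                   flank_bp = 100000,
                                   statistic = c("SUMSTAT", "SUMSQ"),
                                   mode = "max", level = 0.95) {
  statistic <- match.arg(statistic)
  universe_genes <- as.data.frame(universe_genes, stringsAsFactors = FALSE)
  if (n_sets < 1) stop("n_sets must be >= 1")
  if (nrow(universe_genes) < genes_per_set)
    stop("gene universe smaller than genes_per_set")
  if (!is.null(seed)) set.seed(seed)

  p_values <- rep(NA_real_, n_sets)
  k <- integer(n_sets)
  for (s in seq_len(n_sets)) {
    sampled <- universe_genes[sample.int(nrow(universe_genes), genes_per_set), ,
                              drop = FALSE]
    regions <- build_regions(sampled, flank_bp = flank_bp)
    mapped <- map_snps_to_regions(panel$snps, regions)
    if (nrow(mapped) == 0) next  # no SNP in the set: counts as non-significant
    res <- suppressMessages(run_pathway_test(
      panel, regions, sets = list(set = regions$region_id),
      n_perm = n_perm, mode = mode))
    row <- res$results[res$results$statistic == statistic, ]
    p_values[s] <- row$p_emp
    k[s] <- row$k
  }
  n_sig <- sum(p_values < alpha, na.rm = TRUE)
  ci <- binomial_ci(n_sig, n_sets, level = level)
  structure(list(n_sets = n_sets, n_significant = n_sig,
                 rate = n_sig / n_sets,
                 ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
                 alpha = alpha, statistic = statistic,
                 p_values = p_values, k = k),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "random-set calibration (%s): %d / %d sets with p_emp < %g\n",
    x$statistic, x$n_significant, x$n_sets, x$alpha))
  cat(sprintf("  type-I rate %.3f (95%% CI %.3f, %.3f)\n",
              x$rate, x$ci_lower, x$ci_upper))
  invisible(x)
}
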