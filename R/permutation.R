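#' Permute case-control labels within clusters
#'
#' Shuffles the phenotype labels independently inside every cluster, so the
#' multiset of labels per cluster — and therefore every cluster's case count —
#' is preserved exactly. This respects the stratified design: permuted
#' datasets retain the original geographic structure, and the permutation
#' null distribution is conditional on the per-cluster case totals.
#'
#' @param phenotype vector of labels (any type).
#' @param cluster cluster labels, same length.
#' @return permuted phenotype vector.
#' @export
permute_labels_within_clusters <- function(phenotype, cluster) {
  if (length(phenotype) != length(cluster))
    stop("phenotype and cluster lengths differ")
  out <- phenotype
  for (idx in split(seq_along(cluster), cluster)) {
    out[idx] <- phenotype[idx][sample.int(length(idx))]
  }
  out
}

# fast inner-loop variant on a precomputed index split
.permute01 <- function(y01, cluster_split) {
  out <- y01
  for (idx in cluster_split) {
    out[idx] <- y01[idx][sample.int(length(idx))]
  }
  out
}

#' Permutation empirical p-value
#'
#' Default estimator: the number of permuted statistics strictly exceeding
#' (or, with `better = "less"`, strictly below) the observed statistic,
#' divided by the number of permutations. Ties with the observed value do not
#' count as exceedances, and an observed statistic larger than every permuted
#' one yields p = 0. The positively biased `"add_one"` variant
#' `(r + 1) / (N + 1)`, which cannot return 0, is available as an opt-in.
#'
#' @param observed observed statistic (scalar).
#' @param permuted numeric vector of permuted statistics.
#' @param better direction in which the statistic is more extreme:
#'   `"greater"` (default) or `"less"`.
#' @param estimator `"exceedance"` (r/N, default) or `"add_one"`
#'   ((r+1)/(N+1)).
#' @return empirical p-value.
#' @examples
#' empirical_pvalue(4, c(3, 5, 2, 4))  # 0.25; the tie at 4 does not count
#' @export
empirical_pvalue <- function(observed, permuted,
                             better = c("greater", "less"),
                             estimator = c("exceedance", "add_one")) {
  better <- match.arg(better)
  estimator <- match.arg(estimator)
  if (length(permuted) < 1) stop("need at least one permuted value")
  if (is.na(observed)) return(NA_real_)
  r <- if (better == "greater") sum(permuted > observed, na.rm = TRUE)
       else sum(permuted < observed, na.rm = TRUE)
  n <- sum(!is.na(permuted))
  if (estimator == "exceedance") r / n else (r + 1) / (n + 1)
}

# region scores (max or second-best |z|) on the fast path; NA for regions
# with no converged SNP
.region_scores_fast <- function(absz, conv, region_snp_idx, mode) {
  vapply(region_snp_idx, function(idx) {
    v <- absz[idx][conv[idx]]
    if (length(v) == 0) return(NA_real_)
    if (mode == "max" || length(v) == 1) max(v) else sort(v, decreasing = TRUE)[2]
  }, 0)
}

#' Pathway permutation test (SUMSTAT / SUMSQ)
#'
#' Runs the full gene-set analysis: a per-SNP logistic association scan on
#' the observed labels, max-SNP (or second-best-SNP) scoring of each region,
#' and SUMSTAT / SUMSQ statistics for each set; then repeats the identical
#' pipeline on `n_perm` datasets whose case-control labels are permuted
#' within clusters (genotypes and covariates untouched), and reports the
#' empirical p-value of each set and statistic. All sets and both statistics
#' are evaluated on the same stream of permuted datasets, matching a design
#' in which whole datasets — not per-set draws — are permuted.
#'
#' Regions whose SNPs all fail to converge in a given (observed or permuted)
#' scan are dropped from that scan's effective k; an empty set contributes a
#' statistic of 0 for that scan.
#'
#' @param panel a quality-controlled [genotype_panel()].
#' @param regions regions from [build_regions()].
#' @param sets named list of region-id vectors; default [region_sets()] (the
#'   full set plus one set per subgroup).
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed; `NULL` continues the current RNG stream.
#' @param mode gene scoring mode, `"max"` (default) or `"second_best"`.
#' @param covariates extra covariates, as in [association_scan()].
#' @param estimator passed to [empirical_pvalue()].
#' @return object of class `pathway_permutation`: list with `results` (one
#'   row per set x statistic: `set`, `statistic`, `observed`, `p_emp`,
#'   `n_perm`, `k`), `permuted` (matrices of permuted statistics), plus the
#'   observed `associations` and `gene_scores`.
#' @export
run_pathway_test <- function(panel, regions, sets = NULL, n_perm = 5000,
                             seed = NULL, mode = c("max", "second_best"),
                             covariates = NULL,
                             estimator = c("exceedance", "add_one")) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sets)) sets <- region_sets(regions)

  mapping <- map_snps_to_regions(panel$snps, regions)
  if (nrow(mapping) == 0) stop("no panel SNP maps to any region")
  snp_idx <- match(mapping$snp_id, panel$snps$snp_id)
  pre <- .precompute_designs(panel, covariates, snp_idx)
  region_ids <- unique(mapping$region_id)
  region_snp_idx <- lapply(region_ids,
                           function(r) which(mapping$region_id == r))
  set_region_idx <- lapply(sets, function(s) which(region_ids %in% s))

  y <- case_indicator(panel)
  cluster_split <- split(seq_along(y), panel$samples$cluster)

  eval_stats <- function(y01) {
    s <- .scan_stats(pre, y01)
    sc <- .region_scores_fast(abs(s$z), s$converged, region_snp_idx, mode)
    list(scan = s, scores = sc,
         sumstat = unname(vapply(set_region_idx,
                                 function(i) sum(sc[i], na.rm = TRUE), 0)),
         sumsq = unname(vapply(set_region_idx,
                               function(i) sum(sc[i]^2, na.rm = TRUE), 0)),
         k = unname(vapply(set_region_idx,
                           function(i) sum(!is.na(sc[i])), 0L)))
  }

  obs <- eval_stats(y)
  n_sets <- length(sets)
  perm_sumstat <- matrix(NA_real_, n_perm, n_sets,
                         dimnames = list(NULL, names(sets)))
  perm_sumsq <- perm_sumstat
  for (b in seq_len(n_perm)) {
    pb <- eval_stats(.permute01(y, cluster_split))
    perm_sumstat[b, ] <- pb$sumstat
    perm_sumsq[b, ] <- pb$sumsq
  }

  results <- do.call(rbind, lapply(seq_len(n_sets), function(i) {
    data.frame(
      set = rep(names(sets)[i], 2),
      statistic = c("SUMSTAT", "SUMSQ"),
      observed = c(obs$sumstat[i], obs$sumsq[i]),
      p_emp = c(empirical_pvalue(obs$sumstat[i], perm_sumstat[, i],
                                 estimator = estimator),
                empirical_pvalue(obs$sumsq[i], perm_sumsq[, i],
                                 estimator = estimator)),
      n_perm = n_perm, k = obs$k[i], stringsAsFactors = FALSE)
  }))

  assoc <- data.frame(snp_id = pre$snp_id, beta = obs$scan$beta,
                      se = obs$scan$se, z = obs$scan$z, p = obs$scan$p,
                      n_used = obs$scan$n_used, converged = obs$scan$converged,
                      or = exp(obs$scan$beta),
                      or_lower = exp(obs$scan$beta - 1.96 * obs$scan$se),
                      or_upper = exp(obs$scan$beta + 1.96 * obs$scan$se),
                      stringsAsFactors = FALSE)
  gene_scores <- score_genes(assoc, mapping, mode = mode)

  structure(list(results = results, permuted = list(sumstat = perm_sumstat,
                                                    sumsq = perm_sumsq),
                 associations = assoc, gene_scores = gene_scores,
                 mapping = mapping, sets = sets, n_perm = n_perm,
                 mode = mode, estimator = estimator),
            class = "pathway_permutation")
}

#' @export
print.pathway_permutation <- function(x, ...) {
  cat(sprintf("pathway_permutation: %d set(s), %d permutations, mode '%s'\n",
              length(x$sets), x$n_perm, x$mode))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Squared genotypic correlation between two SNPs
#'
#' Composite linkage-disequilibrium measure: the squared Pearson correlation
#' of the minor-allele counts over jointly non-missing samples. Sign-blind,
#' so perfectly anti-correlated counts also give 1.
#'
#' @param genotypes_a,genotypes_b minor-allele count vectors.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(genotypes_a, genotypes_b) {
  if (length(genotypes_a) != length(genotypes_b)) stop("length mismatch")
  keep <- !is.na(genotypes_a) & !is.na(genotypes_b)
  if (sum(keep) < 2) stop("need >= 2 jointly non-missing samples")
  a <- genotypes_a[keep]; b <- genotypes_b[keep]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("SNP constant on the jointly non-missing subset")
  stats::cor(a, b)^2
}

# mean-p statistic for one scan: threshold selection + greedy LD pruning
# (ascending p, drop any SNP with r2 > r2_threshold against a retained SNP).
# Returns the sentinel 1.0 when nothing is selected (least extreme possible,
# since a valid mean of selected p-values is <= p_threshold < 1).
.meanp_stat <- function(p, conv, r2mat, p_threshold, r2_threshold) {
  sel <- which(conv & !is.na(p) & p <= p_threshold)
  if (length(sel) == 0) return(list(stat = 1.0, n_selected = 0L))
  sel <- sel[order(p[sel], sel)]
  kept <- integer(0)
  for (j in sel) {
    r2 <- r2mat[j, kept]
    if (length(kept) == 0 || all(is.na(r2) | r2 <= r2_threshold))
      kept <- c(kept, j)
  }
  list(stat = mean(p[kept]), n_selected = length(kept))
}

#' LD-pruned mean-p set test
#'
#' Alternative set statistic in the style of PLINK's set-based test: SNPs of
#' the set with association p-value at or below `p_threshold` are selected,
#' greedily pruned for linkage disequilibrium (iterating in ascending p
#' order, any later SNP with genotypic r-squared above `r2_threshold` against
#' an already retained SNP is discarded), and the mean p-value of the
#' retained SNPs is the set summary. Smaller means are more extreme, so the
#' empirical p-value counts permuted scans whose mean-p falls strictly below
#' the observed one; selection and pruning are re-run on every permuted scan.
#' Pairwise r-squared is computed once on the observed genotypes, which do
#' not change under label permutation.
#'
#' When the observed scan selects no SNP the statistic is undefined and the
#' test is reported as non-significant (`observed` and `p_emp` are `NA`, with
#' a warning). Permuted scans that select no SNP rank as least extreme.
#'
#' @param panel a quality-controlled [genotype_panel()].
#' @param regions regions from [build_regions()].
#' @param set_regions character vector of region ids forming the set;
#'   default all regions.
#' @param p_threshold inclusion threshold on the per-SNP p-value
#'   (default 0.05).
#' @param r2_threshold LD pruning threshold (default 0.5).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param covariates extra covariates, as in [association_scan()].
#' @return data.frame with one row: `set`, `statistic` (`"MEANP"`),
#'   `observed`, `p_emp`, `n_perm`, `n_snps_selected`; the permuted
#'   statistics are attached as attribute `permuted`.
#' @export
mean_p_set_test <- function(panel, regions, set_regions = NULL,
                            p_threshold = 0.05, r2_threshold = 0.5,
                            n_perm = 1000, seed = NULL, covariates = NULL) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            r2_threshold >= 0, r2_threshold <= 1, n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  mapping <- map_snps_to_regions(panel$snps, regions)
  if (!is.null(set_regions))
    mapping <- mapping[mapping$region_id %in% set_regions, , drop = FALSE]
  if (nrow(mapping) == 0) stop("no panel SNP maps to the requested set")
  snp_idx <- match(mapping$snp_id, panel$snps$snp_id)
  pre <- .precompute_designs(panel, covariates, snp_idx)

  G <- panel$genotypes[, snp_idx, drop = FALSE]
  r2mat <- suppressWarnings(
    stats::cor(G, use = "pairwise.complete.obs")^2)

  y <- case_indicator(panel)
  cluster_split <- split(seq_along(y), panel$samples$cluster)

  scan_stat <- function(y01) {
    s <- .scan_stats(pre, y01)
    .meanp_stat(s$p, s$converged, r2mat, p_threshold, r2_threshold)
  }
  obs <- scan_stat(y)
  permuted <- vapply(seq_len(n_perm), function(b)
    scan_stat(.permute01(y, cluster_split))$stat, 0)

  if (obs$n_selected == 0) {
    warning("no SNP passed the selection threshold on the observed data; ",
            "mean-p statistic undefined, reported as non-significant")
    observed <- NA_real_
    p_emp <- NA_real_
  } else {
    observed <- obs$stat
    p_emp <- empirical_pvalue(observed, permuted, better = "less")
  }
  out <- data.frame(set = "set", statistic = "MEANP", observed = observed,
                    p_emp = p_emp, n_perm = n_perm,
                    n_snps_selected = obs$n_selected,
                    stringsAsFactors = FALSE)
  attr(out, "permuted") <- permuted
  out
}
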