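#' Genotype call rate of a single SNP
#'
#' Fraction of samples with a non-missing genotype. The quality-control filter
#' applied by [apply_qc()] is strict: a SNP is excluded when its call rate is
#' strictly below the threshold, so a SNP at exactly the threshold passes.
#'
#' @param genotypes vector of minor-allele counts (0/1/2, `NA` missing).
#' @return call rate in `[0, 1]`.
#' @export
call_rate <- function(genotypes) {
  if (length(genotypes) < 1) stop("need at least one sample")
  mean(!is.na(genotypes))
}

#' Minor allele frequency of a single SNP
#'
#' Empirical allele frequency over non-missing genotypes, folded to `[0, 0.5]`
#' so it is a frequency of the rarer allele regardless of orientation.
#' Monomorphic SNPs have MAF 0. A SNP with no non-missing genotype has MAF
#' `NA`.
#'
#' @inheritParams call_rate
#' @return MAF in `[0, 0.5]`.
#' @export
snp_maf <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0) return(NA_real_)
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the observed allele counts: given the
#' number of minor alleles, the heterozygote count follows the standard exact
#' HWE distribution, and the p-value is the total probability of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count. Probabilities within a relative tolerance of 1e-7 of
#' the observed one are counted as ties and included, which makes the
#' symmetric-table ties deterministic in floating point.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (homozygous for one allele,
#'   heterozygous, homozygous for the other allele).
#' @return exact p-value in `(0, 1]`; monomorphic tables give 1.
#' @examples
#' hwe_exact_test(5, 50, 45)
#' hwe_exact_test(0, 0, 50)  # monomorphic: 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("need at least one genotyped sample")
  m <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # rarer allele count
  if (m == 0) return(1)
  h <- seq.int(m %% 2, m, by = 2)             # possible heterozygote counts
  # conditional log-probabilities up to a shared constant
  lp <- h * log(2) - lfactorial(h) - lfactorial((m - h) / 2) -
    lfactorial(n - (m + h) / 2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Cross-cluster allele-frequency heterogeneity test
#'
#' Pearson chi-squared test on the 2 x K table of minor/major allele counts
#' across K clusters, with K - 1 degrees of freedom (six geographic clusters
#' give the 5 d.f. test used for stratification screening). Clusters with a
#' zero allele total are dropped before computing the degrees of freedom. A
#' SNP that is monomorphic across all clusters carries no frequency
#' information and returns p = 1.
#'
#' @param allele_counts 2 x K matrix; row 1 minor-allele counts, row 2
#'   major-allele counts, one column per cluster.
#' @return p-value of the heterogeneity test.
#' @examples
#' heterogeneity_test(rbind(c(10, 30), c(90, 70)))
#' @export
heterogeneity_test <- function(allele_counts) {
  ac <- as.matrix(allele_counts)
  if (nrow(ac) != 2) stop("allele_counts must have two rows (minor, major)")
  ac <- ac[, colSums(ac) > 0, drop = FALSE]
  if (ncol(ac) < 2)
    stop("need at least two clusters with non-zero allele totals")
  if (any(rowSums(ac) == 0)) return(1)  # monomorphic everywhere
  suppressWarnings(stats::chisq.test(ac, correct = FALSE)$p.value)
}

# minor/major allele counts per cluster for one SNP
.allele_counts_by_cluster <- function(genotypes, cluster) {
  cl <- sort(unique(cluster))
  sapply(cl, function(k) {
    g <- genotypes[cluster == k]
    g <- g[!is.na(g)]
    c(minor = sum(g), major = 2 * length(g) - sum(g))
  })
}

#' Per-SNP quality control
#'
#' Applies the three SNP exclusion rules in a fixed order so every SNP is
#' counted exactly once:
#'
#' 1. call rate strictly below `callrate_min`;
#' 2. minor allele frequency strictly below `maf_min` (set `maf_min = 0` to
#'    disable MAF screening);
#' 3. exact HWE p-value below `hwe_alpha` **and** cross-cluster heterogeneity
#'    p-value above `heterogeneity_alpha` — i.e. the HWE deviation is only an
#'    exclusion when it cannot be attributed to allele-frequency
#'    stratification across clusters. With a single cluster the heterogeneity
#'    p is taken to be 1 (no stratification can explain the deviation).
#'
#' @param panel a [genotype_panel()].
#' @param callrate_min minimum call rate (default 0.97; strict `<` excludes).
#' @param hwe_alpha exact-HWE significance threshold (default 1e-5).
#' @param heterogeneity_alpha heterogeneity threshold gating the HWE rule
#'   (default 0.001).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_sample compute the HWE test on all samples (`"pooled"`, the
#'   default) or on controls only (`"controls_only"`).
#' @return list with elements `panel` (the SNPs with verdict `"pass"`) and
#'   `report`, a data.frame with one row per input SNP: `snp_id`, `call_rate`,
#'   `maf`, `hwe_p`, `heterogeneity_p`, `verdict` (one of `pass`,
#'   `excluded_callrate`, `excluded_maf`, `excluded_hwe`).
#' @examples
#' pan <- make_qc_fixture(20, 2, 1, seed = 1)
#' qc <- apply_qc(pan, maf_min = 0)
#' table(qc$report$verdict)
#' @export
apply_qc <- function(panel, callrate_min = 0.97, hwe_alpha = 1e-5,
                     heterogeneity_alpha = 0.001, maf_min = 0.01,
                     hwe_sample = c("pooled", "controls_only")) {
  hwe_sample <- match.arg(hwe_sample)
  stopifnot(callrate_min >= 0, callrate_min <= 1,
            hwe_alpha > 0, hwe_alpha < 1,
            heterogeneity_alpha > 0, heterogeneity_alpha < 1,
            maf_min >= 0, maf_min <= 0.5)
  m <- n_snps(panel)
  if (m == 0) {
    report <- data.frame(snp_id = character(), call_rate = numeric(),
                         maf = numeric(), hwe_p = numeric(),
                         heterogeneity_p = numeric(), verdict = character(),
                         stringsAsFactors = FALSE)
    return(list(panel = panel, report = report))
  }
  G <- panel$genotypes
  cluster <- panel$samples$cluster
  hwe_rows <- if (hwe_sample == "controls_only")
    panel$samples$phenotype == "control" else rep(TRUE, nrow(G))
  multi_cluster <- length(unique(cluster)) >= 2

  cr <- maf <- hwe_p <- het_p <- numeric(m)
  for (j in seq_len(m)) {
    g <- G[, j]
    cr[j] <- call_rate(g)
    maf[j] <- snp_maf(g)
    gh <- g[hwe_rows]
    gh <- gh[!is.na(gh)]
    hwe_p[j] <- if (length(gh) == 0) 1 else
      hwe_exact_test(sum(gh == 2), sum(gh == 1), sum(gh == 0))
    het_p[j] <- if (!multi_cluster) 1 else
      heterogeneity_test(.allele_counts_by_cluster(g, cluster))
  }
  maf_eff <- ifelse(is.na(maf), 0, maf)

  verdict <- rep("pass", m)
  verdict[cr < callrate_min] <- "excluded_callrate"
  idx <- verdict == "pass" & maf_eff < maf_min
  verdict[idx] <- "excluded_maf"
  idx <- verdict == "pass" & hwe_p < hwe_alpha & het_p > heterogeneity_alpha
  verdict[idx] <- "excluded_hwe"

  report <- data.frame(snp_id = panel$snps$snp_id, call_rate = cr, maf = maf,
                       hwe_p = hwe_p, heterogeneity_p = het_p,
                       verdict = verdict, stringsAsFactors = FALSE)
  list(panel = subset_panel_snps(panel, verdict == "pass"), report = report)
}
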