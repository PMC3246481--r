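test_that("within-cluster permutation conserves per-cluster label multisets", {
  set.seed(71)
  cluster <- rep(c("a", "b", "c"), c(5, 1, 8))
  phen <- c(rep(c("case", "control"), c(2, 3)), "case",
            rep(c("case", "control"), 4))
  for (r in 1:50) {
    perm <- permute_labels_within_clusters(phen, cluster)
    for (cl in unique(cluster)) {
      expect_equal(sum(perm[cluster == cl] == "case"),
                   sum(phen[cluster == cl] == "case"))
    }
  }
  # single-sample cluster: label fixed
  expect_equal(permute_labels_within_clusters(phen, cluster)[6], "case")
  # global case count conserved
  perm <- permute_labels_within_clusters(phen, cluster)
  expect_equal(sum(perm == "case"), sum(phen == "case"))
})

test_that("empirical p-value follows the strict-exceedance definition", {
  expect_equal(empirical_pvalue(4, c(3, 5, 2, 4)), 0.25)  # tie not counted
  expect_equal(empirical_pvalue(10, c(1, 2, 3)), 0)
  expect_equal(empirical_pvalue(0, c(1, 2, 3)), 1)
  expect_equal(empirical_pvalue(4, c(3, 5, 2, 4), estimator = "add_one"),
               2 / 5)
  expect_equal(empirical_pvalue(0.01, c(0.5, 0.001), better = "less"), 0.5)
  expect_error(empirical_pvalue(1, numeric(0)), "at least one")
  # p_emp * N is an integer count under the default estimator
  set.seed(5)
  for (r in 1:20) {
    perm <- rnorm(50)
    p <- empirical_pvalue(rnorm(1), perm)
    expect_equal(p * 50, round(p * 50))
  }
})

test_that("empirical p-value is antitone in the observed statistic", {
  set.seed(72)
  perm <- rnorm(100)
  obs <- sort(rnorm(20))
  p <- vapply(obs, empirical_pvalue, 0, permuted = perm)
  expect_true(all(diff(p) <= 0))
})

test_that("ld_r2 matches its definition and contracts", {
  set.seed(73)
  a <- rbinom(1000, 2, 0.3)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2L - a), 1)        # sign-blind
  b <- rbinom(1000, 2, 0.3)
  expect_lt(ld_r2(a, b), 0.02)             # independent SNPs
  expect_error(ld_r2(a, rep(1L, 1000)), "constant")
  expect_error(ld_r2(c(1, NA), c(NA, 1)), "non-missing")
  # missing entries are excluded pairwise
  a2 <- a; a2[1:100] <- NA
  expect_equal(ld_r2(a2, a), 1)
})

test_that("pathway test results are reproducible and shaped as documented", {
  h <- null_panel(seed = 74)
  r1 <- suppressMessages(run_pathway_test(h$panel, h$regions, n_perm = 30,
                                          seed = 10))
  r2 <- suppressMessages(run_pathway_test(h$panel, h$regions, n_perm = 30,
                                          seed = 10))
  expect_identical(r1$results, r2$results)
  expect_identical(r1$permuted, r2$permuted)
  expect_equal(nrow(r1$results), 2)        # All x {SUMSTAT, SUMSQ}
  expect_equal(dim(r1$permuted$sumstat), c(30, 1))
  expect_true(all(r1$results$p_emp * 30 == round(r1$results$p_emp * 30)))
  expect_true(all(r1$results$observed >= 0))
  # observed associations exposed for reporting
  expect_equal(nrow(r1$associations), n_snps(h$panel))
})

test_that("Monte-Carlo empirical p matches exhaustive enumeration (SUMSTAT/SUMSQ)", {
  tp <- tiny_panel()
  assigns <- enumerate_within_cluster_assignments(tp$panel$samples$phenotype,
                                                  tp$panel$samples$cluster)
  expect_equal(nrow(assigns), 36)          # choose(4,2)^2
  stats <- t(apply(assigns, 1, function(ph) {
    st <- set_stats_for_labels(tp$panel, tp$regions, ph)
    c(sumstat = st$sumstat, sumsq = st$sumsq)
  }))
  obs <- set_stats_for_labels(tp$panel, tp$regions, tp$panel$samples$phenotype)
  p_enum_sumstat <- mean(stats[, "sumstat"] > obs$sumstat)
  p_enum_sumsq <- mean(stats[, "sumsq"] > obs$sumsq)

  res <- suppressMessages(run_pathway_test(
    tp$panel, tp$regions, sets = list(All = tp$regions$region_id),
    n_perm = 5000, seed = 77))
  p_mc <- res$results$p_emp
  tol <- function(p) max(3 * sqrt(p * (1 - p) / 5000), 1e-12)
  expect_lt(abs(p_mc[res$results$statistic == "SUMSTAT"] - p_enum_sumstat),
            tol(p_enum_sumstat) + 1e-12)
  expect_lt(abs(p_mc[res$results$statistic == "SUMSQ"] - p_enum_sumsq),
            tol(p_enum_sumsq) + 1e-12)
})

test_that("mean-p selection, pruning and orientation follow the definitions", {
  # single selected SNP: the statistic is its p-value
  h <- null_panel(seed = 78, n_snps = 6, causal_log_or = log(2),
                  n_per_arm = 250)
  scan <- association_scan(h$panel)
  thr <- sort(scan$p)[1] * 1.001           # only the best SNP selected
  res <- mean_p_set_test(h$panel, h$regions, p_threshold = thr,
                         n_perm = 20, seed = 2)
  expect_equal(res$observed, min(scan$p))
  expect_equal(res$n_snps_selected, 1)

  # two perfectly correlated SNPs: the smaller-p one is retained
  pan <- h$panel
  G <- cbind(pan$genotypes, dup = pan$genotypes[, 1])
  snps <- rbind(pan$snps,
                data.frame(snp_id = "rs_dup", chrom = pan$snps$chrom[1],
                           pos = pan$snps$pos[1] + 1L, minor = "A",
                           major = "G"))
  pan2 <- genotype_panel(G, snps, pan$samples)
  res2 <- mean_p_set_test(pan2, h$regions, p_threshold = 1, r2_threshold = 0.5,
                          n_perm = 5, seed = 3)
  scan2 <- association_scan(pan2)
  r2 <- suppressWarnings(cor(pan2$genotypes, use = "pairwise.complete.obs")^2)
  expect_equal(res2$observed,
               meanp_oracle_stat(scan2$p, scan2$converged, r2, 1, 0.5))
  expect_equal(res2$n_snps_selected, sum(scan2$converged) - 1)

  # nothing selected on the observed data: warning, NA result
  expect_warning(
    res3 <- mean_p_set_test(h$panel, h$regions, p_threshold = 1e-12,
                            n_perm = 5, seed = 4),
    "non-significant")
  expect_true(is.na(res3$observed))
  expect_true(is.na(res3$p_emp))
})

test_that("Monte-Carlo mean-p empirical p matches exhaustive enumeration", {
  tp <- tiny_panel()
  p_threshold <- 0.6
  r2_threshold <- 0.5
  r2 <- suppressWarnings(cor(tp$panel$genotypes,
                             use = "pairwise.complete.obs")^2)
  stat_for <- function(ph) {
    pan <- genotype_panel(tp$panel$genotypes, tp$panel$snps,
                          transform(tp$panel$samples, phenotype = ph))
    scan <- association_scan(pan)
    meanp_oracle_stat(scan$p, scan$converged, r2, p_threshold, r2_threshold)
  }
  assigns <- enumerate_within_cluster_assignments(tp$panel$samples$phenotype,
                                                  tp$panel$samples$cluster)
  stats <- apply(assigns, 1, stat_for)
  obs <- stat_for(tp$panel$samples$phenotype)
  expect_false(is.na(obs))  # the fixture selects at least one SNP
  stats[is.na(stats)] <- 1                  # unselected scans rank least extreme
  p_enum <- mean(stats < obs)

  res <- mean_p_set_test(tp$panel, tp$regions, p_threshold = p_threshold,
                         r2_threshold = r2_threshold, n_perm = 5000, seed = 79)
  tol <- max(3 * sqrt(p_enum * (1 - p_enum) / 5000), 1e-12)
  expect_lt(abs(res$p_emp - p_enum), tol + 1e-12)
})
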