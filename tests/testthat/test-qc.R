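test_that("call rate exclusion is strict at the 0.97 boundary", {
  g <- rep(1L, 100)
  expect_equal(call_rate(g), 1)
  g[1:3] <- NA
  expect_equal(call_rate(g), 0.97)
  g[4] <- NA
  expect_equal(call_rate(g), 0.96)

  # boundary SNP passes, one more missing call fails
  mk <- function(n_miss) {
    G <- matrix(rep(c(0L, 1L, 2L, 1L), 25), ncol = 1)
    G[seq_len(n_miss), 1] <- NA
    genotype_panel(G, data.frame(snp_id = "rs1", chrom = "1", pos = 1L),
                   data.frame(sample_id = sprintf("s%d", 1:100),
                              phenotype = rep(c("case", "control"), 50),
                              cluster = rep(c("a", "b"), each = 50)))
  }
  expect_equal(apply_qc(mk(3), maf_min = 0)$report$verdict, "pass")
  expect_equal(apply_qc(mk(4), maf_min = 0)$report$verdict,
               "excluded_callrate")
})

test_that("exact HWE test: monomorphic, symmetry, and known table", {
  expect_equal(hwe_exact_test(0, 0, 50), 1)
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  expect_equal(hwe_exact_test(5, 50, 45), hwe_oracle(5, 50, 45))
  # allele-label swap leaves p unchanged
  expect_equal(hwe_exact_test(5, 50, 45), hwe_exact_test(45, 50, 5))
  expect_equal(hwe_exact_test(3, 7, 90), hwe_exact_test(90, 7, 3))
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("exact HWE test matches the recurrence oracle on a table sweep", {
  set.seed(42)
  for (rep in 1:300) {
    n <- sample(1:120, 1)
    n_Aa <- sample(0:n, 1)
    n_AA <- sample(0:(n - n_Aa), 1)
    n_aa <- n - n_Aa - n_AA
    expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
                 hwe_oracle(n_AA, n_Aa, n_aa), tolerance = 1e-9,
                 info = sprintf("(%d,%d,%d)", n_AA, n_Aa, n_aa))
  }
})

test_that("heterogeneity test reproduces the Pearson chi-squared value", {
  # hand computation: 2x2 table with chi^2 = 12.5 on 1 d.f.
  expect_equal(heterogeneity_test(rbind(c(10, 30), c(90, 70))),
               pchisq(12.5, df = 1, lower.tail = FALSE))
  # identical frequencies and totals: statistic 0, p = 1
  expect_equal(heterogeneity_test(rbind(c(20, 20, 20), c(80, 80, 80))), 1)
  # six clusters use 5 d.f.
  set.seed(1)
  minor <- rpois(6, 30)
  major <- rpois(6, 120)
  tab <- rbind(minor, major)
  stat <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  expect_equal(heterogeneity_test(tab),
               pchisq(unname(stat), df = 5, lower.tail = FALSE))
  # zero-total clusters are dropped before computing d.f.
  expect_equal(heterogeneity_test(cbind(tab, c(0, 0))),
               heterogeneity_test(tab))
  expect_error(heterogeneity_test(matrix(1:9, nrow = 3)), "two rows")
  expect_error(heterogeneity_test(rbind(c(5, 0), c(10, 0))), "two clusters")
  # monomorphic across all clusters carries no information
  expect_equal(heterogeneity_test(rbind(c(0, 0), c(50, 60))), 1)
})

test_that("HWE exclusion requires homogeneous cross-cluster frequencies", {
  set.seed(7)
  n_per <- 150
  # SNP 1: heterozygote deficit with the same frequency in both clusters ->
  # excluded; SNP 2: same deficit but very different cluster frequencies ->
  # deviation attributable to stratification, retained.
  draw_f <- function(f, n) {
    pr <- c((1 - f)^2 + 0.9 * f * (1 - f), 2 * f * (1 - f) * 0.1,
            f^2 + 0.9 * f * (1 - f))
    sample(0:2, n, replace = TRUE, prob = pr)
  }
  g1 <- as.integer(c(draw_f(0.35, n_per), draw_f(0.35, n_per)))
  g2 <- as.integer(c(draw_f(0.08, n_per), draw_f(0.6, n_per)))
  pan <- genotype_panel(
    cbind(g1, g2),
    data.frame(snp_id = c("hom", "strat"), chrom = "1", pos = c(1L, 2L)),
    data.frame(sample_id = sprintf("s%d", 1:(2 * n_per)),
               phenotype = rep(c("case", "control"), n_per),
               cluster = rep(c("a", "b"), each = n_per)))
  rep <- apply_qc(pan, maf_min = 0)$report
  expect_lt(rep$hwe_p[1], 1e-5)
  expect_gt(rep$heterogeneity_p[1], 0.001)
  expect_equal(rep$verdict[1], "excluded_hwe")
  expect_lt(rep$hwe_p[2], 1e-5)
  expect_lt(rep$heterogeneity_p[2], 0.001)
  expect_equal(rep$verdict[2], "pass")
})

test_that("QC verdicts partition the SNPs and QC is idempotent", {
  pan <- make_qc_fixture(40, 6, 3, seed = 11)
  qc <- apply_qc(pan, maf_min = 0)
  expect_equal(nrow(qc$report), 40)
  expect_equal(sum(table(qc$report$verdict)), 40)
  expect_equal(n_snps(qc$panel), sum(qc$report$verdict == "pass"))
  qc2 <- apply_qc(qc$panel, maf_min = 0)
  expect_identical(qc2$panel$snps$snp_id, qc$panel$snps$snp_id)
  expect_true(all(qc2$report$verdict == "pass"))
})

test_that("MAF screening is a separate verdict and empty panels are handled", {
  G <- cbind(a = c(0L, 0L, 0L, 1L), b = c(0L, 1L, 2L, 1L))
  pan <- genotype_panel(
    G, data.frame(snp_id = c("rare", "common"), chrom = "1", pos = 1:2),
    data.frame(sample_id = paste0("s", 1:4),
               phenotype = c("case", "case", "control", "control"),
               cluster = "a"))
  rep <- apply_qc(pan, maf_min = 0.2)$report
  expect_equal(rep$verdict, c("excluded_maf", "pass"))
  rep0 <- apply_qc(pan, maf_min = 0)$report
  expect_true(all(rep0$verdict == "pass"))

  pan0 <- pathperm:::subset_panel_snps(pan, logical(2))
  qc0 <- apply_qc(pan0)
  expect_equal(nrow(qc0$report), 0)
  expect_equal(n_snps(qc0$panel), 0)
})
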