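test_that("flanked overlapping genes merge into one region", {
  genes <- data.frame(gene = c("A", "B"), chrom = "1",
                      start = c(1000, 150000), end = c(2000, 160000))
  reg <- build_regions(genes, flank_bp = 100000)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$region_id, "A/B")
  expect_equal(reg$start, 1)        # flank floored at position 1
  expect_equal(reg$end, 260000)
  expect_equal(reg$n_genes, 2)

  # flank 0 and disjoint genes: no merging
  reg0 <- build_regions(genes, flank_bp = 0)
  expect_equal(nrow(reg0), 2)
  expect_equal(reg0$region_id, c("A", "B"))
})

test_that("region merging is order-independent and unions subgroups", {
  genes <- data.frame(
    gene = c("A", "B", "C", "D"), chrom = c("2", "2", "2", "7"),
    start = c(100000, 220000, 900000, 5000), end = c(150000, 260000, 950000, 9000),
    subgroups = c("Treg", "Secreted", "", "Treg"))
  reg1 <- build_regions(genes, flank_bp = 50000)
  set.seed(3)
  reg2 <- build_regions(genes[sample(4), ], flank_bp = 50000)
  expect_identical(reg1[c("region_id", "chrom", "start", "end")],
                   reg2[c("region_id", "chrom", "start", "end")])
  expect_equal(reg1$region_id, c("A/B", "C", "D"))
  expect_setequal(reg1$subgroups[[1]], c("Secreted", "Treg"))
  expect_equal(reg1$subgroups[[2]], character())
})

test_that("SNP-to-region mapping is inclusive at both boundaries", {
  genes <- data.frame(gene = "A", chrom = "1", start = 5000, end = 6000)
  reg <- build_regions(genes, flank_bp = 1000)   # region [4000, 7000]
  snps <- data.frame(snp_id = paste0("rs", 1:5),
                     chrom = c("1", "1", "1", "1", "9"),
                     pos = c(3999, 4000, 7000, 7001, 5000))
  mp <- map_snps_to_regions(snps, reg)
  expect_equal(mp$snp_id, c("rs2", "rs3"))       # boundaries included
  expect_false("rs5" %in% mp$snp_id)             # wrong chromosome
  expect_equal(attr(mp, "empty_regions"), character(0))
  mp2 <- map_snps_to_regions(snps[5, ], reg)
  expect_equal(attr(mp2, "empty_regions"), "A")
})

test_that("gene scoring: max and second-best modes, tie-break, drop rules", {
  assoc <- data.frame(
    snp_id = paste0("rs", 1:6),
    beta = 1, se = 1,
    z = c(1.2, -2.3, 0.4, 3.0, -3.0, 0.8),
    p = c(0.2, 0.02, 0.7, 0.001, 0.001, 0.4),
    n_used = 100, converged = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  mapping <- data.frame(snp_id = paste0("rs", 1:6),
                        region_id = c("R1", "R1", "R1", "R2", "R2", "R3"))
  sc <- suppressMessages(score_genes(assoc, mapping, mode = "max"))
  expect_equal(sc$score[sc$region_id == "R1"], 2.3)
  expect_equal(sc$best_snp_id[sc$region_id == "R1"], "rs2")
  # tie at |z| = 3: lowest snp_id wins the report, score unaffected
  expect_equal(sc$best_snp_id[sc$region_id == "R2"], "rs4")
  expect_equal(sc$score[sc$region_id == "R2"], 3.0)
  # all SNPs non-converged: region dropped from scoring
  expect_false("R3" %in% sc$region_id)
  expect_equal(sc$n_snps[sc$region_id == "R1"], 3)
  expect_equal(sc$n_snps_p05[sc$region_id == "R1"], 1)
  expect_equal(sc$min_p[sc$region_id == "R1"], 0.02)

  sc2 <- suppressMessages(score_genes(assoc, mapping, mode = "second_best"))
  expect_equal(sc2$score[sc2$region_id == "R1"], 1.2)
  expect_equal(sc2$score[sc2$region_id == "R2"], 3.0)

  # single-SNP region falls back to its only SNP in second_best mode
  one <- suppressMessages(score_genes(assoc[1, ], mapping[1, ],
                                      mode = "second_best"))
  expect_equal(one$score, 1.2)
})

test_that("set statistics are sums over scored regions only", {
  gs <- data.frame(region_id = c("R1", "R2", "R3"), best_snp_id = "x",
                   score = c(1.5, 2.0, 0.5), n_snps = 1, n_snps_p05 = 0,
                   min_p = 0.5)
  st <- set_statistics(gs, list(All = c("R1", "R2", "R3"),
                                Sub = c("R1", "R3"),
                                Missing = c("R9")))
  expect_equal(st$sumstat, c(4.0, 2.0, 0))
  expect_equal(st$sumsq, c(6.5, 2.5, 0))
  expect_equal(st$k, c(3, 2, 0))
  # singleton identity: SUMSTAT = sqrt(SUMSQ)
  s1 <- set_statistics(gs[2, ], list(one = "R2"))
  expect_equal(s1$sumstat, sqrt(s1$sumsq))
  expect_equal(s1$sumstat, 2.0)
})

test_that("Cauchy-Schwarz bounds hold for every computed set", {
  set.seed(9)
  for (r in 1:20) {
    k <- sample(1:10, 1)
    gs <- data.frame(region_id = paste0("R", 1:k), best_snp_id = "x",
                     score = abs(rnorm(k)), n_snps = 1, n_snps_p05 = 0,
                     min_p = 0.5)
    st <- set_statistics(gs, list(S = gs$region_id))
    expect_lte(st$sumsq, st$sumstat^2 + 1e-12)
    expect_lte(st$sumstat^2, st$k * st$sumsq + 1e-9)
  }
})

test_that("a subgroup's SUMSTAT never exceeds the full set's", {
  h <- null_panel(seed = 91, n_snps = 10, n_genes = 5)
  regions <- h$regions
  regions$subgroups <- I(lapply(seq_len(nrow(regions)), function(i)
    if (i <= 2) "Treg" else character()))
  res <- suppressMessages(run_pathway_test(h$panel, regions, n_perm = 5,
                                           seed = 1))
  obs <- res$results[res$results$statistic == "SUMSTAT", ]
  expect_lte(obs$observed[obs$set == "Treg"], obs$observed[obs$set == "All"])
})

test_that("region sets expose the full set plus one set per subgroup", {
  genes <- data.frame(gene = c("A", "B"), chrom = c("1", "2"),
                      start = c(100, 100), end = c(200, 200),
                      subgroups = c("Treg,Secreted", ""))
  reg <- build_regions(genes, flank_bp = 0)
  sets <- region_sets(reg)
  expect_named(sets, c("All", "Secreted", "Treg"))
  expect_equal(sets$All, reg$region_id)
  expect_equal(sets$Treg, "A")
})
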