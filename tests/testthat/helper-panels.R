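# Reusable synthetic inputs built in code.

# Four genes on one chromosome, far enough apart not to merge at 10 kb flank.
toy_genes <- function(n_genes = 4) {
  data.frame(gene = paste0("G", seq_len(n_genes)), chrom = "1",
             start = 2e6 * seq_len(n_genes),
             end = 2e6 * seq_len(n_genes) + 5e4,
             stringsAsFactors = FALSE)
}

# Stratified null panel: cluster-specific allele frequencies, no causal SNPs.
null_panel <- function(seed, n_clusters = 2, n_per_arm = 40, n_snps = 8,
                       n_genes = 4, causal_log_or = 0) {
  genes <- toy_genes(n_genes)
  snps <- data.frame(snp_id = sprintf("rs%03d", seq_len(n_snps)),
                     gene = rep(genes$gene, length.out = n_snps),
                     effect_log_or = c(causal_log_or,
                                       rep(0, n_snps - 1)),
                     stringsAsFactors = FALSE)
  set.seed(seed)
  maf <- matrix(stats::runif(n_snps * n_clusters, 0.15, 0.45),
                n_snps, n_clusters)
  cfg <- sim_config(
    clusters = data.frame(label = paste0("cl", seq_len(n_clusters)),
                          n_cases = n_per_arm, n_controls = n_per_arm,
                          baseline_log_odds = -0.5),
    snps = snps, maf = maf, genes = genes, seed = seed)
  list(panel = generate_panel(cfg), genes = genes,
       regions = build_regions(genes, flank_bp = 1e4))
}

# Fixed 8-sample, 2-cluster panel small enough to enumerate all within-cluster
# label assignments (choose(4,2)^2 = 36). Genotypes are hand-laid so each SNP
# varies within both clusters.
tiny_panel <- function() {
  G <- matrix(as.integer(c(
    # rs1 rs2 rs3
    2, 1, 0,
    1, 0, 1,
    0, 2, 2,
    1, 1, 0,
    2, 0, 1,
    0, 1, 0,
    1, 2, 2,
    0, 0, 1)), nrow = 8, byrow = TRUE)
  snps <- data.frame(snp_id = c("rs1", "rs2", "rs3"), chrom = "1",
                     pos = c(2005000L, 2010000L, 4010000L),
                     stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    phenotype = c("case", "case", "control", "control",
                  "case", "case", "control", "control"),
    cluster = rep(c("a", "b"), each = 4), stringsAsFactors = FALSE)
  panel <- genotype_panel(G, snps, samples)
  genes <- data.frame(gene = c("G1", "G2"), chrom = "1",
                      start = c(2e6, 4e6), end = c(2.05e6, 4.05e6),
                      stringsAsFactors = FALSE)
  list(panel = panel, genes = genes,
       regions = build_regions(genes, flank_bp = 1e4))
}

# Evaluate SUMSTAT/SUMSQ for an arbitrary phenotype vector through the
# public, one-shot pipeline (scan -> score -> set statistics).
set_stats_for_labels <- function(panel, regions, phenotype,
                                 mode = "max") {
  panel$samples$phenotype <- phenotype
  panel <- genotype_panel(panel$genotypes, panel$snps, panel$samples)
  assoc <- association_scan(panel)
  mapping <- map_snps_to_regions(panel$snps, regions)
  scores <- suppressMessages(score_genes(assoc, mapping, mode = mode))
  set_statistics(scores, list(All = regions$region_id))
}
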