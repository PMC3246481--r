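# pathperm

Pathway-level (SNP-set) association testing for stratified case-control
genome-wide association panels.

Individually weak susceptibility variants scattered across a biologically
coherent gene set — the motivating application is tumour-immunosuppression
genes in melanoma — can carry a detectable aggregate signal even when no
single SNP approaches genome-wide significance. `pathperm` implements the
max-SNP gene-set approach for this situation, end to end:

* **QC**: per-SNP call-rate, MAF, and exact Hardy-Weinberg screening, with
  the HWE rule gated by a cross-cluster allele-frequency heterogeneity test
  (a HWE deviation explicable by stratification is retained);
* **association**: per-SNP additive-model logistic regression with
  geographic-cluster indicator covariates (plus optional numeric covariates
  such as principal components), yielding Wald statistics
  `z = beta / se(beta)`;
* **gene sets**: gene intervals extended by 100 kb and merged when
  overlapping; each region scored by its maximal `|z|` (or second-best, as a
  robustness variant); set statistics `SUMSTAT = sum |z_j|` and
  `SUMSQ = sum z_j^2` over the `k` scored regions of each set;
* **inference**: empirical p-values from permutation of case-control labels
  *within clusters* (preserving every cluster's case count), re-running the
  whole scan–score–sum pipeline on each permuted dataset;
* **calibration & alternatives**: random-gene-set type-I calibration with
  exact (Clopper-Pearson) binomial intervals, an LD-pruned mean-p set test,
  and the analytic probability that a random gene set contains a truly
  associated gene;
* **simulation**: a stratified case-control genotype generator (cluster
  quotas, cluster-specific allele frequencies, additive causal effects,
  missingness, inbreeding-style HWE violations) so the full pipeline is
  testable with no external data.

Input formats are text pedigree/map pairs (cluster label in the family-ID
column) and a tab-separated gene-region file; a curated 43-gene
immunosuppression panel with approximate NCBI build-36 coordinates ships in
`inst/extdata/`. See the methods vignette
(`vignettes/pathway-permutation-methods.Rmd`) for the model, numerical
choices, and the generator's scope and limitations.

## Worked example

Simulate a six-cluster study over the packaged gene panel (two SNPs per
gene, one causal SNP at OR 1.6 in *TNFRSF18*), run QC, and test the full set
and every subgroup with 1000 within-cluster permutations:

```r
library(pathperm)

genes <- read_region_file(system.file("extdata",
  "immunosuppression_gene_panel.tsv", package = "pathperm"))
set.seed(1)
snps <- data.frame(snp_id = sprintf("rs%04d", 1:86),
                   gene = rep(genes$gene, each = 2),
                   effect_log_or = c(log(1.6), rep(0, 85)))
cfg <- sim_config(
  clusters = data.frame(label = c("sweden", "australia", "italy",
                                  "uk_netherlands", "france", "spain"),
                        n_cases = 50, n_controls = 120,
                        baseline_log_odds = -0.8),
  snps = snps, maf = matrix(runif(86 * 6, 0.15, 0.45), 86, 6),
  genes = genes, seed = 2026)
panel <- generate_panel(cfg)

qc <- apply_qc(panel)                       # all 86 SNPs pass here
regions <- build_regions(genes, flank_bp = 100000)  # 43 genes -> 39 regions
res <- run_pathway_test(qc$panel, regions, n_perm = 1000, seed = 7)
res
#> pathway_permutation: 6 set(s), 1000 permutations, mode 'max'
#>       set statistic   observed p_emp n_perm  k
#>       All   SUMSTAT  55.249126 0.003   1000 39
#>       All     SUMSQ 104.040324 0.000   1000 39
#>    Anergy   SUMSTAT   3.953579 0.682   1000  4
#>    Anergy     SUMSQ   5.230216 0.619   1000  4
#>    Costim   SUMSTAT  18.834357 0.018   1000 12
#>    Costim     SUMSQ  37.839380 0.017   1000 12
#>  Secreted   SUMSTAT  14.292693 0.084   1000 10
#>  Secreted     SUMSQ  24.352472 0.103   1000 10
#>       tDC   SUMSTAT  16.742115 0.067   1000 12
#>       tDC     SUMSQ  27.387091 0.111   1000 12
#>      Treg   SUMSTAT  24.894665 0.064   1000 18
#>      Treg     SUMSQ  47.285316 0.031   1000 18
```

Reading the output: `observed` is the set statistic on the real labels, `k`
the number of regions that contributed a score (regions with no converged
SNP drop out), and `p_emp` the fraction of the 1000 permuted datasets whose
statistic strictly exceeded the observed one. Here the full 39-region set is
clearly enriched (`p_emp = 0.003` — the embedded causal SNP plus chance
signal elsewhere), `p_emp = 0.000` means no permuted SUMSQ exceeded the
observed value, and the subgroup rows locate the signal without refitting
anything. Per-SNP results and per-region scores are in `res$associations`
and `res$gene_scores`; `run_full_analysis()` wraps the same pipeline around
file input/output plus a run manifest, and `inst/scripts/pathperm.R` exposes
it as a command line (`run`, `simulate`, `calibrate`, `meanp`).

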