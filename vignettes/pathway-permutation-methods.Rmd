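---
title: "Methods: pathway-level SNP-set testing by within-cluster permutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-level SNP-set testing by within-cluster permutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathperm)
```

## The statistical problem

Genome-wide association (GWA) scans of case-control panels are powered to
find common variants of moderate effect at stringent genome-wide
significance. Variants of small individual effect scattered across a
biologically coherent gene set — here, genes involved in
tumour-immunosuppression (regulatory T cells, T-cell anergy, costimulatory
receptors, tolerogenic dendritic cells, secreted suppressive factors) — can
remain individually indistinguishable from noise while carrying a detectable
signal in aggregate. `pathperm` implements a max-SNP gene-set test for this
situation, together with everything needed to run and stress-test it without
access to any real genotype data.

## The model and the test

For SNP $i$ with minor-allele count $g \in \{0,1,2\}$, disease status is
modelled by additive-coding logistic regression

$$\operatorname{logit} P(\text{case}) = \alpha + \beta_i g + \boldsymbol\gamma^\top \mathbf{c},$$

where $\mathbf{c}$ holds $K-1$ indicator covariates for the $K$ geographic
clusters (reference: first cluster in sorted label order) plus any
user-supplied numeric covariates such as principal components. The per-SNP
evidence is the Wald statistic $z_i = \hat\beta_i / \widehat{se}(\hat\beta_i)$.

Genes are represented by genomic regions: each gene interval is extended by
100 kb on both sides and overlapping (or abutting) flanked intervals on the
same chromosome are merged, so a cluster of co-located genes becomes one
region. Each region is scored by the maximal $|z_i|$ over its SNPs
(optionally the second-largest $|z_i|$, a variant less sensitive to a single
outlying SNP). For a set $S$ of $k$ scored regions,

$$\mathrm{SUMSTAT} = \sum_{j \in S} |z_j|, \qquad
  \mathrm{SUMSQ} = \sum_{j \in S} z_j^2 .$$

Significance is assessed empirically: case-control labels are permuted
*within clusters*, preserving every cluster's case count and hence the
stratified structure of the study; the full scan–score–sum pipeline is
re-run on each permuted dataset; and the empirical p-value is the number of
permuted statistics strictly exceeding the observed one divided by the
number of permutations. This estimator can return 0; the positively biased
$(r+1)/(N+1)$ variant is available as an opt-in (`estimator = "add_one"`).
All sets and both statistics are evaluated on one shared stream of permuted
datasets — whole datasets are permuted, not per-set draws — so subgroup
results are comparable across sets.

## Quality control

Per-SNP QC applies three rules in a fixed order, so every SNP receives
exactly one verdict:

1. **Call rate** below 0.97 (strict inequality: exactly 0.97 passes).
2. **MAF** below `maf_min` (default 0.01). The threshold is exposed because
   different designs screen at different levels; setting `maf_min = 0`
   disables the rule, which is how the 60 + 5 exclusion accounting of the
   packaged QC fixture is reproduced.
3. **Exact HWE** p below $10^{-5}$ *and* cross-cluster allele-frequency
   heterogeneity p above 0.001. The conjunction matters: a HWE deviation
   that co-occurs with strong frequency differences between clusters is
   plausibly an artefact of stratification rather than genotyping error, and
   the SNP is retained.

The exact HWE test conditions on the observed allele counts and sums the
probabilities of all heterozygote counts no more probable than the observed
one. Probabilities within a relative $10^{-7}$ of the observed one count as
ties and are included; this makes the symmetric-table ties deterministic in
floating point, and the test suite verifies exact agreement with an
independent recurrence-based enumeration for every genotype table up to
$n = 200$. HWE is computed on the pooled sample by default
(`hwe_sample = "controls_only"` is available) — with quota-sampled cases the
pooled genotype distribution is a case-enriched mixture, but for the
QC use of the test (flagging gross genotyping failure) the distinction is
immaterial and the pooled choice matches the exclusion accounting the
package reproduces. The heterogeneity test is a Pearson $\chi^2$ on the
2 × K minor/major allele-count table (df $K-1$; six clusters give the 5-df
screen); clusters with zero allele totals are dropped, and with a single
cluster the heterogeneity p is defined as 1 so that the HWE rule acts alone.

## Numerical choices in the regression

`stats::glm.fit` (IRLS) does the fitting, with deviance tolerance $10^{-8}$
and at most 100 iterations; on collapsible 2 × 2 data the estimates agree
with the log cross-product ratio and Woolf standard error to $10^{-6}$,
which the suite asserts. Samples missing a genotype are dropped for that SNP
only. Collinear covariates are removed deterministically by QR pivoting; if
the genotype column itself is aliased the fit is degenerate. Quasi-separated
fits are flagged by a heuristic guard ($|\hat\beta| > 15$ or
$\widehat{se} > 100$, or IRLS non-convergence) and excluded from gene
scoring rather than set to $z = 0$: a zero would deflate SUMSTAT by an
amount depending on which permutation happened to separate, whereas
exclusion mirrors the handling of missing genotypes (the region's k shrinks
for that scan). On the 8-sample enumeration fixtures used in testing this
guard fires regularly and identically on both the Monte-Carlo and the
exhaustive path, so the agreement checks cover it.

Ties in $|z|$ within a region are broken by lowest SNP id; this affects only
which SNP is *reported* as best, never the score.

## The mean-p alternative

The LD-pruned mean-p test uses no gene level: SNPs of the set with
association $p \le$ `p_threshold` (default 0.05) are ranked by p, greedily
pruned so that no retained pair has genotypic $r^2 >$ `r2_threshold`
(default 0.5; $r^2$ is computed once on the observed genotypes, which label
permutation does not change), and the mean p of the retained SNPs is the set
summary. Orientation is a documented choice: smaller means are more extreme,
so the empirical p counts permuted scans with a strictly smaller mean-p.
Scans selecting no SNP are ranked least extreme (internally a sentinel value
of 1, which exceeds any attainable mean of selected p-values); if the
*observed* scan selects nothing the statistic is undefined and the test is
reported as non-significant with a warning. The greedy-by-significance
pruning rule is itself a design decision — other prunings exist — and is
therefore re-implemented independently in the test suite's oracle.

## What the synthetic generator emulates — and what it does not

`generate_panel()` draws genotypes per cluster as binomial(2, $f$) counts
with cluster-specific frequencies, which produces exactly the
population-stratification structure the within-cluster permutation is
designed to respect. Phenotypes are assigned by rejection sampling against
the additive logistic model until each cluster's case and control quotas are
filled — the design is quota-based case-control, not prospective — with a
cap of $10^6$ candidate draws per cluster guarding non-termination. HWE
violations are induced by an inbreeding-style coefficient $F$ (heterozygote
probability scaled by $1-F$), a single monotone knob chosen because it
reaches the extreme heterozygote deficits that exact-HWE screening targets.
Missing genotypes are masked independently per entry at a per-SNP rate.
Minor-allele orientation is fixed at generation time (`A` minor, `G` major)
so allele-recoding behaviour is explicitly testable.

SNPs are generated independently: there is no linkage-disequilibrium block
structure (a perfectly duplicated SNP can be appended in tests to exercise
LD pruning), no haplotype phase, no genotyping-batch artefacts, and X
chromosome dosage is treated as autosomal (male hemizygosity is not
modelled; the gene panel includes X-linked genes and this naive handling is
a documented limitation). Passing tests on these panels therefore
demonstrates correctness of the statistical machinery under the stated
model, not robustness to LD, imputation error or differential genotyping —
on real data the permutation test remains valid (labels are exchangeable
within clusters under the null) but gene scores are correlated through LD in
ways these simulations do not probe.

`make_qc_fixture()` constructs panels with an exact, verified QC outcome
(so many low-call-rate SNPs, so many homogeneous HWE violators, everything
else clean) by redrawing any SNP whose realised genotypes violate its
intended verdict, with a bounded number of attempts.

## Study-condition sizes used by the checks

The packaged checks run at sizes chosen to exercise the documented designs
while remaining enumerable or quick to simulate; they are stated here as the
package's own reference conditions:

* QC accounting: 1178 SNPs across 6 clusters of 100 samples, with 60
  low-call-rate SNPs and 5 homogeneous HWE violators, leaving 1113 survivors.
* Region construction: the packaged 43-gene immunosuppression panel
  (approximate NCBI build-36 coordinates) with 100 kb flanks, collapsing to
  39 regions; its Secreted subgroup spans 10 regions.
* Exhaustive permutation oracle: 8 samples in 2 clusters of 4
  ($\binom{4}{2}^2 = 36$ label assignments), 3 SNPs in 2 regions, compared
  against 5000 Monte-Carlo permutations within three Monte-Carlo standard
  errors, for SUMSTAT, SUMSQ and mean-p.
* Type-I calibration: 200 independent null panels (2 clusters × 80 samples,
  8 SNPs in 4 genes, cluster-specific frequencies) × 200 permutations;
  the rejection fraction at $\alpha = 0.05$ must lie in the exact binomial
  99% acceptance band. Note the strict-exceedance estimator makes
  $P(p_{\mathrm{emp}} \le \alpha) = (\lfloor \alpha N\rfloor + 1)/(N+1)$,
  slightly above $\alpha$, which the band accommodates.
* Power: a causal SNP at OR $\in \{1.0, 1.3, 2.0\}$ in panels of 1000
  samples, 30 replicates with paired seeds; rejections must be monotone in
  the OR.

## Reproducibility

Every stochastic entry point takes a seed; `run_full_analysis()` derives
deterministic per-stage sub-seeds from its single top-level seed, so stages
are independently reproducible and a rerun of the same configuration is
byte-identical. The run manifest records configuration, input digests,
package version and the per-stage record counts (SNPs in → post-QC → mapped
→ scored regions per set).

## Known limitations

* No LD modelling in the generator; LD pruning is exercised only through
  constructed duplicates.
* X-chromosome dosage is naive (0/1/2 regardless of sex).
* The Wald statistic is used throughout (matching the coefficient/SE
  definition of the gene score); likelihood-ratio or score tests are not
  provided.
* Multi-allelic variants and binary pedigree formats are out of scope;
  phenotypes must be complete.
* With few permutations the empirical p has coarse granularity (multiples of
  $1/N$); choose `n_perm` accordingly, e.g. 5000 for p-values near $10^{-3}$.
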