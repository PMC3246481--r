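#' Describe a synthetic stratified case-control genotype study
#'
#' Bundles and validates everything [generate_panel()] needs: the cluster
#' layout (one stratum per geographic group, each with its own case and
#' control quota and baseline disease log-odds), the per-SNP generative
#' parameters, and optionally gene intervals used to place SNPs on the genome.
#'
#' Minor-allele frequencies may differ between clusters (`maf` as a matrix),
#' which is the population-stratification structure the within-cluster
#' permutation test is designed to respect. Per-SNP Hardy-Weinberg violations
#' are parameterised by an inbreeding-style coefficient `hwe_f` in `[-1, 1]`:
#' the heterozygote probability is scaled by `(1 - F)` with the excess mass
#' moved onto the homozygotes, so `F` near 1 produces the extreme heterozygote
#' deficits that the exact HWE test flags, identically in every cluster.
#'
#' @param clusters data.frame with columns `label`, `n_cases`, `n_controls`,
#'   `baseline_log_odds`.
#' @param snps data.frame with column `snp_id` and optional columns `gene`
#'   (symbol in `genes`, or `NA` for intergenic), `effect_log_or` (per-allele
#'   log odds ratio, default 0), `missing_rate` (default 0), `hwe_f`
#'   (default 0), `chrom`, `pos`.
#' @param maf minor-allele frequency specification: a single number, a vector
#'   of length `nrow(snps)` (shared across clusters), or a
#'   `nrow(snps) x nrow(clusters)` matrix of per-cluster frequencies, all
#'   strictly inside (0, 1).
#' @param genes optional data.frame with columns `gene`, `chrom`, `start`,
#'   `end` and optionally `subgroups` (comma-separated labels). SNPs with a
#'   `gene` but no explicit position are spread evenly inside their gene.
#' @param seed default RNG seed stored with the configuration.
#' @return object of class `sim_config`.
#' @examples
#' cfg <- sim_config(
#'   clusters = data.frame(label = c("uk", "se"), n_cases = c(30, 30),
#'                         n_controls = c(30, 30), baseline_log_odds = -1),
#'   snps = data.frame(snp_id = paste0("rs", 1:4)),
#'   maf = c(0.2, 0.3, 0.25, 0.4), seed = 1)
#' pan <- generate_panel(cfg)
#' @export
sim_config <- function(clusters, snps, maf, genes = NULL, seed = NULL) {
  clusters <- as.data.frame(clusters, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "n_cases", "n_controls", "baseline_log_odds") %in%
                  names(clusters)),
            "snp_id" %in% names(snps))
  if (anyDuplicated(clusters$label)) stop("duplicated cluster label")
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp_id")
  if (any(clusters$n_cases < 0) || any(clusters$n_controls < 0))
    stop("cluster quotas must be >= 0")
  if (any(clusters$n_cases + clusters$n_controls < 2))
    stop("each cluster needs at least 2 samples in total")

  if (!"effect_log_or" %in% names(snps)) snps$effect_log_or <- 0
  if (!"missing_rate" %in% names(snps)) snps$missing_rate <- 0
  if (!"hwe_f" %in% names(snps)) snps$hwe_f <- 0
  if (any(snps$missing_rate < 0 | snps$missing_rate >= 1))
    stop("missing_rate must be in [0, 1)")
  if (any(snps$hwe_f < -1 | snps$hwe_f > 1))
    stop("hwe_f must be in [-1, 1]")

  n_snp <- nrow(snps)
  n_cl <- nrow(clusters)
  maf <- if (is.matrix(maf)) maf else matrix(maf, nrow = n_snp, ncol = n_cl)
  if (nrow(maf) != n_snp || ncol(maf) != n_cl)
    stop("maf must be a scalar, a length-n_snps vector, or an n_snps x n_clusters matrix")
  if (any(maf <= 0 | maf >= 1))
    stop("allele frequencies must be strictly inside (0, 1)")
  # genotype class probabilities must stay valid under the inbreeding distortion
  phet <- 2 * maf * (1 - maf) * (1 - snps$hwe_f)
  pmin_hom <- maf^2 + snps$hwe_f * maf * (1 - maf)
  if (any(phet < 0) || any(pmin_hom < 0) || any(1 - phet - pmin_hom < 0))
    stop("hwe_f incompatible with allele frequency: negative genotype probability")

  if (!is.null(genes)) {
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
    if (any(genes$start > genes$end)) stop("gene start > end")
  }
  if ("gene" %in% names(snps)) {
    known <- snps$gene %in% c(genes$gene, NA)
    if (!all(known))
      stop("snp gene symbols not in gene_specs: ",
           paste(unique(snps$gene[!known]), collapse = ", "))
  } else {
    snps$gene <- NA_character_
  }
  # place SNPs: explicit chrom/pos wins, else evenly spaced inside the gene,
  # else a synthetic chromosome "0" grid for intergenic placeholders
  if (!"chrom" %in% names(snps)) snps$chrom <- NA_character_
  if (!"pos" %in% names(snps)) snps$pos <- NA_integer_
  for (j in seq_len(n_snp)) {
    if (!is.na(snps$pos[j])) next
    if (!is.na(snps$gene[j])) {
      gi <- genes[genes$gene == snps$gene[j], ][1, ]
      in_gene <- which(!is.na(snps$gene) & snps$gene == snps$gene[j])
      rank <- match(j, in_gene)
      snps$chrom[j] <- as.character(gi$chrom)
      snps$pos[j] <- as.integer(round(gi$start +
        rank * (gi$end - gi$start) / (length(in_gene) + 1)))
      if (snps$pos[j] < gi$start) snps$pos[j] <- as.integer(gi$start)
    } else {
      snps$chrom[j] <- "0"
      snps$pos[j] <- j * 1000L
    }
  }
  structure(list(clusters = clusters, snps = snps, maf = maf, genes = genes,
                 seed = seed),
            class = "sim_config")
}

# genotype probabilities (classes 0/1/2 minor-allele copies) under inbreeding F
.geno_probs <- function(f, F_coef) {
  p2 <- f^2 + F_coef * f * (1 - f)
  p1 <- 2 * f * (1 - f) * (1 - F_coef)
  cbind(p0 = 1 - p1 - p2, p1 = p1, p2 = p2)
}

# draw an m x n_snp genotype matrix given per-SNP class probabilities
.draw_genotypes <- function(m, probs) {
  n_snp <- nrow(probs)
  u <- matrix(stats::runif(m * n_snp), nrow = m)
  g <- matrix(0L, nrow = m, ncol = n_snp)
  for (j in seq_len(n_snp)) {
    g[, j] <- (u[, j] > probs[j, 1]) + (u[, j] > probs[j, 1] + probs[j, 2])
  }
  g
}

#' Generate a stratified case-control genotype panel
#'
#' Draws genotypes per cluster as binomial(2, f) counts of the minor allele,
#' optionally distorted by the per-SNP inbreeding coefficient, and assigns
#' phenotypes by rejection sampling against the additive logistic model
#' `logit P(case) = baseline + sum(beta * g)` until each cluster's case and
#' control quotas are filled exactly. Missing genotypes are then masked at the
#' per-SNP rate. The run is fully reproducible from the seed.
#'
#' Within each cluster the accepted samples are laid out cases first, then
#' controls. A cap of 1e6 candidate draws per cluster guards against
#' unfillable quotas (for example a strongly negative baseline with a large
#' case quota), which raise an error.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to the seed stored in `config`.
#' @return a [genotype_panel()]; minor allele is `"A"` and major `"G"` by
#'   generation-time convention.
#' @export
generate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cl <- config$clusters
  sn <- config$snps
  n_snp <- nrow(sn)
  beta <- sn$effect_log_or
  nz <- which(beta != 0)

  blocks <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    probs <- .geno_probs(config$maf[, i], sn$hwe_f)
    n_ca <- cl$n_cases[i]
    n_co <- cl$n_controls[i]
    if (length(nz) == 0) {
      # no genetic effect: phenotype independent of genotype, draw directly
      g <- .draw_genotypes(n_ca + n_co, probs)
    } else {
      got_ca <- matrix(0L, 0, n_snp)
      got_co <- matrix(0L, 0, n_snp)
      drawn <- 0
      cap <- 1e6
      while ((nrow(got_ca) < n_ca || nrow(got_co) < n_co) && drawn < cap) {
        need <- (n_ca - nrow(got_ca)) + (n_co - nrow(got_co))
        b <- min(max(4 * need, 64), cap - drawn)
        drawn <- drawn + b
        gb <- .draw_genotypes(b, probs)
        eta <- cl$baseline_log_odds[i] +
          as.vector(gb[, nz, drop = FALSE] %*% beta[nz])
        is_case <- stats::runif(b) < stats::plogis(eta)
        if (nrow(got_ca) < n_ca) {
          take <- which(is_case)[seq_len(min(sum(is_case), n_ca - nrow(got_ca)))]
          got_ca <- rbind(got_ca, gb[take, , drop = FALSE])
        }
        if (nrow(got_co) < n_co) {
          take <- which(!is_case)[seq_len(min(sum(!is_case), n_co - nrow(got_co)))]
          got_co <- rbind(got_co, gb[take, , drop = FALSE])
        }
      }
      if (nrow(got_ca) < n_ca || nrow(got_co) < n_co)
        stop(sprintf("cluster '%s': could not fill case/control quotas within %g draws",
                     cl$label[i], cap))
      g <- rbind(got_ca, got_co)
    }
    blocks[[i]] <- g
  }
  G <- do.call(rbind, blocks)

  # mask missing genotypes at the per-SNP rate
  mr <- sn$missing_rate
  for (j in which(mr > 0)) {
    G[stats::runif(nrow(G)) < mr[j], j] <- NA_integer_
  }

  phen <- unlist(lapply(seq_len(nrow(cl)), function(i)
    rep(c("case", "control"), c(cl$n_cases[i], cl$n_controls[i]))))
  clus <- rep(cl$label, cl$n_cases + cl$n_controls)
  samples <- data.frame(
    sample_id = sprintf("%s_%04d", clus, unlist(lapply(
      cl$n_cases + cl$n_controls, seq_len))),
    phenotype = phen, cluster = clus, stringsAsFactors = FALSE)
  snp_meta <- data.frame(snp_id = sn$snp_id, chrom = sn$chrom, pos = sn$pos,
                         minor = "A", major = "G", stringsAsFactors = FALSE)
  genotype_panel(G, snp_meta, samples)
}

#' Construct a panel with a prescribed quality-control outcome
#'
#' Builds a stratified panel (six clusters of equal size by default) in which
#' exactly `n_low_callrate` SNPs have call rate strictly below 0.97, exactly
#' `n_hwe_violating` SNPs show an extreme heterozygote deficit (exact HWE
#' p < 1e-5) with homogeneous cross-cluster allele frequencies (heterogeneity
#' p > 0.001), and every remaining SNP passes all filters. The HWE violation
#' is induced by an inbreeding coefficient near 1 applied identically in all
#' clusters; construction is verified against the realised genotypes and
#' offending SNPs are redrawn (bounded number of attempts, then an error).
#'
#' @param n_total_snps total SNP count.
#' @param n_low_callrate number of SNPs with call rate below 0.97.
#' @param n_hwe_violating number of HWE-violating (but homogeneous) SNPs.
#' @param seed RNG seed.
#' @param n_clusters number of clusters (default 6).
#' @param samples_per_cluster samples per cluster, half cases half controls
#'   (default 100).
#' @return a [genotype_panel()].
#' @examples
#' pan <- make_qc_fixture(30, 3, 2, seed = 7)
#' sum(apply_qc(pan, maf_min = 0)$report$verdict == "pass")  # 25
#' @export
make_qc_fixture <- function(n_total_snps, n_low_callrate, n_hwe_violating,
                            seed, n_clusters = 6, samples_per_cluster = 100) {
  stopifnot(n_low_callrate >= 0, n_hwe_violating >= 0,
            n_low_callrate + n_hwe_violating <= n_total_snps,
            n_clusters >= 2, samples_per_cluster >= 4)
  set.seed(seed)
  n <- n_clusters * samples_per_cluster
  cluster <- rep(sprintf("cluster%d", seq_len(n_clusters)),
                 each = samples_per_cluster)
  phen <- rep(rep(c("case", "control"), each = samples_per_cluster / 2),
              n_clusters)

  status <- sample(c(rep("lowcall", n_low_callrate),
                     rep("hwe", n_hwe_violating),
                     rep("pass", n_total_snps - n_low_callrate - n_hwe_violating)))
  G <- matrix(NA_integer_, nrow = n, ncol = n_total_snps)
  n_mask <- ceiling(0.035 * n)  # call rate 1 - 0.035 < 0.97, strictly

  draw_ok <- function(kind) {
    for (attempt in 1:200) {
      if (kind == "hwe") {
        f <- stats::runif(1, 0.25, 0.45)
        pr <- .geno_probs(f, 0.95)
        u <- stats::runif(n)
        g <- (u > pr[1]) + (u > pr[1] + pr[2])
      } else {
        f <- stats::runif(1, 0.15, 0.45)
        g <- stats::rbinom(n, 2, f)
      }
      gi <- as.integer(g)
      hp <- hwe_exact_test(sum(gi == 2), sum(gi == 1), sum(gi == 0))
      het <- heterogeneity_test(.allele_counts_by_cluster(gi, cluster))
      maf <- snp_maf(gi)
      ok <- if (kind == "hwe")
        hp < 1e-5 && het > 0.001 && maf >= 0.01
      else
        hp >= 1e-5 && maf >= 0.01
      if (ok) return(gi)
    }
    stop("make_qc_fixture: could not realise a '", kind,
         "' SNP within 200 attempts")
  }

  for (j in seq_len(n_total_snps)) {
    kind <- if (status[j] == "hwe") "hwe" else "pass"
    G[, j] <- draw_ok(kind)
    if (status[j] == "lowcall") {
      G[sample.int(n, n_mask), j] <- NA_integer_
    }
  }

  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(n_total_snps)),
                     chrom = "1", pos = 10000L * seq_len(n_total_snps),
                     minor = "A", major = "G", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("s%05d", seq_len(n)),
                        phenotype = phen, cluster = cluster,
                        stringsAsFactors = FALSE)
  genotype_panel(G, snps, samples)
}
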