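#' Construct a case-control genotype panel
#'
#' A genotype panel bundles a sample-by-SNP matrix of minor-allele counts with
#' the SNP and sample metadata the downstream association machinery needs.
#' Genotypes are coded 0/1/2 (copies of the minor allele) with `NA` for a
#' missing call. Every sample carries a phenotype (`"case"` or `"control"`)
#' and a cluster label (the geographic stratum used both as a regression
#' covariate and as the permutation block); additional numeric columns in
#' `samples` (for example pre-computed principal components) can be passed to
#' the association functions as extra covariates.
#'
#' X-chromosome genotypes receive no special treatment: male hemizygous calls
#' must already be coded on the 0/1/2 scale by the caller. This mirrors the
#' naive autosomal handling of the analysis the package implements and is a
#' documented limitation.
#'
#' @param genotypes numeric or integer matrix, samples in rows, SNPs in
#'   columns; entries in `{0, 1, 2, NA}`.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based
#'   base-pair position) and optionally `minor`, `major` (allele letters).
#' @param samples data.frame with columns `sample_id`, `phenotype`
#'   (`"case"`/`"control"`) and `cluster`; extra numeric columns are kept.
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes`, `snps`, `samples`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 1L), nrow = 2,
#'             dimnames = list(NULL, c("rs1", "rs2")))
#' snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L))
#' samples <- data.frame(sample_id = c("s1", "s2"),
#'                       phenotype = c("case", "control"), cluster = "uk")
#' genotype_panel(g, snps, samples)
#' @export
genotype_panel <- function(genotypes, snps, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  req_snp <- c("snp_id", "chrom", "pos")
  if (!all(req_snp %in% names(snps)))
    stop("`snps` must have columns: ", paste(req_snp, collapse = ", "))
  req_sam <- c("sample_id", "phenotype", "cluster")
  if (!all(req_sam %in% names(samples)))
    stop("`samples` must have columns: ", paste(req_sam, collapse = ", "))
  if (nrow(samples) != nrow(genotypes))
    stop("nrow(genotypes) must equal nrow(samples)")
  if (nrow(snps) != ncol(genotypes))
    stop("ncol(genotypes) must equal nrow(snps)")
  if (!all(genotypes %in% c(0L, 1L, 2L, NA_integer_)))
    stop("genotypes must be 0, 1, 2 or NA")
  if (anyDuplicated(snps$snp_id))
    stop("duplicated snp_id")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id")
  if (any(snps$pos < 1))
    stop("SNP positions must be >= 1")
  if (anyNA(samples$phenotype) || anyNA(samples$cluster))
    stop("phenotype and cluster must be non-missing for all samples")
  if (!all(samples$phenotype %in% c("case", "control")))
    stop("phenotype must be 'case' or 'control'")
  if (!"minor" %in% names(snps)) snps$minor <- "A"
  if (!"major" %in% names(snps)) snps$major <- "G"
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)

  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- snps$snp_id
  structure(list(genotypes = genotypes, snps = snps, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  ph <- table(x$samples$phenotype)
  cat(sprintf("genotype_panel: %d samples x %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  cases: %d  controls: %d  clusters: %d (%s)\n",
              sum(x$samples$phenotype == "case"),
              sum(x$samples$phenotype == "control"),
              length(unique(x$samples$cluster)),
              paste(utils::head(sort(unique(x$samples$cluster)), 6),
                    collapse = ", ")))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' Number of samples / SNPs in a panel
#' @param panel a `genotype_panel`
#' @return integer count.
#' @export
n_samples <- function(panel) nrow(panel$genotypes)

#' @rdname n_samples
#' @export
n_snps <- function(panel) ncol(panel$genotypes)

# 0/1 case indicator in sample order
case_indicator <- function(panel) {
  as.integer(panel$samples$phenotype == "case")
}

# keep a subset of SNP columns (logical or index vector)
subset_panel_snps <- function(panel, keep) {
  genotype_panel(panel$genotypes[, keep, drop = FALSE],
                 panel$snps[keep, , drop = FALSE],
                 panel$samples)
}

# replace the phenotype vector (used by permutation machinery / tests)
set_phenotype <- function(panel, phenotype) {
  panel$samples$phenotype <- phenotype
  genotype_panel(panel$genotypes, panel$snps, panel$samples)
}
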