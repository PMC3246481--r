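#' Read a text pedigree/map file pair into a genotype panel
#'
#' Reads the classic whitespace-separated pedigree dialect: six leading
#' columns (family ID, individual ID, father, mother, sex, phenotype) followed
#' by two allele letters per SNP, with `0` denoting a missing allele. The
#' companion map file has four columns (chromosome, SNP id, genetic distance,
#' base-pair position, 1-based). Conventions:
#'
#' * phenotype `1` = control, `2` = case (anything else is an error — the
#'   analysis requires complete phenotypes);
#' * the cluster label is carried in the family-ID column, so a single file
#'   pair is a complete stratified dataset;
#' * a genotype with any missing allele (`0`) is a missing call;
#' * the minor allele is determined empirically from the pooled allele
#'   counts, with a deterministic tie-break at frequency exactly 0.5: the
#'   lexicographically smaller allele is minor;
#' * monomorphic SNPs are allowed (MAF 0, minor allele `NA`);
#' * more than two observed alleles at a SNP is an error.
#'
#' @param ped_path path to the pedigree file.
#' @param map_path path to the map file.
#' @return a [genotype_panel()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("pedigree file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"),
                           col.names = c("chrom", "snp_id", "cm", "pos"),
                           stringsAsFactors = FALSE)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0) stop("empty pedigree file")

  fields <- strsplit(trimws(lines), "[ \t]+")
  n_expect <- 6 + 2 * m
  bad <- which(lengths(fields) != n_expect)
  if (length(bad))
    stop(sprintf("pedigree line %d: expected %d fields, found %d",
                 bad[1], n_expect, length(fields[[bad[1]]])))
  ped <- matrix(unlist(fields), nrow = n, byrow = TRUE)

  phen_code <- ped[, 6]
  if (!all(phen_code %in% c("1", "2")))
    stop("phenotype codes must be 1 (control) or 2 (case); line ",
         which(!phen_code %in% c("1", "2"))[1])
  samples <- data.frame(sample_id = ped[, 2],
                        phenotype = ifelse(phen_code == "2", "case", "control"),
                        cluster = ped[, 1], stringsAsFactors = FALSE)

  G <- matrix(NA_integer_, nrow = n, ncol = m)
  minor <- major <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    a1 <- ped[, 5 + 2 * j]
    a2 <- ped[, 6 + 2 * j]
    miss <- a1 == "0" | a2 == "0"
    alleles <- c(a1[!miss], a2[!miss])
    if (length(alleles) == 0) next  # fully missing SNP
    tab <- table(alleles)
    if (length(tab) > 2)
      stop("SNP ", map$snp_id[j], ": more than two alleles observed")
    if (length(tab) == 1) {
      major[j] <- names(tab)          # monomorphic: minor allele unknown
      G[!miss, j] <- 0L
      next
    }
    nms <- names(tab)
    minor[j] <- if (tab[1] == tab[2]) min(nms) else nms[which.min(tab)]
    major[j] <- setdiff(nms, minor[j])
    G[!miss, j] <- (a1[!miss] == minor[j]) + (a2[!miss] == minor[j])
  }
  snps <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                     minor = minor, major = major, stringsAsFactors = FALSE)
  genotype_panel(G, snps, samples)
}

#' Write a genotype panel as a text pedigree/map file pair
#'
#' Inverse of [read_plink_text()]: the cluster label goes to the family-ID
#' column, phenotype is coded 1/2, missing genotypes become `0 0`, and each
#' genotype count g is written as g copies of the minor allele and 2 - g of
#' the major. SNPs with an unknown minor allele (monomorphic) are written
#' with the major allele only.
#'
#' @param panel a [genotype_panel()].
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_plink_text <- function(panel, ped_path, map_path) {
  snps <- panel$snps
  utils::write.table(
    data.frame(snps$chrom, snps$snp_id, 0, snps$pos),
    map_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  G <- panel$genotypes
  n <- nrow(G); m <- ncol(G)
  minor <- ifelse(is.na(snps$minor), snps$major, snps$minor)
  major <- snps$major
  al <- matrix("0", nrow = n, ncol = 2 * m)
  for (j in seq_len(m)) {
    g <- G[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, minor[j], major[j]))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, minor[j], major[j]))
    al[, 2 * j - 1] <- a1
    al[, 2 * j] <- a2
  }
  lead <- cbind(panel$samples$cluster, panel$samples$sample_id, "0", "0", "0",
                ifelse(panel$samples$phenotype == "case", "2", "1"))
  writeLines(apply(cbind(lead, al), 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a tab-separated gene-region definition file
#'
#' Expected header columns: `gene`, `chrom`, `start`, `end`, `subgroups`
#' (comma-separated labels; an empty field means the gene belongs only to the
#' full set). Coordinates are 1-based inclusive. Records are returned in file
#' order. Unknown subgroup labels and records with `start > end` are errors.
#'
#' @param path file path.
#' @param allowed_subgroups the subgroup vocabulary (default the five
#'   immunosuppression subgroups `Treg`, `Anergy`, `Costim`, `tDC`,
#'   `Secreted`); pass `NULL` to accept any label.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end` and list
#'   column `subgroups`.
#' @export
read_region_file <- function(path,
                             allowed_subgroups = c("Treg", "Anergy", "Costim",
                                                   "tDC", "Secreted")) {
  if (!file.exists(path)) stop("region file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "start", "end")
  if (!all(req %in% names(df)))
    stop("region file must have columns: ", paste(req, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end)) stop("non-numeric start/end")
  if (any(df$start > df$end))
    stop("start > end for gene ", df$gene[which(df$start > df$end)[1]])
  sg <- if ("subgroups" %in% names(df)) df$subgroups else
    rep("", nrow(df))
  sg <- lapply(sg, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) character() else
      trimws(strsplit(x, ",")[[1]])
  })
  if (!is.null(allowed_subgroups)) {
    unknown <- setdiff(unique(unlist(sg)), allowed_subgroups)
    if (length(unknown))
      stop("unknown subgroup label(s): ", paste(unknown, collapse = ", "))
  }
  out <- df[c("gene", "chrom", "start", "end")]
  out$subgroups <- I(sg)
  out
}

# format a data.frame with fixed numeric precision and write as TSV
.write_tsv <- function(df, path, digits = 6) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.list(df[[nm]]))
      df[[nm]] <- vapply(df[[nm]], paste, "", collapse = ",")
    else if (is.double(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write analysis result tables
#'
#' Serialises the result tables of a pipeline run as TSV files under
#' `out_dir`: `qc_report.tsv`, `associations.tsv`, `gene_scores.tsv`,
#' `set_pvalues.tsv` (whichever are present in `tables`). Numbers are
#' written with a fixed significant-digit precision so reruns are
#' byte-identical; the files round-trip through [read_results()].
#'
#' @param tables named list with any of the elements `qc_report`,
#'   `associations`, `gene_scores`, `set_pvalues` (data.frames).
#' @param out_dir output directory (created if needed).
#' @param digits significant digits for floating-point columns (default 6).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, digits = 6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  known <- c("qc_report", "associations", "gene_scores", "set_pvalues")
  paths <- character()
  for (nm in intersect(known, names(tables))) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    .write_tsv(tables[[nm]], p, digits = digits)
    paths[nm] <- p
  }
  invisible(paths)
}

#' @rdname write_results
#' @return `read_results()` returns the named list of tables found in
#'   `out_dir`.
#' @export
read_results <- function(out_dir) {
  known <- c("qc_report", "associations", "gene_scores", "set_pvalues")
  out <- list()
  for (nm in known) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    if (file.exists(p))
      out[[nm]] <- utils::read.delim(p, stringsAsFactors = FALSE)
  }
  out
}
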