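# canonical chromosome ordering: autosomes numerically, then X, Y, XY, MT,
# then anything else alphabetically
.order_chroms <- function(u) {
  u <- unique(as.character(u))
  num <- suppressWarnings(as.integer(u))
  sp <- match(u, c("X", "Y", "XY", "MT", "M"))
  grp <- ifelse(!is.na(num), 0L, ifelse(!is.na(sp), 1L, 2L))
  u[order(grp, num, sp, u)]
}

#' Build flanked, merged gene regions
#'
#' Extends every gene interval by `flank_bp` on each side (floored at
#' position 1), then merges same-chromosome intervals that overlap or abut
#' transitively into single regions. A merged region spans the union of its
#' members' flanked intervals, carries the union of their subgroup labels,
#' and is identified by the member gene symbols joined with `/` in genomic
#' order. Regions are returned sorted by chromosome, then start.
#'
#' Coordinates are 1-based and inclusive throughout. Abutting flanked
#' intervals (shared or adjacent boundary base) are merged, since a shared
#' boundary base denotes a single locus neighbourhood.
#'
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end` and
#'   optionally `subgroups` (list column or comma-separated string), e.g. from
#'   [read_region_file()].
#' @param flank_bp flanking distance in base pairs (default 100000).
#' @return data.frame with columns `region_id`, `chrom`, `start`, `end`,
#'   `n_genes`, and list columns `genes` and `subgroups`.
#' @examples
#' genes <- data.frame(gene = c("A", "B"), chrom = "1",
#'                     start = c(1000, 150000), end = c(2000, 160000))
#' build_regions(genes, flank_bp = 100000)  # one merged region [1, 260000]
#' @export
build_regions <- function(genes, flank_bp = 100000) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)),
            flank_bp >= 0)
  if (any(genes$start > genes$end)) stop("gene start > end")
  if (any(genes$start < 1)) stop("gene start must be >= 1")
  sg <- .subgroup_list(genes)

  lev <- .order_chroms(genes$chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(genes$chrom), levels = lev),
    ranges = IRanges::IRanges(pmax(1, genes$start - flank_bp),
                              genes$end + flank_bp))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  red <- GenomicRanges::sort(red)
  revmap <- S4Vectors::mcols(red)$revmap

  rows <- lapply(seq_along(red), function(i) {
    idx <- revmap[[i]]
    idx <- idx[order(genes$start[idx], genes$gene[idx])]
    list(region_id = paste(genes$gene[idx], collapse = "/"),
         chrom = as.character(GenomicRanges::seqnames(red)[i]),
         start = GenomicRanges::start(red)[i],
         end = GenomicRanges::end(red)[i],
         n_genes = length(idx),
         genes = genes$gene[idx],
         subgroups = sort(unique(unlist(sg[idx]))))
  })
  out <- data.frame(
    region_id = vapply(rows, `[[`, "", "region_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    n_genes = vapply(rows, `[[`, 0L, "n_genes"),
    stringsAsFactors = FALSE)
  out$genes <- I(lapply(rows, `[[`, "genes"))
  out$subgroups <- I(lapply(rows, `[[`, "subgroups"))
  if (anyDuplicated(out$region_id))
    stop("duplicate region identifiers after merging")
  out
}

# normalise a subgroups column (absent, character, or list) to a list column
.subgroup_list <- function(genes) {
  if (!"subgroups" %in% names(genes))
    return(rep(list(character()), nrow(genes)))
  sg <- genes$subgroups
  if (is.list(sg)) return(lapply(sg, function(x) as.character(x)))
  lapply(as.character(sg), function(x) {
    if (is.na(x) || !nzchar(trimws(x))) character() else
      trimws(strsplit(x, ",")[[1]])
  })
}

#' Map SNPs to gene regions
#'
#' A SNP belongs to a region iff `region$start <= pos <= region$end` on the
#' same chromosome (1-based inclusive on both ends). Because merged regions
#' are disjoint by construction, every SNP maps to at most one region.
#' Regions containing no SNPs take no part in gene scoring, which shrinks the
#' effective set size k exactly as gene sets containing SNP-less genes do.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (for example
#'   `panel$snps`).
#' @param regions regions from [build_regions()].
#' @return data.frame with columns `snp_id`, `region_id` (mapped SNPs only);
#'   the attribute `empty_regions` lists region ids without any SNP.
#' @export
map_snps_to_regions <- function(snps, regions) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  lev <- .order_chroms(c(snps$chrom, regions$chrom))
  gr_snp <- GenomicRanges::GRanges(
    seqnames = factor(as.character(snps$chrom), levels = lev),
    ranges = IRanges::IRanges(snps$pos, width = 1))
  gr_reg <- GenomicRanges::GRanges(
    seqnames = factor(as.character(regions$chrom), levels = lev),
    ranges = IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(gr_snp, gr_reg)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(q))
    stop("a SNP mapped to more than one region; regions must be disjoint")
  out <- data.frame(snp_id = snps$snp_id[q],
                    region_id = regions$region_id[s],
                    stringsAsFactors = FALSE)
  attr(out, "empty_regions") <- setdiff(regions$region_id, out$region_id)
  out
}

#' Score gene regions from a SNP association scan
#'
#' Assigns each region the absolute Wald z of its most strongly associated
#' SNP (`mode = "max"`), or of its second most strongly associated SNP
#' (`mode = "second_best"`, which is less sensitive to a single outlying
#' SNP; single-SNP regions fall back to their only SNP). Non-converged
#' associations are dropped before scoring; a region whose SNPs all failed to
#' converge is dropped from scoring entirely. Ties on equal `|z|` are broken
#' by `snp_id` order, which affects only the reported best SNP, not the
#' score.
#'
#' @param associations data.frame from [association_scan()].
#' @param mapping data.frame from [map_snps_to_regions()].
#' @param mode `"max"` or `"second_best"`.
#' @return data.frame with one row per scored region: `region_id`,
#'   `best_snp_id`, `score` (non-negative), `n_snps` (converged SNPs mapped),
#'   `n_snps_p05` (those with p <= 0.05), `min_p`.
#' @export
score_genes <- function(associations, mapping, mode = c("max", "second_best")) {
  mode <- match.arg(mode)
  a <- merge(mapping, associations, by = "snp_id", sort = FALSE)
  n_dropped <- sum(!a$converged)
  if (n_dropped > 0)
    message(n_dropped, " non-converged SNP association(s) dropped from gene scoring")
  a <- a[a$converged, , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(region_id = character(), best_snp_id = character(),
                      score = numeric(), n_snps = integer(),
                      n_snps_p05 = integer(), min_p = numeric(),
                      stringsAsFactors = FALSE))
  idx <- split(seq_len(nrow(a)), a$region_id)
  rows <- lapply(idx, function(i) {
    absz <- abs(a$z[i])
    ord <- i[order(-absz, a$snp_id[i])]
    pick <- if (mode == "max" || length(ord) == 1) ord[1] else ord[2]
    data.frame(region_id = a$region_id[ord[1]],
               best_snp_id = a$snp_id[pick],
               score = abs(a$z[pick]),
               n_snps = length(i),
               n_snps_p05 = sum(a$p[i] <= 0.05),
               min_p = min(a$p[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$region_id, unique(mapping$region_id))), , drop = FALSE]
}

#' SUMSTAT and SUMSQ set statistics
#'
#' For each named set of regions, sums the gene scores over the set's scored
#' regions: SUMSTAT is the sum of the per-region `|z|` scores and SUMSQ the
#' sum of their squares. Regions of a set that were not scored (no SNPs, or
#' no converged SNPs) do not contribute, so the effective `k` may be smaller
#' than the set size. Subgroup sets reuse the same gene scores; nothing is
#' refitted.
#'
#' @param gene_scores data.frame from [score_genes()].
#' @param sets named list of character vectors of region ids, e.g. from
#'   [region_sets()].
#' @return data.frame with columns `set`, `k`, `sumstat`, `sumsq`.
#' @examples
#' gs <- data.frame(region_id = c("A", "B", "C"), best_snp_id = NA,
#'                  score = c(1.5, 2, 0.5), n_snps = 1, n_snps_p05 = 0,
#'                  min_p = 0.5)
#' set_statistics(gs, list(All = c("A", "B", "C")))  # SUMSTAT 4, SUMSQ 6.5
#' @export
set_statistics <- function(gene_scores, sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  rows <- lapply(names(sets), function(nm) {
    sc <- gene_scores$score[gene_scores$region_id %in% sets[[nm]]]
    data.frame(set = nm, k = length(sc), sumstat = sum(sc),
               sumsq = sum(sc^2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # Cauchy-Schwarz sanity on every output
  stopifnot(all(out$sumsq <= out$sumstat^2 + 1e-9),
            all(out$sumstat^2 <= pmax(out$k, 1) * out$sumsq + 1e-9))
  out
}

#' Default region sets: the full set plus one set per subgroup label
#'
#' @param regions regions from [build_regions()].
#' @param all_label name of the full set (default `"All"`).
#' @return named list of region-id vectors.
#' @export
region_sets <- function(regions, all_label = "All") {
  sets <- list(regions$region_id)
  names(sets) <- all_label
  labels <- sort(unique(unlist(regions$subgroups)))
  for (l in labels) {
    sets[[l]] <- regions$region_id[vapply(regions$subgroups,
                                          function(s) l %in% s, TRUE)]
  }
  sets
}
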