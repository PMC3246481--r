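#' Validate a full-analysis configuration
#'
#' Checks a configuration list before any computation: required paths exist,
#' thresholds are in range, the permutation count and seed are sane, and the
#' optional covariate table is consistent with the pedigree samples. Returns
#' a character vector of problems; an empty vector means the configuration is
#' valid.
#'
#' Recognised fields: `ped`, `map`, `regions` (input paths), `out_dir`,
#' `seed`, `n_perm`, `flank_bp`, `mode` (`max`/`second_best`), `estimator`
#' (`exceedance`/`add_one`), `covariates_file` (optional TSV: `sample_id`
#' plus numeric columns), and a `qc` sub-list (`callrate_min`, `hwe_alpha`,
#' `heterogeneity_alpha`, `maf_min`, `hwe_sample`). Configurations can be
#' written as YAML files and loaded with [yaml::read_yaml()].
#'
#' @param config named list.
#' @return character vector of validation errors (length 0 when valid).
#' @export
validate_config <- function(config) {
  errs <- character()
  req <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  for (f in c("ped", "map", "regions")) {
    if (is.null(config[[f]])) req(FALSE, paste0("missing required path: ", f))
    else req(file.exists(config[[f]]),
             paste0(f, " file not found: ", config[[f]]))
  }
  req(!is.null(config$out_dir), "missing out_dir")
  np <- config$n_perm %||% 5000
  req(is.numeric(np) && np >= 1 && np == round(np),
      "n_perm must be a positive integer")
  sd <- config$seed %||% 1
  req(is.numeric(sd) && sd == round(sd), "seed must be an integer")
  fb <- config$flank_bp %||% 100000
  req(is.numeric(fb) && fb >= 0, "flank_bp must be >= 0")
  md <- config$mode %||% "max"
  req(md %in% c("max", "second_best"), "mode must be 'max' or 'second_best'")
  es <- config$estimator %||% "exceedance"
  req(es %in% c("exceedance", "add_one"),
      "estimator must be 'exceedance' or 'add_one'")

  qc <- config$qc %||% list()
  cr <- qc$callrate_min %||% 0.97
  req(is.numeric(cr) && cr >= 0 && cr <= 1, "qc$callrate_min must be in [0,1]")
  ha <- qc$hwe_alpha %||% 1e-5
  req(is.numeric(ha) && ha > 0 && ha < 1, "qc$hwe_alpha must be in (0,1)")
  ga <- qc$heterogeneity_alpha %||% 0.001
  req(is.numeric(ga) && ga > 0 && ga < 1,
      "qc$heterogeneity_alpha must be in (0,1)")
  mm <- qc$maf_min %||% 0.01
  req(is.numeric(mm) && mm >= 0 && mm <= 0.5, "qc$maf_min must be in [0,0.5]")
  hs <- qc$hwe_sample %||% "pooled"
  req(hs %in% c("pooled", "controls_only"),
      "qc$hwe_sample must be 'pooled' or 'controls_only'")

  if (!is.null(config$covariates_file)) {
    if (!file.exists(config$covariates_file)) {
      req(FALSE, paste0("covariates file not found: ", config$covariates_file))
    } else {
      cv <- utils::read.delim(config$covariates_file, stringsAsFactors = FALSE)
      req("sample_id" %in% names(cv),
          "covariates file must have a sample_id column")
    }
  }
  errs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage sub-seed derived from the top-level seed, so each
# stage is independently reproducible; kept below 2^31
.stage_seed <- function(seed, stage) {
  as.integer((abs(seed) * 2654435761 + stage * 40503) %% 2147483647)
}

#' Run the full pathway analysis pipeline
#'
#' Orchestrates read -> QC -> association scan -> gene scoring -> permutation
#' test as one reproducible run: reads the pedigree/map pair and the gene
#' region file, applies per-SNP quality control, builds flanked merged
#' regions, runs the within-cluster permutation test for the full set and
#' every subgroup, and writes the result tables plus a run manifest
#' (`manifest.json`) under `config$out_dir`. All randomness flows from
#' `config$seed` through deterministic per-stage sub-seeds, so a rerun with
#' the same configuration produces byte-identical outputs.
#'
#' Output tables: `qc_report.tsv` (per-SNP verdicts), `associations.tsv`
#' (per-SNP logistic results with odds ratios), `gene_scores.tsv` (per-region
#' best SNP, score, SNP counts and minimum p), `set_pvalues.tsv` (one row per
#' set with SUMSTAT and SUMSQ empirical p-values). The manifest records the
#' configuration snapshot, input file digests, package version and per-stage
#' record counts.
#'
#' @param config configuration list; see [validate_config()].
#' @return invisibly, a list with `qc`, `regions`, `pathway` (the
#'   [run_pathway_test()] object), `manifest`, and the output `paths`.
#' @export
run_full_analysis <- function(config) {
  errs <- validate_config(config)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  seed <- config$seed %||% 1
  n_perm <- config$n_perm %||% 5000
  flank_bp <- config$flank_bp %||% 100000
  mode <- config$mode %||% "max"
  estimator <- config$estimator %||% "exceedance"
  qc_cfg <- config$qc %||% list()

  panel <- read_plink_text(config$ped, config$map)
  genes <- read_region_file(config$regions,
                            allowed_subgroups = config$allowed_subgroups %||%
                              c("Treg", "Anergy", "Costim", "tDC", "Secreted"))

  covariates <- NULL
  if (!is.null(config$covariates_file)) {
    cv <- utils::read.delim(config$covariates_file, stringsAsFactors = FALSE)
    miss <- setdiff(panel$samples$sample_id, cv$sample_id)
    if (length(miss))
      stop("covariates file lacks sample(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    cv <- cv[match(panel$samples$sample_id, cv$sample_id), , drop = FALSE]
    covariates <- as.matrix(cv[setdiff(names(cv), "sample_id")])
  }

  qc <- apply_qc(panel,
                 callrate_min = qc_cfg$callrate_min %||% 0.97,
                 hwe_alpha = qc_cfg$hwe_alpha %||% 1e-5,
                 heterogeneity_alpha = qc_cfg$heterogeneity_alpha %||% 0.001,
                 maf_min = qc_cfg$maf_min %||% 0.01,
                 hwe_sample = qc_cfg$hwe_sample %||% "pooled")
  message(sprintf("QC: %d of %d SNPs pass (%s)",
                  n_snps(qc$panel), n_snps(panel),
                  paste(sprintf("%s=%d", names(table(qc$report$verdict)),
                                table(qc$report$verdict)), collapse = ", ")))

  regions <- build_regions(genes, flank_bp = flank_bp)
  mapping <- map_snps_to_regions(qc$panel$snps, regions)
  empty <- attr(mapping, "empty_regions")
  if (length(empty))
    message(length(empty), " region(s) contain no post-QC SNP: ",
            paste(utils::head(empty, 5), collapse = ", "))

  pathway <- suppressMessages(run_pathway_test(
    qc$panel, regions, sets = region_sets(regions), n_perm = n_perm,
    seed = .stage_seed(seed, 2), mode = mode, covariates = covariates,
    estimator = estimator))

  # wide set-level table: one row per set, one column per statistic
  res <- pathway$results
  sets_u <- unique(res$set)
  set_pvalues <- data.frame(
    set = sets_u,
    k = res$k[match(sets_u, res$set)],
    SUMSTAT = res$p_emp[res$statistic == "SUMSTAT"][match(
      sets_u, res$set[res$statistic == "SUMSTAT"])],
    SUMSQ = res$p_emp[res$statistic == "SUMSQ"][match(
      sets_u, res$set[res$statistic == "SUMSQ"])],
    stringsAsFactors = FALSE)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_results(list(qc_report = qc$report,
                              associations = pathway$associations,
                              gene_scores = pathway$gene_scores,
                              set_pvalues = set_pvalues),
                         config$out_dir)

  manifest <- list(
    package = "pathperm",
    version = as.character(utils::packageVersion("pathperm")),
    seed = seed,
    n_perm = n_perm,
    mode = mode,
    estimator = estimator,
    flank_bp = flank_bp,
    inputs = list(ped = unname(tools::md5sum(config$ped)),
                  map = unname(tools::md5sum(config$map)),
                  regions = unname(tools::md5sum(config$regions))),
    qc = list(callrate_min = qc_cfg$callrate_min %||% 0.97,
              hwe_alpha = qc_cfg$hwe_alpha %||% 1e-5,
              heterogeneity_alpha = qc_cfg$heterogeneity_alpha %||% 0.001,
              maf_min = qc_cfg$maf_min %||% 0.01,
              hwe_sample = qc_cfg$hwe_sample %||% "pooled"),
    counts = list(
      snps_in = n_snps(panel),
      verdicts = as.list(table(qc$report$verdict)),
      snps_post_qc = n_snps(qc$panel),
      snps_mapped = nrow(mapping),
      regions_total = nrow(regions),
      regions_with_snps = length(unique(mapping$region_id)),
      k_per_set = stats::setNames(as.list(set_pvalues$k), set_pvalues$set)))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths["manifest"] <- manifest_path

  invisible(list(qc = qc, regions = regions, pathway = pathway,
                 set_pvalues = set_pvalues, manifest = manifest,
                 paths = paths))
}
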