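#' Additive-model logistic association for a single SNP
#'
#' Fits a maximum-likelihood logistic regression of case status on the
#' minor-allele count (per-allele additive coding) plus K - 1 cluster
#' indicator covariates (reference level = first cluster in sorted label
#' order) and any user-supplied numeric covariates, such as pre-computed
#' principal components. Samples with a missing genotype are dropped for this
#' SNP only. The reported test is the Wald z = beta / se with its two-sided
#' normal p-value; `|z|` is the ingredient of the gene scores used by the set
#' statistics.
#'
#' Fitting uses iteratively reweighted least squares
#' (`stats::glm.fit`, deviance tolerance 1e-8, at most 100 iterations).
#' Quasi-separated or otherwise unstable fits are flagged `converged = FALSE`
#' (heuristic guard: `|beta| > 15` or `se > 100`, or IRLS non-convergence, or
#' a genotype column aliased out of the design); callers are expected to drop
#' such SNPs from gene scoring. A genotype that is constant among the
#' non-missing samples yields a degenerate record with `NA` estimates.
#'
#' @param phenotype vector of `"case"`/`"control"` (or 0/1, or logical).
#' @param genotype minor-allele counts 0/1/2 with `NA` for missing.
#' @param cluster optional cluster labels (factor/character) adjusted for via
#'   K - 1 indicators.
#' @param covariates optional numeric matrix or data.frame of extra
#'   covariates; constant or collinear columns are dropped deterministically
#'   by QR pivoting.
#' @return one-row data.frame with columns `beta`, `se`, `z`, `p`, `n_used`,
#'   `converged`, `or`, `or_lower`, `or_upper` (odds ratio with 95% Wald CI).
#' @examples
#' phen <- rep(c("case", "control"), c(50, 50))
#' g <- c(rep(1, 30), rep(0, 20), rep(1, 20), rep(0, 30))
#' fit_snp_logistic(phen, g)  # beta = log(2.25)
#' @export
fit_snp_logistic <- function(phenotype, genotype, cluster = NULL,
                             covariates = NULL) {
  y <- .as_case01(phenotype)
  if (length(y) != length(genotype))
    stop("phenotype and genotype lengths differ")
  keep <- !is.na(genotype)
  y <- y[keep]
  g <- as.numeric(genotype[keep])
  if (length(unique(y)) < 2)
    stop("both phenotype classes must be present among genotyped samples")
  X <- .snp_design(g, if (is.null(cluster)) NULL else cluster[keep],
                   if (is.null(covariates)) NULL else
                     covariates[keep, , drop = FALSE])
  res <- .wald_fit(X, y)
  res$n_used <- length(y)
  res$or <- exp(res$beta)
  res$or_lower <- exp(res$beta - 1.96 * res$se)
  res$or_upper <- exp(res$beta + 1.96 * res$se)
  out <- as.data.frame(res)
  rownames(out) <- NULL
  out
}

.as_case01 <- function(phenotype) {
  if (is.character(phenotype) || is.factor(phenotype)) {
    ph <- as.character(phenotype)
    if (!all(ph %in% c("case", "control")))
      stop("phenotype must be 'case'/'control'")
    as.integer(ph == "case")
  } else {
    y <- as.integer(phenotype)
    if (!all(y %in% c(0L, 1L))) stop("numeric phenotype must be 0/1")
    y
  }
}

# design matrix: intercept, genotype, cluster dummies (K-1, sorted levels),
# numeric covariates
.snp_design <- function(g, cluster, covariates) {
  X <- cbind(`(Intercept)` = 1, genotype = g)
  if (!is.null(cluster)) {
    lev <- sort(unique(as.character(cluster)))
    if (length(lev) > 1) {
      for (l in lev[-1]) {
        X <- cbind(X, as.numeric(cluster == l))
        colnames(X)[ncol(X)] <- paste0("cluster", l)
      }
    }
  }
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    if (anyNA(cv)) stop("covariates must be complete (no NA)")
    storage.mode(cv) <- "double"
    X <- cbind(X, cv)
  }
  X
}

# heuristic bounds beyond which a fit is treated as quasi-separated
.SEP_BETA_MAX <- 15
.SEP_SE_MAX <- 100

# Wald statistics for the genotype column (column 2) of a logistic fit
.wald_fit <- function(X, y) {
  degenerate <- list(beta = NA_real_, se = NA_real_, z = NA_real_,
                     p = NA_real_, converged = FALSE)
  if (length(unique(X[, 2])) < 2) return(degenerate)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = list(epsilon = 1e-8, maxit = 100)))
  Qr <- fit$qr
  r <- Qr$rank
  piv <- Qr$pivot[seq_len(r)]
  if (!(2 %in% piv)) return(degenerate)        # genotype aliased out
  covmat <- tryCatch(chol2inv(Qr$qr[seq_len(r), seq_len(r), drop = FALSE]),
                     error = function(e) NULL)
  if (is.null(covmat)) return(degenerate)
  se_all <- rep(NA_real_, ncol(X))
  se_all[piv] <- sqrt(diag(covmat))
  beta <- fit$coefficients[2]
  se <- se_all[2]
  if (!is.finite(beta) || !is.finite(se) || se <= 0) return(degenerate)
  z <- beta / se
  converged <- isTRUE(fit$converged) &&
    abs(beta) <= .SEP_BETA_MAX && se <= .SEP_SE_MAX
  list(beta = unname(beta), se = unname(se), z = unname(z),
       p = 2 * stats::pnorm(-abs(z)), converged = converged)
}

# Precompute per-SNP designs so the permutation engine only swaps in a new
# phenotype vector. Returns list(snp_id, designs = list of (X, rows)).
.precompute_designs <- function(panel, covariates = NULL, snp_idx = NULL) {
  if (is.null(snp_idx)) snp_idx <- seq_len(n_snps(panel))
  cluster <- panel$samples$cluster
  cv <- NULL
  if (!is.null(covariates)) {
    if (is.character(covariates)) {
      missing_cols <- setdiff(covariates, names(panel$samples))
      if (length(missing_cols))
        stop("covariate columns not in panel samples: ",
             paste(missing_cols, collapse = ", "))
      cv <- as.matrix(panel$samples[covariates])
    } else {
      cv <- as.matrix(as.data.frame(covariates))
    }
    if (anyNA(cv)) stop("covariates must be complete (no NA)")
  }
  designs <- lapply(snp_idx, function(j) {
    g <- panel$genotypes[, j]
    rows <- which(!is.na(g))
    X <- .snp_design(as.numeric(g[rows]),
                     cluster[rows],
                     if (is.null(cv)) NULL else cv[rows, , drop = FALSE])
    list(X = X, rows = rows)
  })
  list(snp_id = panel$snps$snp_id[snp_idx], designs = designs)
}

# Fast scan over precomputed designs for a given 0/1 phenotype vector.
# Returns a data.frame-free list of vectors (hot path of the permutation loop).
.scan_stats <- function(pre, y01) {
  m <- length(pre$designs)
  beta <- se <- z <- p <- rep(NA_real_, m)
  conv <- rep(FALSE, m)
  n_used <- integer(m)
  for (j in seq_len(m)) {
    d <- pre$designs[[j]]
    yj <- y01[d$rows]
    n_used[j] <- length(yj)
    if (length(unique(yj)) < 2) next
    w <- .wald_fit(d$X, yj)
    beta[j] <- w$beta; se[j] <- w$se; z[j] <- w$z; p[j] <- w$p
    conv[j] <- w$converged
  }
  list(beta = beta, se = se, z = z, p = p, converged = conv, n_used = n_used)
}

#' Per-SNP association scan across a panel
#'
#' Runs [fit_snp_logistic()] for every SNP of the panel, adjusting for the
#' panel's cluster labels and any extra numeric covariates, and returns one
#' record per SNP in input (map) order. The scan is deterministic and the
#' identical code path is used for observed and permuted phenotypes by the
#' permutation engine.
#'
#' @param panel a [genotype_panel()] (typically after [apply_qc()]).
#' @param covariates optional: character vector naming numeric columns of
#'   `panel$samples`, or a numeric matrix/data.frame with one row per sample.
#' @return data.frame with columns `snp_id`, `beta`, `se`, `z`, `p`,
#'   `n_used`, `converged`, `or`, `or_lower`, `or_upper`.
#' @export
association_scan <- function(panel, covariates = NULL) {
  pre <- .precompute_designs(panel, covariates)
  s <- .scan_stats(pre, case_indicator(panel))
  data.frame(snp_id = pre$snp_id, beta = s$beta, se = s$se, z = s$z, p = s$p,
             n_used = s$n_used, converged = s$converged,
             or = exp(s$beta), or_lower = exp(s$beta - 1.96 * s$se),
             or_upper = exp(s$beta + 1.96 * s$se),
             stringsAsFactors = FALSE)
}
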