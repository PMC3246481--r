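# Independent oracles used across the suite.

# Exact HWE p-value via the Wigginton-style ratio recurrence (independent of
# the package's direct log-factorial route). n genotypes, m = rarer allele
# count, h_obs = observed heterozygote count.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  m <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (m == 0) return(1)
  h <- seq.int(m %% 2, m, by = 2)
  pr <- numeric(length(h))
  pr[1] <- 1
  # P(h+2)/P(h) = 4 * n_rare_hom * n_common_hom / ((h+2) * (h+1))
  for (i in seq_along(h)[-1]) {
    hh <- h[i - 1]
    rare_hom <- (m - hh) / 2
    common_hom <- n - hh - rare_hom
    pr[i] <- pr[i - 1] * 4 * rare_hom * common_hom / ((hh + 2) * (hh + 1))
  }
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Woolf standard error of the log odds ratio for a 2x2 table
woolf_se <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

# All case/control assignments that preserve per-cluster case counts.
# Returns a matrix with one phenotype vector ("case"/"control") per row.
enumerate_within_cluster_assignments <- function(phenotype, cluster) {
  cl <- split(seq_along(cluster), cluster)
  per_cluster <- lapply(cl, function(idx) {
    n_case <- sum(phenotype[idx] == "case")
    sets <- utils::combn(length(idx), n_case, simplify = FALSE)
    lapply(sets, function(s) {
      v <- rep("control", length(idx))
      v[s] <- "case"
      v
    })
  })
  grid <- expand.grid(lapply(per_cluster, seq_along))
  out <- matrix("", nrow = nrow(grid), ncol = length(cluster))
  for (r in seq_len(nrow(grid))) {
    v <- rep("", length(cluster))
    for (ci in seq_along(cl)) {
      v[cl[[ci]]] <- per_cluster[[ci]][[grid[r, ci]]]
    }
    out[r, ] <- v
  }
  out
}

# Test-side mean-p statistic: threshold selection then greedy LD pruning in
# ascending-p order (re-implemented independently of the package internals).
# Returns NA when nothing is selected.
meanp_oracle_stat <- function(p, converged, r2mat, p_threshold, r2_threshold) {
  sel <- which(converged & !is.na(p) & p <= p_threshold)
  if (length(sel) == 0) return(NA_real_)
  sel <- sel[order(p[sel], sel)]
  kept <- integer(0)
  for (j in sel) {
    r2 <- r2mat[j, kept]
    if (length(kept) == 0 || all(is.na(r2) | r2 <= r2_threshold))
      kept <- c(kept, j)
  }
  mean(p[kept])
}
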