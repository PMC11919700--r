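# Shared fixtures and independent oracles, built in code at test time.

# small, fast study configuration used by most pipeline-level tests
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_chroms = 2, chrom_length = 4e6, n_promoter_bins = 60,
         depth = 3e4, n_ctcf_peaks = 150, n_atac_peaks = 250,
         n_planted_links = 20, seed = 11),
    list(...))
  do.call(sim_config, args)
}

# brute-force zero-truncated upper tail by direct pmf summation in log space
# (independent of ztp_pvalue: sums the Poisson pmf term by term); returns
# the log p-value so tails below double-precision range stay comparable
oracle_ztp_log_tail <- function(x, mu, kmax = 5000) {
  k <- seq.int(x, max(x + 50, ceiling(mu + 40 * sqrt(mu)), kmax))
  lt <- stats::dpois(k, mu, log = TRUE)
  m <- max(lt)
  num <- m + log(sum(exp(lt - m)))
  denom <- log(-expm1(-mu))
  min(num - denom, 0)
}

# independent quantile-normalization oracle: rank-and-average by loops
oracle_quantile_norm <- function(mat) {
  totals <- colSums(mat)
  scaled <- mat
  for (j in seq_len(ncol(mat))) scaled[, j] <- mat[, j] / (totals[j] / mean(totals))
  ref <- rowMeans(apply(scaled, 2, sort))
  out <- scaled
  for (j in seq_len(ncol(mat))) {
    o <- order(scaled[, j])          # ties by first occurrence
    out[o, j] <- ref
  }
  out
}

# exact permutation p-value for the Spearman statistic (tiny n only)
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  obs <- abs(stats::cor(rank(x), rank(y)))
  perms <- combinat_perms(n)
  vals <- apply(perms, 1, function(p) abs(stats::cor(rank(x), rank(y[p]))))
  mean(vals >= obs - 1e-12)
}

combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# adjusted Rand index oracle (mclust)
oracle_ari <- function(a, b) mclust::adjustedRandIndex(a, b)
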