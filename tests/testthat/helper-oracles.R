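# Independent brute-force oracles used to freeze expected values.

# Exact two-sided rank-sum p by full enumeration of rank assignments.
# Convention: 2 * min(P(W <= w), P(W >= w)) capped at 1, W = rank-sum of x.
ranksum_exact_oracle <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  w_obs <- sum(rank(pooled)[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  ranks <- rank(pooled)
  w_all <- apply(combos, 2, function(ix) sum(ranks[ix]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact null distribution of the Mann-Whitney U for sizes (m, n) by
# enumeration; returns P(U = u) for u = 0..m*n.
u_null_oracle <- function(m, n) {
  combos <- utils::combn(m + n, m)
  w_all <- apply(combos, 2, sum)
  u_all <- w_all - m * (m + 1) / 2
  tabulate(u_all + 1L, nbins = m * n + 1L) / ncol(combos)
}

# Minimum-likelihood two-sided binomial p by full enumeration.
binom_twosided_oracle <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}

# Direct Pearson / R^2 / RMSE formulas (observed, predicted).
concordance_oracle <- function(obs, pred) {
  r <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  list(
    r = r,
    r2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
    rmse = sqrt(mean((obs - pred)^2))
  )
}

# Build a site_kinetics tibble by hand.
make_sites <- function(pos, mean_ipd, ref_base = "A", strand = "+",
                       contig = "c1", valid_count = 30L) {
  n <- length(pos)
  tibble::tibble(
    contig = rep_len(contig, n), pos = as.integer(pos),
    strand = rep_len(strand, n), ref_base = rep_len(ref_base, n),
    valid_count = rep_len(as.integer(valid_count), n),
    mean_ipd = mean_ipd, ipd_sd = rep_len(0, n)
  )
}

# Observation tibble for a single site.
make_obs <- function(ipd, neighbors_match = TRUE, pos = 0L, strand = "+",
                     ref_base = "A", contig = "c1") {
  n <- length(ipd)
  tibble::tibble(
    read_id = paste0("r", seq_len(n)), contig = rep_len(contig, n),
    pos = rep_len(as.integer(pos), n), strand = rep_len(strand, n),
    ref_base = rep_len(ref_base, n), ipd = ipd,
    neighbors_match = rep_len(neighbors_match, n)
  )
}
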