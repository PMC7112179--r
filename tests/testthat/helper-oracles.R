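# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (enumeration / pair counting / definitional
# formulas) and share no code with the functions they check.

# Two-sided Fisher p by exhaustive enumeration of the hypergeometric
# support with the observed margins (minimum-likelihood convention).
fisher_oracle_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Tie-corrected Kendall tau-b by O(n^2) pair counting.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) sum(sapply(table(v), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tie_pairs(x)) * (n0 - tie_pairs(y)))
}

# Benjamini-Hochberg by its step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[ord[i]] / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Hypergeometric overlap tail by explicit enumeration over subsets
# (tiny universes only).
overlap_oracle <- function(k_obs, n_a, n_b, n_universe) {
  x <- 0:min(n_a, n_b)
  probs <- dhyper(x, n_a, n_universe - n_a, n_b)
  sum(probs[x >= k_obs])
}

# Brute-force gap distance on 1-based inclusive intervals.
gap_oracle <- function(s1, e1, s2, e2) {
  if (e1 < s2) return(s2 - e1 - 1)
  if (e2 < s1) return(s1 - e2 - 1)
  0
}

# Small count-matrix builder for two-group DE tests.
make_cm <- function(vals, n_per_group = ncol(vals) / 2,
                    tissues = c("A", "B")) {
  rownames(vals) <- sprintf("f%04d", seq_len(nrow(vals)))
  count_matrix(vals, data.frame(
    sample_id = paste0("s", seq_len(ncol(vals))),
    tissue = rep(tissues, each = n_per_group),
    replicate = rep(seq_len(n_per_group), 2)))
}
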