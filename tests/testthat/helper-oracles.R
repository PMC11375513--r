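# shared fixtures and independent oracles used across test files

# paired standardized noise blocks with shared sample ids
rand_std_blocks <- function(n, p, q, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("g%03d", 1:p)))
  Y <- matrix(rnorm(n * q), n, q,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("t%03d", 1:q)))
  list(x = standardize(omics_matrix(X, "expression")),
       y = standardize(omics_matrix(Y, "expression")))
}

# brute-force Benjamini-Hochberg step-up: adj_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / j, capped at 1
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# exact hypergeometric upper-tail by explicit choose() summation
hyper_tail_oracle <- function(k, K, N, s) {
  js <- k:min(s, K)
  js <- js[js >= max(0, s + K - N)]
  if (length(js) == 0) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, s - js) - lchoose(N, s)))
}

# naive rank random walk written independently of es_random_walk
es_walk_oracle <- function(stat, gene_set, tau = 1) {
  N <- length(stat)
  ord <- names(sort(stat, decreasing = TRUE))
  r <- (rank(stat) - (N + 1) / 2)[ord]
  inside <- ord %in% gene_set
  denom <- sum(abs(r[inside])^tau)
  walk <- 0; vmax <- 0; vmin <- 0
  for (i in seq_len(N)) {
    walk <- walk + if (inside[i]) abs(r[i])^tau / denom else -1 / (N - sum(inside))
    vmax <- max(vmax, walk); vmin <- min(vmin, walk)
  }
  vmax + vmin
}

f1_score <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  if (length(selected) == 0 || tp == 0) return(0)
  prec <- tp / length(selected)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}

auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
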