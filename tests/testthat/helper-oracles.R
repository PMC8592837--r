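# Independent oracles used to cross-check package implementations.
# These deliberately use the most literal (slow) formulation of each
# computation and share no code with the package internals.

# O(mn) brute-force pair count within a radius (inclusive), excluding
# pairs that are the same physical cell; unordered j<k when the two sets
# are identical.
brute_pair_count <- function(cells_a, cells_b, threshold = 100) {
  count <- 0L
  same <- setequal(cells_a$cell_id, cells_b$cell_id) &&
    nrow(cells_a) == nrow(cells_b)
  for (j in seq_len(nrow(cells_a))) {
    for (k in seq_len(nrow(cells_b))) {
      if (cells_a$cell_id[j] == cells_b$cell_id[k]) next
      d <- sqrt((cells_a$x_px[j] - cells_b$x_px[k])^2 +
                (cells_a$y_px[j] - cells_b$y_px[k])^2)
      if (d <= threshold) count <- count + 1L
    }
  }
  if (same) count %/% 2L else count
}

# Literal Benjamini-Hochberg step-up: sort ascending, q_i = min over
# j >= i of p_(j) * n / j, capped at 1, mapped back to input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Textbook Yates-corrected chi-square p for a 2x2 table.
yates_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum(pmax(abs(tab - e) - 0.5, 0)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins that are no more
# probable than the observed one (with the standard relative tolerance).
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (no ties assumed), mirroring the exact two-sided rule
# min(1, 2 * min(P(W <= w), P(W >= w))).
ranksum_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(nx + ny, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Minimum within-cluster sum-of-squares split of sorted 1-D data into two
# contiguous groups (the optimal 2-means partition in one dimension).
best_1d_split <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  best <- Inf; best_cut <- 1
  for (cut in 1:(n - 1)) {
    ss <- sum((xs[1:cut] - mean(xs[1:cut]))^2) +
      sum((xs[(cut + 1):n] - mean(xs[(cut + 1):n]))^2)
    if (ss < best) { best <- ss; best_cut <- cut }
  }
  grp <- integer(n)
  grp[o] <- rep(1:2, c(best_cut, n - best_cut))
  grp
}
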