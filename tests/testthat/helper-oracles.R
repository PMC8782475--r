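# Independent oracles used across the test files.

# Rank sum of `test` in the combined sample, computed from first
# principles: explicit ascending sort, positions as ranks, tie groups
# averaged to midranks. Deliberately avoids base rank().
brute_rank_sum <- function(ref, test) {
  vals <- c(ref, test)
  ord <- order(vals)
  pos <- numeric(length(vals))
  pos[ord] <- seq_along(vals)
  r <- pos
  for (v in unique(vals)) {
    idx <- which(vals == v)
    if (length(idx) > 1L) r[idx] <- mean(pos[idx])
  }
  sum(r[seq_along(test) + length(ref)])
}

# Exact null distribution of the test rank sum for tiny (m, n) by
# exhaustive enumeration of which ranks the test sample occupies.
enum_w_null <- function(m, n) {
  sets <- utils::combn(m + n, n)
  w <- colSums(matrix(sets, nrow = n))
  tab <- table(w)
  data.frame(w = as.numeric(names(tab)),
             p = as.numeric(tab) / ncol(sets))
}

# Direct, non-incremental evaluation of the double-smoothed statistic
# from the stored rank-sum history (running means recomputed from
# scratch at every step).
direct_double_stat <- function(w, l_outer, l_inner, mu) {
  t_max <- length(w)
  h <- numeric(t_max)
  out <- numeric(t_max)
  for (t in seq_len(t_max)) {
    wbar <- if (t == 1) mu else mean(w[seq_len(t - 1)])
    h[t] <- l_inner * w[t] + (1 - l_inner) * wbar
    hbar <- if (t == 1) mu else mean(h[seq_len(t - 1)])
    out[t] <- l_outer * h[t] + (1 - l_outer) * hbar
  }
  out
}

# Draw rank-sum statistics under the null by the pairwise-count
# identity, vectorized over many replications (no ties a.s.).
sim_w_null <- function(reps, m, n, rdraw) {
  X <- matrix(rdraw(reps * m), reps, m)
  Y <- matrix(rdraw(reps * n), reps, n)
  u <- numeric(reps)
  for (j in seq_len(m))
    for (k in seq_len(n))
      u <- u + (X[, j] < Y[, k])
  u + n * (n + 1) / 2
}
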