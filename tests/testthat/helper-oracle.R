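# Independent brute-force enumeration oracle for (cross-)approximate
# entropy: explicit double loop over template pairs, no shared code with the
# package's kernel.

oracle_embed <- function(x, m, lag) {
  n <- length(x) - (m - 1) * lag
  out <- matrix(0, n, m)
  for (k in seq_len(m)) out[, k] <- x[seq_len(n) + (k - 1) * lag]
  out
}

oracle_phi <- function(query, targets, r) {
  n <- nrow(targets)
  tot <- 0
  for (i in seq_len(nrow(query))) {
    c_i <- 0
    for (j in seq_len(n))
      if (max(abs(query[i, ] - targets[j, ])) <= r) c_i <- c_i + 1
    if (c_i == 0) c_i <- 1  # zero-match floor: 1 / n_targets
    tot <- tot + log(c_i / n)
  }
  tot / nrow(query)
}

oracle_capen <- function(u, v, m, lag, r) {
  u <- (u - mean(u)) / sd(u)
  v <- (v - mean(v)) / sd(v)
  one_dir <- function(a, b)
    oracle_phi(oracle_embed(a, m, lag), oracle_embed(b, m, lag), r) -
      oracle_phi(oracle_embed(a, m + 1, lag), oracle_embed(b, m + 1, lag), r)
  (one_dir(u, v) + one_dir(v, u)) / 2
}

# common-source coupling model used by the monotonicity checks:
# x = a*s + sqrt(1-a^2)*n1, y = a*s + sqrt(1-a^2)*n2
common_source_pair <- function(alpha, n, rate = 500) {
  s <- capen:::ar2_source(n, rate, 10, 0.95)
  x <- alpha * s + sqrt(1 - alpha^2) * rnorm(n)
  y <- alpha * s + sqrt(1 - alpha^2) * rnorm(n)
  list(x = x, y = y)
}
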