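# Independent oracle implementations used to check the package's statistics.
# These are deliberately written as direct arithmetic, not calls into the
# functions they verify.

oracle_es_hea <- function(q_hits, qc_hits, q_n, qc_n, pc = 0.5) {
  if (q_hits == 0 || qc_hits == 0) {
    q_hits <- q_hits + pc
    qc_hits <- qc_hits + pc
  }
  log((q_hits / qc_hits) / (q_n / qc_n), base = 2)
}

oracle_es_odds <- function(a, b, c, d, pc = 0.5) {
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    a <- a + pc; b <- b + pc; c <- c + pc; d <- d + pc
  }
  log((a / c) / (b / d), base = 2)
}

# Exact hypergeometric upper tail P(X >= a) by explicit enumeration with
# binomial coefficients.
oracle_fisher_enum <- function(a, b, c, d) {
  m <- a + c   # annotated / hit
  k <- a + b   # drawn (query side)
  N <- a + b + c + d
  js <- a:min(k, m)
  if (length(js) == 0L || a > min(k, m)) return(0)
  sum(choose(m, js) * choose(N - m, k - js)) / choose(N, k)
}

# BH step-up with cumulative minimum, order-preserving.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Random 2x2 contingency tables (occasionally with zero cells).
random_tables <- function(n, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      a = rpois(n, 3), b = rpois(n, 20),
      c = rpois(n, 5), d = rpois(n, 200)
    )
  })
}

adjusted_rand_index <- function(x, y) mclust::adjustedRandIndex(x, y)
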