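# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the exact-test oracle enumerates the hypergeometric
# distribution from log-binomial coefficients, the Wilson oracle goes through
# prop.test, and the overlap oracle is a brute-force all-pairs loop.

# Two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins; mass comparison uses the customary (1 + 1e-7) slack.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Wilson bounds via prop.test (score interval without continuity correction)
oracle_wilson <- function(x, n, level = 0.95) {
  ci <- stats::prop.test(x, n, conf.level = level, correct = FALSE)$conf.int
  c(lower = ci[1], upper = ci[2])
}

# reference BH step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# brute-force any-overlap of intervals (1-based inclusive) with a flank
oracle_overlaps <- function(q_contig, q_start, q_end,
                            f_contig, f_start, f_end, flank = 0) {
  vapply(seq_along(q_start), function(i) {
    any(f_contig == q_contig[i] &
        f_start - flank <= q_end[i] & f_end + flank >= q_start[i])
  }, logical(1))
}

# random 2x2 tables with total at most `max_total`
random_tables <- function(n, max_total = 200, seed = 1) {
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    total <- sample.int(max_total, 1)
    cuts <- sort(sample.int(total + 1, 3, replace = TRUE)) - 1L
    c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], total - cuts[3])
  }, numeric(4)))
}
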