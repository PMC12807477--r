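# Independent brute-force oracles used across test files.  Each one reaches
# the expected value by a different computational route than the package
# implementation (likelihood functions, step-by-step loops, naive
# agglomeration), so agreement is informative.

# G statistic via Poisson log-likelihoods (saturated vs common-rate model)
oracle_g <- function(c_ip, c_igg, t_ip, t_igg) {
  theta <- (c_ip + c_igg) / (t_ip + t_igg)
  l_sat <- stats::dpois(c_ip, max(c_ip, 1e-300), log = TRUE) +
    stats::dpois(c_igg, max(c_igg, 1e-300), log = TRUE)
  l_null <- stats::dpois(c_ip, theta * t_ip, log = TRUE) +
    stats::dpois(c_igg, theta * t_igg, log = TRUE)
  2 * (l_sat - l_null)
}

# Welch t-test from first principles
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Benjamini-Hochberg step-up by explicit definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# binomial LRT via dbinom
oracle_binom_lrt <- function(i1, n1, i2, n2) {
  p0 <- (i1 + i2) / (n1 + n2)
  ll <- function(i, n, p) stats::dbinom(i, n, p, log = TRUE)
  2 * (ll(i1, n1, i1 / n1) + ll(i2, n2, i2 / n2) -
         ll(i1, n1, p0) - ll(i2, n2, p0))
}

# GSEA enrichment score by an explicit step-by-step walk
oracle_gsea_es <- function(ranking, set, weight = 1) {
  r <- sort(ranking, decreasing = TRUE)
  nr <- sum(abs(r[names(r) %in% set])^weight)
  n_miss <- sum(!names(r) %in% set)
  run <- 0; mx <- -Inf; mn <- Inf
  for (i in seq_along(r)) {
    if (names(r)[i] %in% set) run <- run + abs(r[i])^weight / nr
    else run <- run - 1 / n_miss
    if (run > mx) mx <- run
    if (run < mn) mn <- run
  }
  # same tie convention as the implementation: positive extreme wins ties
  unname(if (mx + mn >= -1e-12) mx else mn)
}

# naive O(n^3) average-linkage agglomeration returning sorted merge heights
oracle_average_linkage_heights <- function(d) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(dm[clusters[[i]], clusters[[j]]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# small helpers shared by tests
tiny_sim <- function(seed = 1, ...) {
  sim_config(seed = seed, n_proteins = 60L,
             ub = list(n_sites = 120L, n_ub_proteins = 40L, n_planted = 6L),
             ip = list(n_planted = 8L),
             screen = list(n_genes = 20L, n_planted = 4L),
             splice = list(n_events = 60L, n_planted = 6L),
             image = list(n_nuclei = 2L),
             ...)
}
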