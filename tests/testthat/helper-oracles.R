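# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive every quantity from first principles and
# share no code with the implementation under test.

# median-of-ratios size factors, literal definition
oracle_size_factors <- function(k) {
  m <- ncol(k)
  geo <- apply(k, 1, function(x) prod(x)^(1 / m))
  usable <- apply(k, 1, function(x) all(x > 0))
  vapply(seq_len(m), function(j) {
    stats::median(k[usable, j] / geo[usable])
  }, numeric(1))
}

# NB pmf via log-gamma, avoiding stats::dnbinom
oracle_nb_pmf <- function(x, mu, size) {
  exp(lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
        size * (log(size) - log(size + mu)) +
        x * (log(mu) - log(size + mu)))
}

# exact conditioned NB p-value by direct enumeration over all splits
oracle_nbinom_p <- function(counts_a, counts_b, sf_a, sf_b, alpha) {
  ka <- sum(counts_a)
  kb <- sum(counts_b)
  ks <- ka + kb
  q <- ks / (sum(sf_a) + sum(sf_b))
  mu_a <- q * sum(sf_a)
  mu_b <- q * sum(sf_b)
  var_a <- sum(q * sf_a + alpha * q^2 * sf_a^2)
  var_b <- sum(q * sf_b + alpha * q^2 * sf_b^2)
  size_a <- mu_a^2 / (var_a - mu_a)
  size_b <- mu_b^2 / (var_b - mu_b)
  probs <- vapply(0:ks, function(a) {
    oracle_nb_pmf(a, mu_a, size_a) * oracle_nb_pmf(ks - a, mu_b, size_b)
  }, numeric(1))
  p_obs <- probs[ka + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]) / sum(probs))
}

# BH step-up by its textbook definition (loop, no vector tricks)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    running_min <- min(running_min, sorted[i] * m / i)
    adj[i] <- running_min
  }
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# textbook one-sample t-test p-value
oracle_one_sample_p <- function(x) {
  n <- length(x)
  tstat <- mean(x) / (stats::sd(x) / sqrt(n))
  2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
}

# fixed pool of distinct 6-bp indices for hand-built sample sheets
generate_indices_for_test <- function(m) {
  pool <- c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT", "ACGTAC", "TGCATG",
            "GATCGA", "CTAGCT")
  pool[seq_len(m)]
}

# small screen fixture shared by several tests
small_screen <- function(seed = 11, planted = NULL, depth = 300,
                         n_genes = 30, hairpins_per_gene = 4, ...) {
  simulate_screen(screen_sim_config(
    n_genes = n_genes, hairpins_per_gene = hairpins_per_gene,
    depth_mean = depth, n_replicates = 3,
    planted_sensitizers = planted, seed = seed, ...))
}
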