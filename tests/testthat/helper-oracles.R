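# Independent oracles used across tests. Each is written from the defining
# formula, not from the package's implementation path.

# Benjamini-Hochberg by definition: sort, p * m / rank, step-up monotonize.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exact HWE p-value by brute-force enumeration of every genotype table with
# the observed allele counts, using choose() products for the conditional
# probability (a different algebraic route than the implementation).
hwe_oracle <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  na <- 2 * n_hom_minor + n_het          # copies of the first allele
  hets <- seq(min(na, 2 * n - na) %% 2, min(na, 2 * n - na), by = 2)
  weight <- vapply(hets, function(h) {
    naa <- (na - h) / 2
    nbb <- n - h - naa
    choose(n, naa) * choose(n - naa, h) * 2^h
  }, numeric(1))
  prob <- weight / sum(weight)
  obs <- prob[hets == n_het]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# OLS of y on (1, d, a) from the normal equations.
ols_oracle <- function(y, d, a) {
  X <- cbind(1, d, a)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - 3)
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  list(beta_hat = beta[2], se = se, t_stat = beta[2] / se,
       p_value = 2 * pt(-abs(beta[2] / se), df = length(y) - 3))
}

# A small simulated study used by several tests.
small_sim <- function(seed = 1, n_samples = 200, n_snps = 5, n_cpgs = 40,
                      effect_table = NULL, ...) {
  simulate_meqtl_dataset(meqtl_sim_config(
    n_samples = n_samples, n_snps = n_snps, n_cpgs = n_cpgs,
    effect_table = effect_table, seed = seed, ...
  ))
}
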