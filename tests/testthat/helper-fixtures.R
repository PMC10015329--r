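# Shared fixtures and independent oracles, all built in code.

# path graph on n nodes (1-2-3-...-n)
path_net <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) adj[i, i + 1L] <- adj[i + 1L, i] <- 1L
  as_dw_network(adj)
}

# star: node 1 is the hub with k leaves
star_net <- function(k) {
  adj <- matrix(0L, k + 1L, k + 1L)
  adj[1L, -1L] <- adj[-1L, 1L] <- 1L
  as_dw_network(adj)
}

# minimal sample block: an M x N sample matrix plus the state at the end
# of relaxation (defaults to the sample means)
make_block <- function(samples, state_at_relax = colMeans(samples),
                       param_value = 0.1) {
  samples <- as.matrix(samples)
  list(param_value = param_value, samples = samples,
       state_at_relax = state_at_relax, means = colMeans(samples),
       sds = apply(samples, 2L, sd))
}

# brute-force tau-b: count concordant/discordant pairs over all n(n-1)/2
# pairs and apply the tie correction
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(x), 2))
  n2 <- sum(choose(table(y), 2))
  if (n0 - n1 == 0 || n0 - n2 == 0) return(NA_real_)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# maximum-likelihood tail-exponent estimate for a discrete power law
# truncated below at kmin (continuous approximation)
plaw_alpha_mle <- function(degrees, kmin) {
  d <- degrees[degrees >= kmin]
  1 + length(d) / sum(log(d / (kmin - 0.5)))
}
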