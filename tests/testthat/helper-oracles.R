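# Independent oracles used across the test suite.

# Exact absorbing-Markov-chain solution of the diploid Wright-Fisher model:
# states are mutant allele counts 0..2N; absorption probabilities and the
# first two moments of the conditional fixation time come from dense linear
# solves, with no diffusion approximation and no Monte Carlo. Feasible for
# N up to a few hundred.
exact_wf_chain <- function(N, scheme) {
  K <- 2L * N
  p <- (0:K) / K
  ps <- wf_expected_frequency(p, scheme)
  P <- t(vapply(ps, function(q) dbinom(0:K, K, q), numeric(K + 1)))
  Q <- P[2:K, 2:K]
  IQ <- diag(K - 1) - Q
  u <- solve(IQ, P[2:K, K + 1])            # fixation probability
  theta <- solve(IQ, u)                    # E[T * 1_fix]
  theta2 <- solve(IQ, u + 2 * as.numeric(Q %*% theta))  # E[T^2 * 1_fix]
  t_cond <- theta / u
  list(u = u, theta = theta, t_cond = t_cond,
       t_cond_sd = sqrt(pmax(theta2 / u - t_cond^2, 0)),
       single = list(u = u[1], theta = theta[1], t_cond = t_cond[1],
                     t_cond_sd = sqrt(max(theta2[1] / u[1] - t_cond[1]^2, 0))))
}

# Rejection sampler for improvement sizes, independent of the production
# inverse-CDF sampler: proposes from the exponential occurrence density and
# accepts with probability proportional to the fixation filter implied by
# the closed-form improvement density.
rejection_sample_improvement <- function(n, dist) {
  a <- dist$alpha
  N <- dist$N
  cN <- if (is.finite(N)) (a + N + 1) / (N * (N + a + 1)) else 0
  bound <- 1 + cN
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)) * ceiling(bound / (a * dist$beta)), 1000L)
    s <- rexp(m, rate = a)
    g <- 1 - exp(-2 * s) + cN * exp(-(N + 1) * s)
    keep <- runif(m) < g / bound
    out <- c(out, s[keep])
  }
  out[seq_len(n)]
}

# Normalised occurrence-times-fixation product density (the quantity the
# closed-form improvement CDF approximates), integrated adaptively.
product_density_cdf <- function(s, alpha, N) {
  dens <- function(x)
    alpha * exp(-alpha * x) *
      vapply(x, function(si)
        fixation_probability_closed(1 / (2 * N), s_het = si, N = N), 0)
  Z <- integrate(dens, 0, Inf, rel.tol = 1e-10)$value
  vapply(s, function(v)
    integrate(dens, 0, v, rel.tol = 1e-10)$value / Z, 0)
}
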