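# Closed-form and brute-force oracles used across tests. These are kept
# independent of the package's computation paths: multivariate-normal
# densities are built from the model matrices directly, and the joint
# covariance of a linear-Gaussian SSM is assembled by recursion.

log_dmvnorm <- function(x, mu, S) {
  k <- length(mu)
  ch <- chol(S)
  q <- sum(backsolve(ch, x - mu, transpose = TRUE)^2)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

# joint mean/covariance of (y_0, ..., y_T) for a 1-D linear-Gaussian SSM
ssm_y_joint <- function(ssm, T_len) {
  a <- ssm$a[1]; q <- ssm$q_var[1]; cc <- ssm$C[1, 1]; r <- ssm$r_var[1]
  p0 <- ssm$p0_var[1]; mu0 <- ssm$mu0[1]
  n <- T_len + 1L
  # cov(z_i, z_j) = a^{|i-j|} var(z_min)
  vz <- numeric(n)
  vz[1] <- p0
  if (n > 1) for (t in 2:n) vz[t] <- a^2 * vz[t - 1] + q
  Sz <- outer(seq_len(n), seq_len(n), function(i, j) {
    a^(abs(i - j)) * vz[pmin(i, j)]
  })
  mu_z <- mu0 * a^(seq_len(n) - 1L)
  list(mu = cc * mu_z, S = cc^2 * Sz + diag(r, n))
}

# constant-output network helpers: zero weights, chosen biases
zero_mlp <- function(pp, bias) {
  pp$W <- lapply(pp$W, function(W) W * 0)
  L <- length(pp$b)
  pp$b <- lapply(pp$b, function(b) b * 0)
  pp$b[[L]] <- matrix(bias, 1L)
  pp
}

# small shared gait cohort (memoised per test run)
local({
  cache <- new.env()
  tiny_cohort <<- function() {
    if (is.null(cache$coh)) {
      cache$coh <- generate_cohort(1, 3, seed = 3, duration = 8)
      cache$spec <- fit_minmax(cache$coh$recordings)
      cache$obs <- lapply(cache$coh$recordings, build_observations,
                          spec = cache$spec)
    }
    list(coh = cache$coh, spec = cache$spec, obs = cache$obs)
  }
})

expect_close <- function(object, expected, tol = 1e-8) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max abs diff %.3g < %.3g",
                              max(abs(object - expected)), tol))
}
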