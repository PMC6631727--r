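# Backbone model: prior, transition mixture, emitter, joint probability,
# ancestral sampling, and the exact linear-Gaussian correspondence.

test_that("initial prior is a proper diagonal Gaussian", {
  set.seed(1)
  gp <- generative_params(latent_dim = 2, obs_dim = 4, hidden = c(8))
  pr <- initial_prior(gp)
  # standard-normal prior at the origin (variance carries the 1e-6 floor)
  expect_close(pr$log_density(c(0, 0)),
               sum(dnorm(c(0, 0), 0, sqrt(1 + 1e-6), log = TRUE)), tol = 1e-12)
  set.seed(2)
  S <- pr$sample(1e4)
  expect_true(all(abs(colMeans(S) - pr$mean) < 4 / sqrt(1e4)))
  # density integrates to one on a wide grid
  g <- seq(-6, 6, length.out = 120)
  h <- g[2] - g[1]
  pts <- as.matrix(expand.grid(g, g))
  expect_close(sum(exp(pr$log_density(pts))) * h^2, 1, tol = 0.01)
})

test_that("transition mixture is a valid conditional distribution", {
  set.seed(5)
  gp <- generative_params(latent_dim = 2, obs_dim = 4, mixture_K = 3,
                          hidden = c(8))
  # weights sum to one for random conditioning states
  Z <- matrix(rnorm(200), 100, 2)
  td <- transition_distribution(Z, gp)
  expect_close(rowSums(td$weights), rep(1, 100), tol = 1e-12)

  # mixture log-density equals direct summation over components
  td1 <- transition_distribution(c(0.4, -1), gp)
  zq <- c(0.2, 0.7)
  direct <- log(sum(vapply(1:3, function(k) {
    td1$weights[1, k] * prod(dnorm(zq, td1$means[[k]][1, ],
                                   sqrt(td1$vars[[k]][1, ])))
  }, 0)))
  expect_close(td1$log_density(zq), direct, tol = 1e-9)

  # constant network: distribution independent of z_prev
  gp1 <- generative_params(latent_dim = 2, obs_dim = 4, mixture_K = 1,
                           hidden = c(8))
  gp1$trans <- zero_mlp(gp1$trans, c(0, 0.3, -0.2,
                                     ldmf:::softplus_inv(0.5),
                                     ldmf:::softplus_inv(0.5)))
  ta <- transition_distribution(c(5, 5), gp1)
  tb <- transition_distribution(c(-5, 0), gp1)
  expect_identical(ta$means[[1]], tb$means[[1]])
  expect_identical(ta$vars[[1]], tb$vars[[1]])

  expect_error(transition_distribution(c(NA, 1), gp), "non-finite")
})

test_that("emitter behaves as a diagonal Gaussian over observations", {
  set.seed(6)
  # identity-like readout in a d = obs_dim configuration: mean equals z
  gp <- generative_params(latent_dim = 3, obs_dim = 3, hidden = integer(0))
  W <- matrix(0, 3, 6); W[, 1:3] <- diag(3)
  gp$emit$W$W1 <- W
  gp$emit$b$b1 <- matrix(c(0, 0, 0, rep(ldmf:::softplus_inv(0.2), 3)), 1)
  z <- c(0.5, -1, 2)
  ed <- emitter_distribution(z, gp)
  expect_close(as.numeric(ed$mean), z, tol = 1e-12)
  # mode: log-density at the mean beats any other point
  at_mean <- ed$log_density(z)
  set.seed(7)
  for (i in 1:20) expect_lt(ed$log_density(z + rnorm(3, sd = 0.5)), at_mean)
  # per-coordinate 1-D Gaussian sum oracle
  y <- c(1, 0, -0.5)
  expect_close(ed$log_density(y),
               sum(dnorm(y, mean = z, sd = sqrt(as.numeric(ed$var)),
                         log = TRUE)), tol = 1e-9)
  expect_error(emitter_distribution(matrix(1, 1, 5), gp), "dimension mismatch")
})

test_that("multinomial emitter gives normalised bin log-probabilities", {
  set.seed(8)
  gp <- generative_params(latent_dim = 2, obs_dim = 1, hidden = c(4),
                          emitter_family = "multinomial", bins = 8)
  ed <- emitter_distribution(c(0.1, -0.3), gp)
  # probabilities over the 8 bins of the single feature sum to one
  mids <- (1:8 - 0.5) / 8
  tot <- sum(vapply(mids, function(m) exp(ed$log_density(m)), 0))
  expect_close(tot, 1, tol = 1e-9)
})

test_that("joint log-probability telescopes and matches per-term summation", {
  set.seed(9)
  gp <- generative_params(latent_dim = 2, obs_dim = 4, hidden = c(8))
  s <- sample_trajectory(gp, 5, seed = 10)
  # T = 0 base case
  base <- joint_log_prob(s$y[1, , drop = FALSE], s$z[1, , drop = FALSE], gp)
  pr <- initial_prior(gp)
  expect_close(base, pr$log_density(s$z[1, ]) +
                 emitter_distribution(s$z[1, ], gp)$log_density(s$y[1, ]),
               tol = 1e-9)
  # term-by-term oracle for T = 5
  lp <- pr$log_density(s$z[1, ]) +
    emitter_distribution(s$z[1, ], gp)$log_density(s$y[1, ])
  for (t in 2:6) {
    lp <- lp + emitter_distribution(s$z[t, ], gp)$log_density(s$y[t, ]) +
      transition_distribution(s$z[t - 1, ], gp)$log_density(s$z[t, ])
  }
  expect_close(joint_log_prob(s$y, s$z, gp), lp, tol = 1e-8)
  # additivity: adding step T adds exactly the two step-T terms
  lp5 <- joint_log_prob(s$y[1:5, ], s$z[1:5, ], gp)
  stepT <- emitter_distribution(s$z[6, ], gp)$log_density(s$y[6, ]) +
    transition_distribution(s$z[5, ], gp)$log_density(s$z[6, ])
  expect_close(joint_log_prob(s$y, s$z, gp), lp5 + stepT, tol = 1e-8)
  expect_error(joint_log_prob(s$y, s$z[1:3, ], gp), "length mismatch")
})

test_that("ancestral sampling is reproducible and moment-consistent", {
  set.seed(11)
  gp <- generative_params(latent_dim = 1, obs_dim = 2, hidden = integer(0))
  s1 <- sample_trajectory(gp, 20, seed = 4)
  s2 <- sample_trajectory(gp, 20, seed = 4)
  expect_identical(s1, s2)

  # one-step conditional variance: empirical spread of z_1 | z_0 matches the
  # transition variance
  td <- transition_distribution(0.7, gp)
  set.seed(12)
  draws <- td$sample(1e4)
  expect_close(stats::var(draws[, 1]), td$vars[[1]][1, 1],
               tol = 5 * td$vars[[1]][1, 1] / sqrt(1e4) * 3)
  expect_close(mean(draws[, 1]), td$means[[1]][1, 1],
               tol = 4 * sqrt(td$vars[[1]][1, 1]) / sqrt(1e4) * 3)
})

test_that("with K=1 and linear networks the model is exactly linear-Gaussian", {
  set.seed(13)
  ssm <- generate_linear_gaussian_ssm(d = 1, obs_dim = 1, T_len = 4, seed = 14,
                                      a = 0.8, q_sd = 0.6, r_sd = 0.4,
                                      C = matrix(1.3, 1, 1))
  params <- ssm_to_params(ssm)
  # joint over (z, y) from the package vs direct factorised Gaussian terms
  lp <- joint_log_prob(ssm$y, ssm$z, params)
  direct <- dnorm(ssm$z[1, 1], ssm$mu0, sqrt(ssm$p0_var), log = TRUE) +
    sum(dnorm(ssm$y[, 1], 1.3 * ssm$z[, 1], 0.4, log = TRUE)) +
    sum(dnorm(ssm$z[2:5, 1], 0.8 * ssm$z[1:4, 1], 0.6, log = TRUE))
  expect_close(lp, direct, tol = 1e-5)

  # marginal likelihood: Kalman prediction-error decomposition equals the
  # closed-form joint Gaussian density of y_{0:T}
  kf <- kalman_filter(ssm)
  jy <- ssm_y_joint(ssm, 4)
  expect_close(kf$loglik, log_dmvnorm(ssm$y[, 1], jy$mu, jy$S), tol = 1e-8)
})

test_that("emitted distribution parameters stay finite on a wide input box", {
  set.seed(15)
  gp <- generative_params(latent_dim = 2, obs_dim = 6, hidden = c(16, 16))
  Z <- as.matrix(expand.grid(seq(-10, 10, length.out = 7),
                             seq(-10, 10, length.out = 7)))
  ed <- emitter_distribution(Z, gp)
  td <- transition_distribution(Z, gp)
  expect_true(all(is.finite(ed$mean)) && all(is.finite(ed$var)))
  expect_true(all(ed$var > 0))
  expect_true(all(is.finite(td$means[[1]])) && all(td$vars[[1]] > 0))
})
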