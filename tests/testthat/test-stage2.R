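# Predict-correct filtering: predict moments, combiner, causality, and
# combiner-only training.

test_that("predict step reduces to the Kalman prediction for linear K=1", {
  set.seed(1)
  gp <- generative_params(latent_dim = 1, obs_dim = 1, hidden = integer(0))
  gp$trans$W$W1 <- matrix(c(0, 0.9, 0), 1, 3)
  gp$trans$b$b1 <- matrix(c(0, 0, ldmf:::softplus_inv(0.25)), 1, 3)
  ps <- predict_state(list(mu = 2, var = 0.5), gp)
  expect_close(ps$mean, 0.9 * 2, tol = 1e-9)
  expect_close(ps$var, 0.9^2 * 0.5 + 0.25 + 1e-6, tol = 1e-7)

  # identity-mean, (near) zero-process-noise: prediction keeps the mean
  gp$trans$W$W1 <- matrix(c(0, 1, 0), 1, 3)
  gp$trans$b$b1 <- matrix(c(0, 0, ldmf:::softplus_inv(1e-10)), 1, 3)
  ps2 <- predict_state(list(mu = -1.3, var = 0.2), gp)
  expect_close(ps2$mean, -1.3, tol = 1e-9)
  expect_close(ps2$var, 0.2, tol = 1e-4)
})

test_that("K=2 mixture prediction matches sampled moments", {
  set.seed(2)
  gp <- generative_params(latent_dim = 1, obs_dim = 1, mixture_K = 2,
                          hidden = c(6))
  z_prev <- 0.4
  td <- transition_distribution(z_prev, gp)
  set.seed(3)
  draws <- td$sample(1e5)
  ps <- predict_state(list(mu = z_prev, var = 0), gp) # no input variance
  expect_close(ps$mean, mean(draws), tol = 4 * sd(draws) / sqrt(1e5))
  expect_close(ps$var, stats::var(draws[, 1]),
               tol = 6 * stats::var(draws[, 1]) / sqrt(1e5) * 3)
})

test_that("combiner is a deterministic map with positive variance", {
  set.seed(4)
  comb <- combiner_params(obs_dim = 6, latent_dim = 2, hidden = c(8))
  expect_true(all(combine_state(c(0.1, -0.2), c(0.5, 0.5), rnorm(6),
                                comb)$var > 0))
  set.seed(4); y <- rnorm(6)
  a <- combine_state(c(1, 1), c(0.2, 0.3), y, comb)
  b <- combine_state(c(1, 1), c(0.2, 0.3), y, comb)
  expect_identical(a, b)

  # zero-weight network with bias: output independent of the observation,
  # mean follows the prediction (residual head with zero correction)
  comb0 <- comb
  comb0$mlp <- zero_mlp(comb0$mlp, c(0, 0, rep(ldmf:::softplus_inv(0.4), 2)))
  c1 <- combine_state(c(1, -1), c(0.2, 0.2), rnorm(6), comb0)
  c2 <- combine_state(c(1, -1), c(0.2, 0.2), rnorm(6), comb0)
  expect_identical(c1, c2)
  expect_close(c1$mu, c(1, -1), tol = 1e-12)
  expect_error(combine_state(c(1, -1), c(0.2, 0.2), rnorm(5), comb0),
               "dimension mismatch")
})

test_that("the filter is causal: future windows never change past states", {
  set.seed(5)
  gp <- generative_params(latent_dim = 2, obs_dim = 6, hidden = c(8))
  comb <- combiner_params(6, 2, c(8))
  Y <- matrix(rnorm(20 * 6), 20, 6)
  base <- filter_sequence(Y, gp, comb)
  expect_equal(dim(base$mu), c(20L, 2L))
  for (trial in 1:10) {
    t_cut <- sample(1:19, 1)
    Y2 <- Y
    Y2[(t_cut + 1):20, ] <- Y2[(t_cut + 1):20, ] + matrix(rnorm((20 - t_cut) * 6), ncol = 6)
    pert <- filter_sequence(Y2, gp, comb)
    expect_identical(base$mu[1:t_cut, ], pert$mu[1:t_cut, ])
    expect_identical(base$var[1:t_cut, ], pert$var[1:t_cut, ])
  }
})

test_that("stage-2 training updates only the combiner and improves the bound", {
  tc <- tiny_cohort()
  s1 <- train_stage1(tc$obs, list(latent_dim = 2, hidden = c(8),
                                  rnn_hidden = 8, epochs = 2,
                                  subseq_len = 40, stride = 40, seed = 1))
  theta_before <- ldmf:::gen_trainable(s1$params)
  cfg <- list(epochs = 4, lr = 5e-3, subseq_len = 40, stride = 40,
              hidden = c(8), seed = 2)
  s2 <- train_stage2(tc$obs, s1$params, cfg)
  # backbone untouched, bitwise
  expect_identical(ldmf:::gen_trainable(s1$params), theta_before)
  # objective improves over epochs
  expect_gt(utils::tail(s2$log$objective, 1), s2$log$objective[1])
  # determinism
  s2b <- train_stage2(tc$obs, s1$params, cfg)
  expect_identical(s2$combiner, s2b$combiner)
  # requires a trained backbone
  expect_error(train_stage2(tc$obs, list(), cfg), "generative_params")
})
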