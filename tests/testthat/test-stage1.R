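# Encoder, KL divergence, ELBO estimator and stage-1 training.

test_that("encoder posteriors depend only on present and future windows", {
  set.seed(1)
  enc <- encoder_params(obs_dim = 6, latent_dim = 2, rnn_hidden = 8)
  Y <- matrix(rnorm(42), 7, 6)
  post <- encode(Y, enc)
  expect_equal(dim(post$mu), c(7L, 2L))
  expect_true(all(post$var > 0))
  # perturbing the first window leaves the final-step posterior unchanged
  Y2 <- Y; Y2[1, ] <- Y2[1, ] + 100
  post2 <- encode(Y2, enc)
  expect_identical(post$mu[7, ], post2$mu[7, ])
  expect_identical(post$var[7, ], post2$var[7, ])
  # ... but changes the step-0 posterior
  expect_false(all(post$mu[1, ] == post2$mu[1, ]))

  # zero-weight readout with bias (0, softplus^-1(1)): standard normal at
  # every step
  enc0 <- enc
  enc0$W <- enc0$W * 0
  enc0$b <- matrix(c(0, 0, rep(ldmf:::softplus_inv(1), 2)), 1)
  p0 <- encode(Y, enc0)
  expect_close(p0$mu, matrix(0, 7, 2), tol = 1e-12)
  expect_close(p0$var, matrix(1 + 1e-6, 7, 2), tol = 1e-9)
})

test_that("gaussian_kl matches the closed form and numeric integration", {
  expect_equal(gaussian_kl(c(1, -2), c(0.5, 2), c(1, -2), c(0.5, 2)), 0)
  expect_equal(gaussian_kl(1, 1, 0, 1), 0.5)
  expect_error(gaussian_kl(0, -1, 0, 1), "positive")
  # diagonal 3-D pair: KL is the sum of per-dimension 1-D integrals of
  # q log(q/p)
  set.seed(2)
  mu_q <- rnorm(3); var_q <- exp(rnorm(3, sd = 0.3))
  mu_p <- rnorm(3); var_p <- exp(rnorm(3, sd = 0.3))
  num <- sum(vapply(1:3, function(i) {
    stats::integrate(function(x) {
      q <- dnorm(x, mu_q[i], sqrt(var_q[i]))
      q * (dnorm(x, mu_q[i], sqrt(var_q[i]), log = TRUE) -
             dnorm(x, mu_p[i], sqrt(var_p[i]), log = TRUE))
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }, 0))
  expect_close(gaussian_kl(mu_q, var_q, mu_p, var_p), num, tol = 1e-7)
})

test_that("elbo collapses to the marginal when encoder, prior and transition agree", {
  set.seed(3)
  d <- 2; p <- 3
  gp <- generative_params(latent_dim = d, obs_dim = p, hidden = c(4))
  # transition == prior == N(0, 1 + floor); emitter independent of z
  gp$trans <- zero_mlp(gp$trans, c(0, rep(0, d),
                                   rep(ldmf:::softplus_inv(1), d)))
  emit_bias <- c(0.2, 0.5, -0.1)
  gp$emit <- zero_mlp(gp$emit, c(emit_bias, rep(ldmf:::softplus_inv(0.3), p)))
  enc <- encoder_params(p, d, 4)
  enc$gru <- ldmf:::par_map(enc$gru, function(x) x * 0)
  enc$W <- enc$W * 0
  enc$b <- matrix(c(rep(0, d), rep(ldmf:::softplus_inv(1), d)), 1)
  Y <- matrix(rnorm(12), 4, p)
  rep_ <- elbo(Y, gp, enc, n_samples = 2, seed = 5)
  expect_close(rep_$kl0_term, 0, tol = 1e-9)
  expect_close(rep_$kl_sum_term, 0, tol = 1e-9)
  marg <- sum(dnorm(Y, mean = matrix(emit_bias, 4, p, byrow = TRUE),
                    sd = sqrt(0.3 + 1e-6), log = TRUE))
  expect_close(rep_$elbo, marg, tol = 1e-7)
})

test_that("elbo is bounded by the reconstruction term and the exact likelihood", {
  set.seed(6)
  gp <- generative_params(latent_dim = 2, obs_dim = 4, hidden = c(8))
  enc <- encoder_params(4, 2, 8)
  s <- sample_trajectory(gp, 6, seed = 7)
  rep_ <- elbo(s$y, gp, enc, n_samples = 4, seed = 8)
  expect_lte(rep_$elbo, rep_$recon_term)
  expect_close(rep_$elbo,
               rep_$recon_term - rep_$kl0_term - rep_$kl_sum_term, tol = 1e-9)

  # linear-Gaussian toy: the ELBO never exceeds the exact Kalman evidence
  ssm <- generate_linear_gaussian_ssm(1, 1, T_len = 3, seed = 9, a = 0.7,
                                      q_sd = 0.5, r_sd = 0.5,
                                      C = matrix(1, 1, 1))
  params <- ssm_to_params(ssm)
  exact <- kalman_filter(ssm)$loglik
  for (i in 1:5) {
    set.seed(100 + i)
    enc_i <- encoder_params(1, 1, 4)
    r <- elbo(ssm$y, params, enc_i, n_samples = 500, seed = i)
    expect_lt(r$elbo, exact + 0.05)
  }
})

test_that("stage-1 training is deterministic and improves the bound", {
  tc <- tiny_cohort()
  cfg <- list(latent_dim = 2, hidden = c(8), rnn_hidden = 8, epochs = 2,
              subseq_len = 40, stride = 40, seed = 1)
  a <- train_stage1(tc$obs, cfg)
  b <- train_stage1(tc$obs, cfg)
  expect_identical(a$params, b$params)
  expect_identical(a$encoder, b$encoder)
  expect_equal(nrow(a$log), 2L)

  # a few more epochs: smoothed ELBO at the end is above epoch 1
  c3 <- train_stage1(tc$obs, utils::modifyList(cfg, list(epochs = 6, lr = 5e-3)))
  expect_gt(mean(utils::tail(c3$log$elbo, 2)), c3$log$elbo[1])
})

test_that("training on constant observations drives the emitter to the constant", {
  cfg <- list(latent_dim = 1, hidden = integer(0), rnn_hidden = 4,
              epochs = 15, lr = 3e-2, subseq_len = 10, stride = 10, seed = 2)
  Y <- matrix(0.7, 60, 3)
  fit <- train_stage1(list(Y), cfg)
  ops <- ldmf:::model_ops()
  post <- encode(Y[1:10, ], fit$encoder)
  recon <- ldmf:::emit_forward_gauss(ops, fit$params$emit, post$mu, 3)$mu
  init_err <- 0.7^2 * 3 # squared error of a zero-mean initial guess, per row
  expect_lt(mean(rowSums((recon - 0.7)^2)), init_err / 10)
})
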