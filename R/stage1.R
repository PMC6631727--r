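# Stage 1: backward-recurrent encoder, evidence lower bound, and joint
# training of the backbone and encoder parameters.

#' Construct encoder parameters
#'
#' The encoder implements the variational posterior q(z_t | y_{t:T}) with a
#' GRU run backwards in time over the observation windows; a linear readout
#' of the hidden state gives the posterior mean and (softplus) variance.
#' Because the recurrence runs from T down to t, the step-t posterior depends
#' only on the present and future observations. Uses the current RNG state.
#'
#' @param obs_dim observation dimension (24 for stacked windows).
#' @param latent_dim latent dimension d.
#' @param rnn_hidden GRU hidden width.
#' @return Object of class \code{encoder_params}.
#' @export
encoder_params <- function(obs_dim = 24L, latent_dim = 2L, rnn_hidden = 32L) {
  d <- as.integer(latent_dim)
  structure(list(
    obs_dim = as.integer(obs_dim), latent_dim = d,
    rnn_hidden = as.integer(rnn_hidden),
    gru = gru_init(obs_dim, rnn_hidden),
    W = glorot(rnn_hidden, 2L * d),
    b = matrix(c(rep(0, d), rep(softplus_inv(1), d)), 1L, 2L * d)
  ), class = "encoder_params")
}

enc_trainable <- function(enc) list(gru = enc$gru, W = enc$W, b = enc$b)
enc_update <- function(enc, tr) {
  enc$gru <- tr$gru; enc$W <- tr$W; enc$b <- tr$b
  enc
}

# Backward GRU pass. Ylist: list over time of (batch x obs_dim) matrices.
# Returns list over time of list(mu, var) nodes (batch x d).
encode_forward <- function(ops, epp, Ylist) {
  L <- length(Ylist)
  W <- ops$value(epp$W)
  d <- ncol(W) %/% 2L
  n <- nrow(Ylist[[1L]])
  h <- ops$const(matrix(0, n, nrow(W)))
  out <- vector("list", L)
  for (t in seq.int(L, 1L)) {
    h <- gru_cell(ops, epp$gru, ops$const(Ylist[[t]]), h)
    ro <- ops$addb(ops$mm(h, epp$W), epp$b)
    out[[t]] <- list(mu = ops$cols(ro, seq_len(d)),
                     var = softplus_var(ops, ops$cols(ro, d + seq_len(d))))
  }
  out
}

#' Encode an observation sequence into per-step posteriors
#'
#' @param y an \code{obs_seq} or (T+1) x 24 matrix.
#' @param enc an \code{\link{encoder_params}} object.
#' @return List with matrices \code{mu} and \code{var}, each (T+1) x d:
#'   the Gaussian posterior q(z_t | y_{t:T}) at every step.
#' @export
encode <- function(y, enc) {
  Y <- obs_matrix(y)
  if (ncol(Y) != enc$obs_dim) {
    stop("observation dimension mismatch: expected ", enc$obs_dim)
  }
  ops <- model_ops()
  Ylist <- lapply(seq_len(nrow(Y)), function(i) Y[i, , drop = FALSE])
  post <- encode_forward(ops, enc_trainable(enc), Ylist)
  list(mu = do.call(rbind, lapply(post, `[[`, "mu")),
       var = do.call(rbind, lapply(post, `[[`, "var")))
}

#' Kullback-Leibler divergence between diagonal Gaussians
#'
#' Closed form, in nats; nonnegative and zero iff the distributions match.
#'
#' @param mu_q,var_q mean and variance vectors of q.
#' @param mu_p,var_p mean and variance vectors of p.
#' @return Scalar KL(q || p).
#' @export
gaussian_kl <- function(mu_q, var_q, mu_p, var_p) {
  if (any(var_q <= 0) || any(var_p <= 0)) stop("variances must be positive")
  0.5 * sum(var_q / var_p + (mu_q - mu_p)^2 / var_p - 1 - log(var_q / var_p))
}

# Shared ELBO graph for a batch of equal-length sequences.
# Ylist: list over time of (batch x obs_dim) matrices; eps: list over time of
# (batch x d) standard-normal draws. gpp/epp are (possibly leafed)
# trainables. Returns scalar nodes summed over batch.
elbo_graph <- function(ops, params, gpp, epp, Ylist, eps) {
  L <- length(Ylist)
  d <- params$latent_dim
  post <- encode_forward(ops, epp, Ylist)
  z <- vector("list", L)
  recon <- NULL
  for (t in seq_len(L)) {
    sd_t <- ops$sqrt(post[[t]]$var)
    z[[t]] <- ops$add(post[[t]]$mu, ops$mul(sd_t, ops$const(eps[[t]])))
    r <- emit_logdens(ops, params, gpp$emit, z[[t]], Ylist[[t]])
    recon <- if (is.null(recon)) r else ops$add(recon, r)
  }
  pm <- prior_moments(ops, gpp$prior)
  n <- nrow(Ylist[[1L]])
  kl0 <- kl_rows_b(ops, post[[1L]]$mu, post[[1L]]$var, pm$mu, pm$var)
  klsum <- NULL
  for (t in seq_len(L)[-1L]) {
    tr <- trans_forward(ops, gpp$trans, z[[t - 1L]], params$mixture_K, d)
    if (params$mixture_K == 1L) {
      kt <- kl_rows(ops, post[[t]]$mu, post[[t]]$var, tr$mu[[1L]], tr$var[[1L]])
    } else {
      # sampled log-ratio log q(z_t) - log p(z_t | z_{t-1})
      lq <- gauss_logdens_rows(ops, post[[t]]$mu, post[[t]]$var, z[[t]])
      lp <- mixture_logdens(ops, tr, z[[t]])
      kt <- ops$sub(lq, lp)
    }
    klsum <- if (is.null(klsum)) kt else ops$add(klsum, kt)
  }
  if (is.null(klsum)) klsum <- ops$const(matrix(0, n, 1L))
  list(recon = ops$sum(recon), kl0 = ops$sum(kl0),
       klsum = ops$sum(klsum))
}

# KL rows against a broadcast 1 x d prior (tape-differentiable in the prior)
kl_rows_b <- function(ops, mu_q, var_q, mu_p_row, var_p_row) {
  n_mu <- ops$value(mu_q)
  reps <- nrow(n_mu)
  mu_p <- ops$mm(ops$const(matrix(1, reps, 1L)), mu_p_row)
  var_p <- ops$mm(ops$const(matrix(1, reps, 1L)), var_p_row)
  kl_rows(ops, mu_q, var_q, mu_p, var_p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte-Carlo evidence lower bound for one sequence
#'
#' Estimates the sequence ELBO with reparameterised samples from the encoder
#' posteriors: reconstruction expectations for every step, the analytic
#' KL(q(z_0) || p(z_0)), and transition KL terms evaluated at sampled
#' z_{t-1} (analytic KL for a single-component transition, sampled log-ratio
#' for mixtures).
#'
#' @param y an \code{obs_seq} or (T+1) x 24 matrix.
#' @param params a \code{\link{generative_params}} object.
#' @param enc an \code{\link{encoder_params}} object.
#' @param n_samples Monte-Carlo sample count (>= 1).
#' @param seed integer seed for the reparameterisation draws.
#' @return Object of class \code{elbo_report}: list with \code{elbo},
#'   \code{recon_term}, \code{kl0_term}, \code{kl_sum_term} (nats),
#'   \code{n_samples}, \code{seed}; \code{elbo = recon - kl0 - kl_sum}.
#' @export
elbo <- function(y, params, enc, n_samples = 1L, seed = 1L) {
  stopifnot(n_samples >= 1L)
  Y <- obs_matrix(y)
  set.seed(seed)
  ops <- model_ops()
  L <- nrow(Y)
  d <- params$latent_dim
  # replicate the sequence across the batch dimension: one row per MC sample
  Ylist <- lapply(seq_len(L), function(t) {
    matrix(Y[t, ], n_samples, ncol(Y), byrow = TRUE)
  })
  eps <- lapply(seq_len(L), function(t) {
    matrix(stats::rnorm(n_samples * d), n_samples, d)
  })
  terms <- elbo_graph(ops, params, gen_trainable(params), enc_trainable(enc),
                      Ylist, eps)
  recon <- as.numeric(terms$recon) / n_samples
  kl0 <- as.numeric(terms$kl0) / n_samples
  klsum <- as.numeric(terms$klsum) / n_samples
  structure(list(elbo = recon - kl0 - klsum, recon_term = recon,
                 kl0_term = kl0, kl_sum_term = klsum,
                 n_samples = n_samples, seed = seed),
            class = "elbo_report")
}

#' @export
print.elbo_report <- function(x, ...) {
  cat(sprintf("ELBO %.4f = recon %.4f - KL0 %.4f - KLtrans %.4f (%d sample%s)\n",
              x$elbo, x$recon_term, x$kl0_term, x$kl_sum_term, x$n_samples,
              if (x$n_samples > 1) "s" else ""))
  invisible(x)
}

# Slice sequences into equal-length training subsequences.
slice_subsequences <- function(dataset, len, stride) {
  out <- list()
  for (Y in dataset) {
    Y <- obs_matrix(Y)
    n <- nrow(Y)
    if (n < len) next
    starts <- seq.int(1L, n - len + 1L, by = stride)
    for (s in starts) out[[length(out) + 1L]] <- Y[s + 0:(len - 1L), , drop = FALSE]
  }
  if (length(out) == 0L) stop("no sequence is at least ", len, " windows long")
  out
}

default_stage1_config <- function() {
  list(latent_dim = 2L, obs_dim = 24L, mixture_K = 1L,
       hidden = c(32L, 32L), rnn_hidden = 32L,
       emitter_family = "gaussian", bins = 32L,
       batch_size = 64L, epochs = 20L, lr = 1e-3,
       subseq_len = 100L, stride = 50L, n_samples = 1L,
       kl_weight = 1, seed = 1L)
}

stage1_config <- function(config = list()) {
  utils::modifyList(default_stage1_config(), config)
}

#' Train the first stage (backbone + encoder)
#'
#' Gradient ascent on the Monte-Carlo ELBO with reparameterised samples,
#' jointly over the backbone parameters (initial prior, transition, emitter)
#' and the encoder. Long recordings are sliced into fixed-length overlapping
#' subsequences which are shuffled into minibatches. The emitter mean bias is
#' initialised at the training-data mean. Fully reproducible under
#' \code{config$seed}.
#'
#' @param dataset list of \code{obs_seq} matrices (or a single one).
#' @param config list overriding the defaults: \code{latent_dim} (2),
#'   \code{mixture_K} (1), \code{hidden} (c(32, 32)), \code{rnn_hidden} (32),
#'   \code{emitter_family} ("gaussian"), \code{batch_size} (64),
#'   \code{epochs} (20), \code{lr} (1e-3), \code{subseq_len} (100),
#'   \code{stride} (50), \code{kl_weight} (1; KL annealing off by default),
#'   \code{seed} (1).
#' @return List with \code{params} (\code{generative_params}),
#'   \code{encoder} (\code{encoder_params}), \code{log} (data frame with
#'   per-epoch elbo/recon/kl in nats per subsequence), and \code{config}.
#' @export
train_stage1 <- function(dataset, config = list()) {
  if (is.matrix(dataset)) dataset <- list(dataset)
  stopifnot(length(dataset) > 0)
  cfg <- stage1_config(config)
  set.seed(cfg$seed)
  subs <- slice_subsequences(dataset, cfg$subseq_len, cfg$stride)
  allY <- do.call(rbind, lapply(dataset, obs_matrix))
  obs_dim <- ncol(allY)
  params <- generative_params(
    latent_dim = cfg$latent_dim, obs_dim = obs_dim,
    mixture_K = cfg$mixture_K, hidden = cfg$hidden,
    emitter_family = cfg$emitter_family, bins = cfg$bins,
    emitter_mean_bias = if (cfg$emitter_family == "gaussian") colMeans(allY),
    emitter_var = max(mean(apply(allY, 2L, stats::var)), 1e-3))
  enc <- encoder_params(obs_dim, cfg$latent_dim, cfg$rnn_hidden)
  gpp <- gen_trainable(params)
  epp <- enc_trainable(enc)
  opt_g <- adam_init(gpp, lr = cfg$lr)
  opt_e <- adam_init(epp, lr = cfg$lr)
  log <- data.frame(epoch = integer(), elbo = numeric(),
                    recon = numeric(), kl = numeric())
  n_sub <- length(subs)
  L <- cfg$subseq_len
  d <- cfg$latent_dim
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_sub)
    ep_elbo <- 0; ep_recon <- 0; ep_kl <- 0
    for (b0 in seq.int(1L, n_sub, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n_sub)]
      nb <- length(idx)
      Ylist <- lapply(seq_len(L), function(t) {
        do.call(rbind, lapply(subs[idx], function(S) S[t, , drop = FALSE]))
      })
      eps <- lapply(seq_len(L), function(t) matrix(stats::rnorm(nb * d), nb, d))
      tp <- ad_tape()
      ops <- model_ops(tp)
      gl <- par_leaf(tp, gpp)
      el <- par_leaf(tp, epp)
      terms <- elbo_graph(ops, params, gl, el, Ylist, eps)
      kl_tot <- ad_add(tp, terms$kl0, terms$klsum)
      elbo_node <- ad_sub(tp, terms$recon,
                          if (cfg$kl_weight == 1) kl_tot
                          else ad_scale(tp, kl_tot, cfg$kl_weight))
      loss <- ad_scale(tp, elbo_node, -1 / nb)
      if (!is.finite(ad_value(tp, loss)[1L])) {
        stop("stage-1 training diverged: non-finite loss at epoch ", ep)
      }
      ad_backward(tp, loss)
      gpp <- adam_step(opt_g, gpp, par_grads(tp, gl))
      epp <- adam_step(opt_e, epp, par_grads(tp, el))
      ep_elbo <- ep_elbo + (as.numeric(ad_value(tp, terms$recon)) -
                            as.numeric(ad_value(tp, kl_tot)))
      ep_recon <- ep_recon + as.numeric(ad_value(tp, terms$recon))
      ep_kl <- ep_kl + as.numeric(ad_value(tp, kl_tot))
    }
    log <- rbind(log, data.frame(epoch = ep, elbo = ep_elbo / n_sub,
                                 recon = ep_recon / n_sub, kl = ep_kl / n_sub))
  }
  params <- gen_update(params, gpp)
  enc <- enc_update(enc, epp)
  list(params = params, encoder = enc, log = log, config = cfg)
}
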