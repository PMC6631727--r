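# Stage 2: causal filtering with a combiner network.
#
# The filter alternates a predict step through the frozen transition network
# (moment matching of the mixture plus first-order propagation of the input
# variance, which reduces exactly to the Kalman predict step for a linear
# single-component transition) and a correct step where an MLP maps
# (predicted mean, log predicted variance, current observation) to the
# filtered Gaussian state.

FD_H <- 1e-4 # central-difference step for the transition-mean Jacobian

#' Construct combiner-network parameters
#'
#' The combiner is an MLP from (predicted mean, log predicted variance,
#' observation window) to the filtered posterior mean and (softplus)
#' variance, echoing the correction step of the Kalman filter. Uses the
#' current RNG state.
#'
#' @param obs_dim observation dimension.
#' @param latent_dim latent dimension d.
#' @param hidden integer vector of hidden widths.
#' @return Object of class \code{combiner_params}.
#' @export
combiner_params <- function(obs_dim = 24L, latent_dim = 2L,
                            hidden = c(32L, 32L)) {
  d <- as.integer(latent_dim)
  mlp <- mlp_init(2L * d + as.integer(obs_dim), hidden, 2L * d,
                  out_bias = c(rep(0, d), rep(softplus_inv(0.1), d)))
  structure(list(obs_dim = as.integer(obs_dim), latent_dim = d,
                 hidden = hidden, mlp = mlp),
            class = "combiner_params")
}

comb_trainable <- function(comb) comb$mlp
comb_update <- function(comb, tr) { comb$mlp <- tr; comb }

# predict step as a graph: transition moments at the filtered mean plus
# Jacobian-propagated filtered variance
predict_graph <- function(ops, params, gpp, m_prev, v_prev) {
  d <- params$latent_dim
  K <- params$mixture_K
  tr <- trans_forward(ops, gpp$trans, m_prev, K, d)
  mm <- mixture_moments(ops, tr)
  n <- nrow(ops$value(m_prev))
  # all 2d central-difference perturbations evaluated in one stacked forward
  pert <- vector("list", 2L * d)
  for (j in seq_len(d)) {
    ej <- matrix(0, n, d); ej[, j] <- FD_H
    pert[[2L * j - 1L]] <- ops$add(m_prev, ops$const(ej))
    pert[[2L * j]] <- ops$sub(m_prev, ops$const(ej))
  }
  big <- do.call(ops$rbind, pert)
  mu_big <- mixture_moments(ops, trans_forward(ops, gpp$trans, big, K, d))$mean
  var_prop <- NULL
  for (j in seq_len(d)) {
    mu_p <- ops$rows(mu_big, (2L * j - 2L) * n + seq_len(n))
    mu_m <- ops$rows(mu_big, (2L * j - 1L) * n + seq_len(n))
    Jj <- ops$scale(ops$sub(mu_p, mu_m), 1 / (2 * FD_H)) # n x d: d mean / d z_j
    term <- ops$mulcol(ops$square(Jj), ops$cols(v_prev, j))
    var_prop <- if (is.null(var_prop)) term else ops$add(var_prop, term)
  }
  list(mean = mm$mean, var = ops$add(mm$var, var_prop))
}

# Yt must already be an ops value (matrix under ops_num, node under ops_tape).
# The mean head is residual: the network outputs a correction added to the
# predicted mean, mirroring the Kalman correction step; at zero weights the
# filter follows the prior dynamics.
combine_graph <- function(ops, cpp, pred_mean, pred_var, Yt) {
  d <- ncol(ops$value(pred_mean))
  inp <- ops$cbind(pred_mean, ops$log(pred_var), Yt)
  out <- mlp_fwd(ops, cpp, inp)
  list(mu = ops$add(pred_mean, ops$cols(out, seq_len(d))),
       var = softplus_var(ops, ops$cols(out, d + seq_len(d))))
}

# full causal pass; Ylist: list over time of (batch x obs_dim) matrices.
# Returns per-step list(pred_mean, pred_var, mu, var).
filter_graph <- function(ops, params, gpp, cpp, Ylist) {
  L <- length(Ylist)
  n <- nrow(Ylist[[1L]])
  d <- params$latent_dim
  pm <- prior_moments(ops, gpp$prior)
  ones <- ops$const(matrix(1, n, 1L))
  pred_mean <- ops$mm(ones, pm$mu)
  pred_var <- ops$mm(ones, pm$var)
  out <- vector("list", L)
  for (t in seq_len(L)) {
    if (t > 1L) {
      pr <- predict_graph(ops, params, gpp, out[[t - 1L]]$mu, out[[t - 1L]]$var)
      pred_mean <- pr$mean
      pred_var <- pr$var
    }
    st <- combine_graph(ops, cpp, pred_mean, pred_var, ops$const(Ylist[[t]]))
    out[[t]] <- list(pred_mean = pred_mean, pred_var = pred_var,
                     mu = st$mu, var = st$var)
  }
  out
}

#' Predict step of the filter
#'
#' Propagates a filtered state through the frozen transition network:
#' moment-matched mean and variance of the mixture at the filtered mean,
#' plus the filtered variance pushed through the (finite-difference)
#' Jacobian of the mixture mean. For a single-component linear transition
#' z' = a z + w this is exactly the Kalman predict step
#' (a m, a^2 P + Q).
#'
#' @param state list with \code{mu} and \code{var} (d-vectors), e.g. one row
#'   of a filtered trajectory.
#' @param params frozen \code{\link{generative_params}}.
#' @return List with \code{mean} and \code{var} d-vectors.
#' @export
predict_state <- function(state, params) {
  ops <- model_ops()
  d <- params$latent_dim
  pr <- predict_graph(ops, params, gen_trainable(params),
                      matrix(state$mu, 1L, d), matrix(state$var, 1L, d))
  list(mean = as.numeric(pr$mean), var = as.numeric(pr$var))
}

#' Correct step of the filter
#'
#' Deterministically maps the predicted moments and the current observation
#' window to the filtered Gaussian state via the combiner network.
#'
#' @param pred_mean,pred_var predicted moments (d-vectors).
#' @param y_t observation window (length obs_dim).
#' @param comb a \code{\link{combiner_params}} object.
#' @return List with \code{mu} and \code{var} d-vectors.
#' @export
combine_state <- function(pred_mean, pred_var, y_t, comb) {
  if (length(y_t) != comb$obs_dim) {
    stop("observation dimension mismatch: expected ", comb$obs_dim)
  }
  ops <- model_ops()
  st <- combine_graph(ops, comb_trainable(comb),
                      matrix(pred_mean, 1L), matrix(pred_var, 1L),
                      ops$const(matrix(y_t, 1L)))
  list(mu = as.numeric(st$mu), var = as.numeric(st$var))
}

#' Causal filtering of an observation sequence
#'
#' Iterates predict and correct from t = 0 (where the prediction is the
#' initial-prior moments) to T. The state at time t depends only on
#' y_{0:t}.
#'
#' @param y an \code{obs_seq} or (T+1) x obs_dim matrix.
#' @param params frozen \code{\link{generative_params}}.
#' @param comb trained \code{\link{combiner_params}}.
#' @return Object of class \code{latent_trajectory}: list with \code{mu} and
#'   \code{var} ((T+1) x d matrices), \code{pred_mu}, \code{pred_var}, and
#'   the sequence identifiers.
#' @export
filter_sequence <- function(y, params, comb) {
  Y <- obs_matrix(y)
  stopifnot(nrow(Y) >= 1L)
  ops <- model_ops()
  Ylist <- lapply(seq_len(nrow(Y)), function(i) Y[i, , drop = FALSE])
  out <- filter_graph(ops, params, gen_trainable(params),
                      comb_trainable(comb), Ylist)
  structure(list(
    mu = do.call(rbind, lapply(out, `[[`, "mu")),
    var = do.call(rbind, lapply(out, `[[`, "var")),
    pred_mu = do.call(rbind, lapply(out, `[[`, "pred_mean")),
    pred_var = do.call(rbind, lapply(out, `[[`, "pred_var")),
    subject_id = attr(y, "subject_id") %||% NA_character_,
    motion = attr(y, "motion") %||% NA_character_
  ), class = "latent_trajectory")
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat(sprintf("<latent_trajectory> subject=%s motion=%s T+1=%d d=%d\n",
              x$subject_id, x$motion, nrow(x$mu), ncol(x$mu)))
  invisible(x)
}

default_stage2_config <- function() {
  list(batch_size = 64L, epochs = 20L, lr = 1e-3,
       subseq_len = 100L, stride = 50L, hidden = c(32L, 32L), seed = 1L)
}

#' Train the second stage (combiner network)
#'
#' Maximises the sequence evidence lower bound with the combiner-induced
#' causal filtering distribution substituted for the encoder posterior. Only
#' the combiner parameters receive gradients; the backbone enters the graph
#' as constants, so the transition and emitter networks stay bitwise fixed.
#'
#' @param dataset list of \code{obs_seq} matrices.
#' @param params trained, frozen \code{\link{generative_params}}.
#' @param config list overriding defaults: \code{batch_size} (64),
#'   \code{epochs} (20), \code{lr} (1e-3), \code{subseq_len} (100),
#'   \code{stride} (50), \code{hidden} (c(32, 32)), \code{seed} (1).
#' @return List with \code{combiner} (\code{combiner_params}), \code{log}
#'   (per-epoch objective) and \code{config}.
#' @export
train_stage2 <- function(dataset, params, config = list()) {
  if (!inherits(params, "generative_params")) {
    stop("train_stage2 requires trained stage-1 generative_params")
  }
  if (is.matrix(dataset)) dataset <- list(dataset)
  cfg <- utils::modifyList(default_stage2_config(), config)
  set.seed(cfg$seed)
  subs <- slice_subsequences(dataset, cfg$subseq_len, cfg$stride)
  d <- params$latent_dim
  comb <- combiner_params(params$obs_dim, d, cfg$hidden)
  cpp <- comb_trainable(comb)
  opt <- adam_init(cpp, lr = cfg$lr)
  gpp <- gen_trainable(params)
  log <- data.frame(epoch = integer(), objective = numeric())
  n_sub <- length(subs)
  L <- cfg$subseq_len
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_sub)
    ep_obj <- 0
    for (b0 in seq.int(1L, n_sub, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n_sub)]
      nb <- length(idx)
      Ylist <- lapply(seq_len(L), function(t) {
        do.call(rbind, lapply(subs[idx], function(S) S[t, , drop = FALSE]))
      })
      eps <- lapply(seq_len(L), function(t) matrix(stats::rnorm(nb * d), nb, d))
      tp <- ad_tape()
      ops <- model_ops(tp)
      # backbone as constants: gradients cannot reach theta
      gconst <- par_map(gpp, function(x) ad_const(tp, as_mat(x)))
      cl <- par_leaf(tp, cpp)
      obj <- stage2_objective(ops, params, gconst, cl, Ylist, eps)
      loss <- ad_scale(tp, obj, -1 / nb)
      if (!is.finite(ad_value(tp, loss)[1L])) {
        stop("stage-2 training diverged: non-finite loss at epoch ", ep)
      }
      ad_backward(tp, loss)
      cpp <- adam_step(opt, cpp, par_grads(tp, cl))
      ep_obj <- ep_obj + as.numeric(ad_value(tp, obj))
    }
    log <- rbind(log, data.frame(epoch = ep, objective = ep_obj / n_sub))
  }
  list(combiner = comb_update(comb, cpp), log = log, config = cfg)
}

# ELBO with the filtering distribution q_psi: scalar node, summed over batch
stage2_objective <- function(ops, params, gpp, cpp, Ylist, eps) {
  L <- length(Ylist)
  d <- params$latent_dim
  states <- filter_graph(ops, params, gpp, cpp, Ylist)
  z <- vector("list", L)
  recon <- NULL
  for (t in seq_len(L)) {
    sd_t <- ops$sqrt(states[[t]]$var)
    z[[t]] <- ops$add(states[[t]]$mu, ops$mul(sd_t, ops$const(eps[[t]])))
    r <- emit_logdens(ops, params, gpp$emit, z[[t]], Ylist[[t]])
    recon <- if (is.null(recon)) r else ops$add(recon, r)
  }
  pm <- prior_moments(ops, gpp$prior)
  kl0 <- kl_rows_b(ops, states[[1L]]$mu, states[[1L]]$var, pm$mu, pm$var)
  klsum <- NULL
  for (t in seq_len(L)[-1L]) {
    tr <- trans_forward(ops, gpp$trans, z[[t - 1L]], params$mixture_K, d)
    if (params$mixture_K == 1L) {
      kt <- kl_rows(ops, states[[t]]$mu, states[[t]]$var,
                    tr$mu[[1L]], tr$var[[1L]])
    } else {
      lq <- gauss_logdens_rows(ops, states[[t]]$mu, states[[t]]$var, z[[t]])
      lp <- mixture_logdens(ops, tr, z[[t]])
      kt <- ops$sub(lq, lp)
    }
    klsum <- if (is.null(klsum)) kt else ops$add(klsum, kt)
  }
  if (is.null(klsum)) klsum <- ops$const(matrix(0, nrow(Ylist[[1L]]), 1L))
  ops$sub(ops$sum(recon), ops$add(ops$sum(kl0), ops$sum(klsum)))
}
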