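# The user-facing fitting function and its S3 methods.

#' Fit a two-stage latent dynamics model
#'
#' Fits the full two-stage procedure to a set of observation-window
#' sequences: stage 1 trains the backbone generative model (initial prior,
#' mixture-density transition network, emitter network) jointly with a
#' backward-recurrent encoder by maximising the evidence lower bound;
#' stage 2 freezes the backbone and trains a combiner network that filters
#' latent states causally in a predict-correct cycle.
#'
#' @param y a list of \code{obs_seq} matrices (see
#'   \code{\link{build_observations}}), or a single one. Raw
#'   \code{feature_sequence} recordings can be converted with
#'   \code{\link{fit_minmax}} + \code{\link{build_observations}}.
#' @param latent_dim latent dimension d, typically 2 or 3.
#' @param mixture_K transition mixture components (default 1).
#' @param hidden hidden widths of the transition/emitter/combiner MLPs.
#' @param rnn_hidden encoder GRU width.
#' @param emitter_family "gaussian" (default) or "multinomial".
#' @param epochs length-2 vector: epochs for stage 1 and stage 2.
#' @param lr length-2 vector: learning rates for the two stages.
#' @param batch_size minibatch size (default 64).
#' @param subseq_len,stride training-subsequence slicing of long recordings.
#' @param seed master seed; the whole fit is reproducible under it.
#' @param scaling optional \code{minmax_spec} to remember with the fit (used
#'   when predicting from raw feature sequences).
#' @return Object of class \code{ldmf} with components \code{params},
#'   \code{encoder}, \code{combiner}, the training logs and the call.
#' @seealso \code{\link{filter_sequence}}, \code{\link{predict.ldmf}},
#'   \code{\link{run_cross_validation}}
#' @examples
#' \donttest{
#' coh <- generate_cohort(1, 2, seed = 7, duration = 8)
#' spec <- fit_minmax(coh$recordings)
#' obs <- lapply(coh$recordings, build_observations, spec = spec)
#' fit <- ldmf(obs, latent_dim = 2, hidden = 8, rnn_hidden = 8,
#'             epochs = c(2, 2), subseq_len = 40, seed = 1)
#' print(fit)
#' traj <- predict(fit, obs[[1]])
#' }
#' @export
ldmf <- function(y, latent_dim = 2L, mixture_K = 1L, hidden = c(32L, 32L),
                 rnn_hidden = 32L,
                 emitter_family = c("gaussian", "multinomial"),
                 epochs = c(20L, 20L), lr = c(1e-3, 1e-3),
                 batch_size = 64L, subseq_len = 100L, stride = 50L,
                 seed = 1L, scaling = NULL) {
  emitter_family <- match.arg(emitter_family)
  if (is.matrix(y)) y <- list(y)
  epochs <- rep_len(epochs, 2L)
  lr <- rep_len(lr, 2L)
  s1 <- train_stage1(y, list(
    latent_dim = latent_dim, mixture_K = mixture_K, hidden = hidden,
    rnn_hidden = rnn_hidden, emitter_family = emitter_family,
    batch_size = batch_size, epochs = epochs[1L], lr = lr[1L],
    subseq_len = subseq_len, stride = stride, seed = seed))
  s2 <- train_stage2(y, s1$params, list(
    batch_size = batch_size, epochs = epochs[2L], lr = lr[2L],
    subseq_len = subseq_len, stride = stride, hidden = hidden,
    seed = seed + 1L))
  structure(list(
    params = s1$params, encoder = s1$encoder, combiner = s2$combiner,
    stage1_log = s1$log, stage2_log = s2$log,
    scaling = scaling, latent_dim = s1$params$latent_dim,
    call = match.call()
  ), class = "ldmf")
}

#' @export
print.ldmf <- function(x, ...) {
  cat("Two-stage latent dynamics model\n")
  cat(sprintf("  latent dim %d, obs dim %d, transition mixture K=%d, emitter %s\n",
              x$params$latent_dim, x$params$obs_dim, x$params$mixture_K,
              x$params$emitter_family))
  if (nrow(x$stage1_log)) {
    cat(sprintf("  stage-1 ELBO: %.2f (epoch 1) -> %.2f (epoch %d)\n",
                x$stage1_log$elbo[1L], utils::tail(x$stage1_log$elbo, 1L),
                nrow(x$stage1_log)))
  }
  if (nrow(x$stage2_log)) {
    cat(sprintf("  stage-2 objective: %.2f -> %.2f (epoch %d)\n",
                x$stage2_log$objective[1L],
                utils::tail(x$stage2_log$objective, 1L), nrow(x$stage2_log)))
  }
  invisible(x)
}

#' @export
summary.ldmf <- function(object, ...) {
  n_par <- par_count(gen_trainable(object$params)) +
    par_count(enc_trainable(object$encoder)) +
    par_count(comb_trainable(object$combiner))
  out <- list(latent_dim = object$params$latent_dim,
              obs_dim = object$params$obs_dim,
              mixture_K = object$params$mixture_K,
              emitter_family = object$params$emitter_family,
              n_parameters = n_par,
              stage1_log = object$stage1_log,
              stage2_log = object$stage2_log)
  class(out) <- "summary.ldmf"
  out
}

#' @export
print.summary.ldmf <- function(x, ...) {
  cat(sprintf("Two-stage latent dynamics model: d=%d, obs=%d, K=%d, emitter=%s\n",
              x$latent_dim, x$obs_dim, x$mixture_K, x$emitter_family))
  cat(sprintf("  %d trainable parameters\n", x$n_parameters))
  cat("  stage-1 training (per-subsequence nats):\n")
  print(utils::tail(x$stage1_log, 3L), row.names = FALSE)
  cat("  stage-2 training:\n")
  print(utils::tail(x$stage2_log, 3L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.ldmf <- function(object, ...) {
  list(generative = gen_trainable(object$params),
       encoder = enc_trainable(object$encoder),
       combiner = comb_trainable(object$combiner))
}

#' Predict from a fitted two-stage model
#'
#' \code{type = "latent"} runs the causal filter and returns the latent
#' trajectory; \code{type = "response"} additionally pushes the filtered
#' means through the emitter and returns the reconstructed windows.
#'
#' @param object an \code{\link{ldmf}} fit.
#' @param newdata an \code{obs_seq} matrix (or list of them); a
#'   \code{feature_sequence} is windowed automatically when the fit stores a
#'   scaling spec.
#' @param type "latent" or "response".
#' @param ... unused.
#' @return A \code{latent_trajectory} (or reconstruction matrix), or a list
#'   of them when \code{newdata} is a list.
#' @export
predict.ldmf <- function(object, newdata, type = c("latent", "response"), ...) {
  type <- match.arg(type)
  one <- function(y) {
    if (inherits(y, "feature_sequence")) {
      if (is.null(object$scaling)) {
        stop("fit carries no scaling spec; pass windowed observations")
      }
      y <- build_observations(y, object$scaling)
    }
    if (type == "latent") filter_sequence(y, object$params, object$combiner)
    else reconstruct_ldmf(object, obs_matrix(y))
  }
  if (is.list(newdata) && !inherits(newdata, "feature_sequence")) {
    lapply(newdata, one)
  } else {
    one(newdata)
  }
}

#' Reconstruct observation windows through the filter and emitter
#'
#' The model reconstruction for the MSE comparison: causal filtering of the
#' windows, then the emitter mean at the filtered posterior mean.
#'
#' @param object an \code{\link{ldmf}} fit.
#' @param y n x obs_dim window matrix (one sequence, in time order).
#' @return n x obs_dim reconstruction.
#' @export
reconstruct_ldmf <- function(object, y) {
  traj <- filter_sequence(y, object$params, object$combiner)
  ops <- model_ops()
  if (object$params$emitter_family == "gaussian") {
    emit_forward_gauss(ops, object$params$emit, traj$mu,
                       object$params$obs_dim)$mu
  } else {
    # multinomial emitter: expected bin midpoint per feature
    logits <- mlp_fwd(ops, object$params$emit, traj$mu)
    B <- object$params$bins
    p <- object$params$obs_dim
    out <- matrix(0, nrow(traj$mu), p)
    mids <- (seq_len(B) - 0.5) / B
    for (f in seq_len(p)) {
      lf <- logits[, (f - 1L) * B + seq_len(B), drop = FALSE]
      w <- exp(lf - apply(lf, 1L, max))
      out[, f] <- (w %*% mids) / rowSums(w)
    }
    out
  }
}

#' @export
residuals.ldmf <- function(object, y, ...) {
  Y <- obs_matrix(y)
  Y - reconstruct_ldmf(object, Y)
}

#' Simulate observation sequences from the fitted generative model
#'
#' @param object an \code{\link{ldmf}} fit.
#' @param nsim number of sequences.
#' @param seed integer seed.
#' @param T_len steps after time 0 per sequence.
#' @param ... unused.
#' @return List of lists with \code{z} and \code{y} matrices.
#' @export
simulate.ldmf <- function(object, nsim = 1L, seed = 1L, T_len = 100L, ...) {
  lapply(seq_len(nsim), function(i) {
    sample_trajectory(object$params, T_len, seed = seed + i - 1L)
  })
}

#' Plot a filtered latent trajectory
#'
#' @param x an \code{\link{ldmf}} fit.
#' @param y an \code{obs_seq} to filter and display (first two latent
#'   dimensions).
#' @param ... passed to \code{plot}.
#' @export
plot.ldmf <- function(x, y, ...) {
  traj <- filter_sequence(y, x$params, x$combiner)
  graphics::plot(traj$mu[, 1L], traj$mu[, 2L], type = "l",
                 xlab = expression(z[1]), ylab = expression(z[2]),
                 main = "Filtered latent trajectory", ...)
  invisible(traj)
}
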