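# Incremental PCA baseline, reconstruction MSE and the cross-validated
# MSE-ratio comparison.

#' Fit incremental principal component analysis
#'
#' Streaming PCA over mini-batches: each update stacks the previous singular
#' spectrum, the centred batch, and a mean-correction row, then keeps the
#' top-d right singular vectors. With all data in a single batch this is
#' exactly batch PCA. Component signs follow the largest-magnitude loading,
#' for determinism.
#'
#' @param train an \code{obs_seq} or n x p matrix of training windows.
#' @param d number of components (<= p).
#' @param batch_size mini-batch size (default 64, matching the training
#'   batch size; use \code{nrow(train)} for an exact batch-PCA fit).
#' @return Object of class \code{ipca_model} with \code{components} (d x p,
#'   orthonormal rows), \code{mean}, \code{singular_values}, \code{n_seen}.
#' @export
fit_ipca <- function(train, d, batch_size = 64L) {
  X <- obs_matrix(train)
  p <- ncol(X)
  if (d > p) stop("d = ", d, " exceeds observation dimension ", p)
  if (nrow(X) < d) stop("need at least d = ", d, " training windows")
  mean_ <- NULL
  comp <- NULL
  sv <- NULL
  n_seen <- 0
  batch_size <- max(batch_size, d) # every batch must support d components
  starts <- seq.int(1L, nrow(X), by = batch_size)
  for (s in starts) {
    B <- X[s:min(s + batch_size - 1L, nrow(X)), , drop = FALSE]
    m <- nrow(B)
    bmean <- colMeans(B)
    if (n_seen == 0) {
      mean_ <- bmean
      M <- sweep(B, 2L, bmean)
    } else {
      total <- n_seen + m
      corr <- sqrt(n_seen * m / total) * (mean_ - bmean)
      M <- rbind(comp * sv, sweep(B, 2L, bmean), corr)
      mean_ <- (n_seen * mean_ + m * bmean) / total
    }
    sdec <- svd(M, nu = 0, nv = p)
    keep <- seq_len(d)
    V <- t(sdec$v[, keep, drop = FALSE])
    # deterministic sign: largest-|loading| entry of each component positive
    for (j in keep) {
      i_max <- which.max(abs(V[j, ]))
      if (V[j, i_max] < 0) V[j, ] <- -V[j, ]
    }
    comp <- V
    sv <- sdec$d[keep]
    n_seen <- n_seen + m
  }
  structure(list(components = comp, mean = mean_, singular_values = sv,
                 n_seen = n_seen, d = d),
            class = "ipca_model")
}

#' @export
print.ipca_model <- function(x, ...) {
  cat(sprintf("<ipca_model> d=%d p=%d n_seen=%d\n",
              x$d, ncol(x$components), x$n_seen))
  invisible(x)
}

#' Project-and-reconstruct with an IPCA model
#'
#' @param model an \code{\link{ipca_model}}.
#' @param y n x p matrix of windows.
#' @return n x p reconstruction.
#' @export
reconstruct_ipca <- function(model, y) {
  Y <- obs_matrix(y)
  Xc <- sweep(Y, 2L, model$mean)
  sweep(Xc %*% t(model$components) %*% model$components, 2L, model$mean, `+`)
}

#' Mean squared reconstruction error
#'
#' (1/M) sum_k || x_k - xhat_k ||^2 over the M test windows.
#'
#' @param test an \code{obs_seq} or n x p matrix of test windows.
#' @param reconstructor function mapping an n x p matrix to its n x p
#'   reconstruction.
#' @return Scalar MSE in squared scaled units.
#' @export
reconstruction_mse <- function(test, reconstructor) {
  Y <- obs_matrix(test)
  if (nrow(Y) == 0L) stop("empty test set")
  R <- reconstructor(Y)
  mean(rowSums((Y - R)^2))
}

#' MSE ratio of the IPCA baseline over the latent-dynamics model
#'
#' Ratios above one mean the latent-dynamics reconstruction (causal filter
#' followed by the emitter mean) outperforms the linear baseline on the same
#' test windows.
#'
#' @param test test windows.
#' @param ipca a fitted \code{\link{ipca_model}}.
#' @param reconstructor the model reconstructor (see
#'   \code{\link{reconstruction_mse}}).
#' @return Scalar ratio MSE_IPCA / MSE_model.
#' @export
mse_ratio <- function(test, ipca, reconstructor) {
  m_ipca <- reconstruction_mse(test, function(Y) reconstruct_ipca(ipca, Y))
  m_model <- reconstruction_mse(test, reconstructor)
  if (m_model == 0) stop("model reconstruction MSE is zero; ratio undefined")
  m_ipca / m_model
}

#' Per-subject cross-validated comparison
#'
#' Runs the full training procedure per subject, motion and fold: the
#' recordings of one subject-motion cell are split into consecutive folds
#' (one recording per fold by default); each fold in turn is the test
#' recording while the remaining recordings train stage 1, stage 2 and the
#' IPCA baseline; both reconstructions are scored on the held-out windows.
#' Min-max scaling is fitted once on the whole cohort so one interval covers
#' every subject.
#'
#' @param cohort list with \code{recordings} (list of
#'   \code{feature_sequence}), e.g. from \code{\link{generate_cohort}}.
#' @param config list overriding defaults; notable entries:
#'   \code{latent_dim} (2), \code{k} (folds; default the number of
#'   recordings per cell), \code{epochs1}, \code{epochs2}, \code{lr1},
#'   \code{lr2}, \code{hidden}, \code{rnn_hidden}, \code{subseq_len},
#'   \code{stride}, \code{batch_size}, \code{seed}.
#' @param pooled if TRUE, train one model per fold on the pooled cohort
#'   (all subjects together), splitting folds by recording index, instead of
#'   fitting each subject-motion cell separately. Pooled folds are the
#'   cohort-level headline comparison; per-subject cells mirror the
#'   per-person experimental protocol.
#' @return Data frame with one row per subject, motion and fold:
#'   \code{mse_ipca}, \code{mse_ldmf} and \code{ratio}.
#' @export
run_cross_validation <- function(cohort, config = list(), pooled = FALSE) {
  cfg <- utils::modifyList(list(
    latent_dim = 2L, mixture_K = 1L, hidden = c(32L, 32L), rnn_hidden = 32L,
    batch_size = 64L, epochs1 = 10L, epochs2 = 10L, lr1 = 1e-3, lr2 = 1e-3,
    subseq_len = 100L, stride = 50L, k = NULL, ipca_batch = 64L, seed = 1L
  ), config)
  recs <- cohort$recordings
  spec <- fit_minmax(recs)
  cells <- if (pooled) {
    split(seq_along(recs), vapply(recs, function(r) {
      paste("cohort", r$motion, sep = "|")
    }, ""))
  } else {
    split(seq_along(recs), vapply(recs, function(r) {
      paste(r$subject_id, r$motion, sep = "|")
    }, ""))
  }
  out <- list()
  for (cell in names(cells)) {
    idx <- cells[[cell]]
    rec_no <- vapply(recs[idx], function(r) as.integer(r$recording %||% 1L), 1L)
    if (pooled) {
      # order by recording index so consecutive folds hold one recording per
      # subject
      idx <- idx[order(rec_no)]
      k <- cfg$k %||% length(unique(rec_no))
    } else {
      k <- cfg$k %||% length(idx)
    }
    if (length(idx) < k) {
      stop("subject-motion cell ", cell, " has ", length(idx),
           " recordings; need at least ", k)
    }
    folds <- kfold_split(length(idx), k)
    obs <- lapply(recs[idx], build_observations, spec = spec)
    parts <- strsplit(cell, "|", fixed = TRUE)[[1L]]
    for (f in folds) {
      train_obs <- obs[f$train_indices]
      test_obs <- obs[f$test_indices]
      fit <- ldmf(train_obs, latent_dim = cfg$latent_dim,
                  mixture_K = cfg$mixture_K, hidden = cfg$hidden,
                  rnn_hidden = cfg$rnn_hidden, batch_size = cfg$batch_size,
                  epochs = c(cfg$epochs1, cfg$epochs2),
                  lr = c(cfg$lr1, cfg$lr2), subseq_len = cfg$subseq_len,
                  stride = cfg$stride,
                  seed = cfg$seed + 1000L * f$fold_id)
      ipca <- fit_ipca(do.call(rbind, lapply(train_obs, obs_matrix)),
                       cfg$latent_dim, cfg$ipca_batch)
      # score each held-out recording separately (the filter is sequential)
      # and pool window-weighted
      pooled_mse <- function(reconstructor) {
        n <- vapply(test_obs, nrow, 1L)
        m <- vapply(test_obs, function(y) reconstruction_mse(y, reconstructor), 0)
        sum(n * m) / sum(n)
      }
      m_ipca <- pooled_mse(function(Y) reconstruct_ipca(ipca, Y))
      m_ldmf <- pooled_mse(function(Y) reconstruct_ldmf(fit, Y))
      out[[length(out) + 1L]] <- data.frame(
        subject = parts[1L], motion = parts[2L], dim = cfg$latent_dim,
        fold = f$fold_id, mse_ipca = m_ipca, mse_ldmf = m_ldmf,
        ratio = m_ipca / m_ldmf)
    }
  }
  do.call(rbind, out)
}

#' Aggregate a cross-validation report
#'
#' @param report data frame from \code{\link{run_cross_validation}}.
#' @return List with \code{by_subject} (fold-averaged per subject and
#'   motion), \code{by_motion} (averaged over subjects) and \code{pooled}
#'   (grand means over all folds).
#' @export
summarize_cv <- function(report) {
  agg <- function(df, by) {
    stats::aggregate(df[c("mse_ipca", "mse_ldmf", "ratio")], by = by, FUN = mean)
  }
  list(
    by_subject = agg(report, report[c("subject", "motion", "dim")]),
    by_motion = agg(report, report[c("motion", "dim")]),
    pooled = data.frame(mse_ipca = mean(report$mse_ipca),
                        mse_ldmf = mean(report$mse_ldmf),
                        ratio = mean(report$ratio))
  )
}
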