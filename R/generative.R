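# Backbone generative model: initial prior, mixture-density transition
# network, MLP emitter, joint log-probability and ancestral sampling.
#
# The *_forward functions are written against the ops interpreter so the
# training stages can record them on a tape; the exported distribution
# helpers evaluate them numerically.

LOG2PI <- log(2 * pi)
VAR_FLOOR <- 1e-6

# extra broadcast primitives used by the model forwards
ad_subcol <- function(tp, a, b) { # A - c, c is n x 1 broadcast over columns
  na <- ad_node(tp, a); nb <- ad_node(tp, b)
  A <- na[[1L]]; cv <- nb[[1L]]
  need <- na[[2L]] || nb[[2L]]
  ad_push(tp, A - matrix(cv, nrow(A), ncol(A)), need, if (need) function(g) {
    ad_acc(tp, a, g)
    ad_acc(tp, b, matrix(-rowSums(g), ncol = 1L))
  })
}

ad_mulcol <- function(tp, a, b) { # A * c columnwise broadcast
  na <- ad_node(tp, a); nb <- ad_node(tp, b)
  A <- na[[1L]]; cv <- nb[[1L]]
  need <- na[[2L]] || nb[[2L]]
  Cm <- matrix(cv, nrow(A), ncol(A))
  ad_push(tp, A * Cm, need, if (need) function(g) {
    ad_acc(tp, a, g * Cm)
    ad_acc(tp, b, matrix(rowSums(g * A), ncol = 1L))
  })
}

ops_extras_num <- list(
  subcol = function(a, b) a - matrix(b, nrow(a), ncol(a)),
  mulcol = function(a, b) a * matrix(b, nrow(a), ncol(a))
)

model_ops <- function(tp = NULL) {
  if (is.null(tp)) c(ops_num(), ops_extras_num)
  else c(ops_tape(tp), list(
    subcol = function(a, b) ad_subcol(tp, a, b),
    mulcol = function(a, b) ad_mulcol(tp, a, b)
  ))
}

#' Construct backbone generative-model parameters
#'
#' The backbone holds three pieces: a diagonal-Gaussian initial prior over
#' the latent state, a mixture-density transition network giving
#' p(z_t | z_{t-1}) as a mixture of K diagonal Gaussians whose weights,
#' means and variances are MLP outputs of z_{t-1}, and an emitter network
#' giving the observation distribution p(y_t | z_t). The default emitter is
#' a diagonal Gaussian over the 24-dimensional scaled window; a discretised
#' multinomial emitter (each feature binned into \code{bins} equal bins of
#' [0, 1]) is available via \code{emitter_family = "multinomial"}.
#' Variances are produced through a softplus map plus a small floor, so they
#' are positive for any network output. Uses the current RNG state for
#' weight initialisation.
#'
#' @param latent_dim latent dimension d (the package default setups use 2 or
#'   3).
#' @param obs_dim observation dimension (24 for stacked windows).
#' @param mixture_K number of transition mixture components (default 1, a
#'   single Gaussian).
#' @param hidden integer vector of hidden-layer widths shared by transition
#'   and emitter MLPs; \code{integer(0)} gives linear networks.
#' @param emitter_family "gaussian" or "multinomial".
#' @param bins number of bins per feature for the multinomial emitter.
#' @param emitter_mean_bias optional length-\code{obs_dim} vector initialising
#'   the emitter mean output bias (commonly the training-data mean).
#' @param emitter_var,transition_var initial output variances.
#' @return Object of class \code{generative_params}.
#' @export
generative_params <- function(latent_dim = 2L, obs_dim = 24L, mixture_K = 1L,
                              hidden = c(32L, 32L),
                              emitter_family = c("gaussian", "multinomial"),
                              bins = 32L, emitter_mean_bias = NULL,
                              emitter_var = 0.1, transition_var = 0.1) {
  emitter_family <- match.arg(emitter_family)
  d <- as.integer(latent_dim)
  K <- as.integer(mixture_K)
  p <- as.integer(obs_dim)
  trans_out <- K + 2L * K * d
  trans_bias <- c(rep(0, K), rep(0, K * d),
                  rep(softplus_inv(transition_var), K * d))
  emit <- if (emitter_family == "gaussian") {
    eb <- c(if (is.null(emitter_mean_bias)) rep(0, p) else emitter_mean_bias,
            rep(softplus_inv(emitter_var), p))
    mlp_init(d, hidden, 2L * p, out_bias = eb)
  } else {
    mlp_init(d, hidden, p * as.integer(bins))
  }
  structure(list(
    latent_dim = d, obs_dim = p, mixture_K = K, hidden = hidden,
    emitter_family = emitter_family, bins = as.integer(bins),
    prior = list(mu = matrix(0, 1L, d),
                 rho = matrix(softplus_inv(1), 1L, d)),
    trans = mlp_init(d, hidden, trans_out, out_bias = trans_bias),
    emit = emit
  ), class = "generative_params")
}

#' @export
print.generative_params <- function(x, ...) {
  cat(sprintf(
    "<generative_params> d=%d obs=%d K=%d hidden=[%s] emitter=%s\n",
    x$latent_dim, x$obs_dim, x$mixture_K,
    paste(x$hidden, collapse = ","), x$emitter_family))
  invisible(x)
}

# trainable matrices of the backbone (the shape Adam and the tape see)
gen_trainable <- function(params) {
  list(prior = params$prior, trans = params$trans, emit = params$emit)
}

gen_update <- function(params, tr) {
  params$prior <- tr$prior
  params$trans <- tr$trans
  params$emit <- tr$emit
  params
}

# --- ops-generic model forwards --------------------------------------------

# diagonal-Gaussian log-density, summed over columns: returns n x 1
gauss_logdens_rows <- function(ops, mu, var, x) {
  diff <- ops$sub(x, mu)
  quad <- ops$div(ops$square(diff), var)
  ops$scale(ops$rowsum(ops$add(ops$addc(ops$log(var), LOG2PI), quad)), -0.5)
}

# KL( N(mu_q, var_q) || N(mu_p, var_p) ), diagonal, summed over columns: n x 1
kl_rows <- function(ops, mu_q, var_q, mu_p, var_p) {
  ratio <- ops$div(var_q, var_p)
  quad <- ops$div(ops$square(ops$sub(mu_q, mu_p)), var_p)
  inner <- ops$addc(ops$sub(ops$add(ratio, quad), ops$log(ratio)), -1)
  ops$scale(ops$rowsum(inner), 0.5)
}

softplus_var <- function(ops, rho) ops$addc(ops$softplus(rho), VAR_FLOOR)

# transition network forward: returns log-weights (n x K) and per-component
# means/variances (lists of n x d)
trans_forward <- function(ops, tpp, Z, K, d) {
  out <- mlp_fwd(ops, tpp, Z)
  # K = 1: single Gaussian, no weight machinery needed
  logw <- if (K > 1L) {
    logits <- ops$cols(out, seq_len(K))
    ops$subcol(logits, ops$lse_rows(logits))
  }
  mu <- vector("list", K)
  var <- vector("list", K)
  for (k in seq_len(K)) {
    mu[[k]] <- ops$cols(out, K + (k - 1L) * d + seq_len(d))
    var[[k]] <- softplus_var(ops, ops$cols(out, K + K * d + (k - 1L) * d + seq_len(d)))
  }
  list(logw = logw, mu = mu, var = var, K = K)
}

# mixture log-density at Z_next: n x 1
mixture_logdens <- function(ops, tr, Z_next) {
  if (tr$K == 1L) {
    return(gauss_logdens_rows(ops, tr$mu[[1L]], tr$var[[1L]], Z_next))
  }
  comp <- vector("list", tr$K)
  for (k in seq_len(tr$K)) {
    lk <- gauss_logdens_rows(ops, tr$mu[[k]], tr$var[[k]], Z_next)
    comp[[k]] <- ops$add(lk, ops$cols(tr$logw, k))
  }
  ops$lse_rows(do.call(ops$cbind, comp))
}

# moment-matched mean/variance of the mixture (law of total variance): n x d
mixture_moments <- function(ops, tr) {
  if (tr$K == 1L) return(list(mean = tr$mu[[1L]], var = tr$var[[1L]]))
  w <- ops$exp(tr$logw)
  mean_ <- NULL
  for (k in seq_len(tr$K)) {
    term <- ops$mulcol(tr$mu[[k]], ops$cols(w, k))
    mean_ <- if (is.null(mean_)) term else ops$add(mean_, term)
  }
  var_ <- NULL
  for (k in seq_len(tr$K)) {
    second <- ops$add(tr$var[[k]], ops$square(tr$mu[[k]]))
    term <- ops$mulcol(second, ops$cols(w, k))
    var_ <- if (is.null(var_)) term else ops$add(var_, term)
  }
  # law of total variance; components carry a 1e-6 variance floor so the
  # difference stays positive despite rounding
  var_ <- ops$sub(var_, ops$square(mean_))
  list(mean = mean_, var = var_)
}

# emitter forward (gaussian family): list(mu, var), each n x obs_dim
emit_forward_gauss <- function(ops, epp, Z, obs_dim) {
  out <- mlp_fwd(ops, epp, Z)
  list(mu = ops$cols(out, seq_len(obs_dim)),
       var = softplus_var(ops, ops$cols(out, obs_dim + seq_len(obs_dim))))
}

# emitter log-density, both families: n x 1. Y is a plain matrix (data).
emit_logdens <- function(ops, params, epp, Z, Y) {
  p <- params$obs_dim
  if (params$emitter_family == "gaussian") {
    e <- emit_forward_gauss(ops, epp, Z, p)
    gauss_logdens_rows(ops, e$mu, e$var, ops$const(Y))
  } else {
    B <- params$bins
    logits <- mlp_fwd(ops, epp, Z)
    idx <- pmin(pmax(floor(Y * B), 0), B - 1) # n x p bin indices
    total <- NULL
    for (f in seq_len(p)) {
      lf <- ops$cols(logits, (f - 1L) * B + seq_len(B))
      onehot <- matrix(0, nrow(Y), B)
      onehot[cbind(seq_len(nrow(Y)), idx[, f] + 1L)] <- 1
      picked <- ops$rowsum(ops$mul(lf, ops$const(onehot)))
      term <- ops$sub(picked, ops$lse_rows(lf))
      total <- if (is.null(total)) term else ops$add(total, term)
    }
    total
  }
}

prior_moments <- function(ops, ppp) {
  list(mu = ppp$mu, var = softplus_var(ops, ppp$rho))
}

# --- exported numeric distribution interface --------------------------------

#' Initial-prior distribution over the latent state
#'
#' @param params a \code{\link{generative_params}} object.
#' @return List with \code{mean} and \code{var} (d-vectors), a
#'   \code{log_density(z)} function (z a d-vector or n x d matrix), and a
#'   \code{sample(n)} function using the current RNG state.
#' @export
initial_prior <- function(params) {
  ops <- model_ops()
  pm <- prior_moments(ops, params$prior)
  mu <- as.numeric(pm$mu)
  var <- as.numeric(pm$var)
  d <- params$latent_dim
  list(
    mean = mu, var = var,
    log_density = function(z) {
      Z <- if (is.matrix(z)) z else matrix(z, ncol = d)
      as.numeric(gauss_logdens_rows(ops, matrix(mu, nrow(Z), d, byrow = TRUE),
                                    matrix(var, nrow(Z), d, byrow = TRUE), Z))
    },
    sample = function(n) {
      matrix(stats::rnorm(n * d, mean = rep(mu, each = n),
                          sd = rep(sqrt(var), each = n)), n, d)
    }
  )
}

#' Transition distribution p(z_t | z_{t-1})
#'
#' Evaluates the mixture-density transition network at \code{z_prev}. With
#' K = 1 the mixture reduces to a single diagonal Gaussian.
#'
#' @param z_prev d-vector (or n x d matrix of conditioning points).
#' @param params a \code{\link{generative_params}} object.
#' @return List with \code{weights} (n x K), \code{means}, \code{vars}
#'   (lists of n x d matrices per component), a \code{log_density(z)}
#'   function and a \code{sample(n)} function (single conditioning point
#'   only) using the current RNG state.
#' @export
transition_distribution <- function(z_prev, params) {
  Z <- if (is.matrix(z_prev)) z_prev else matrix(z_prev, ncol = params$latent_dim)
  if (!all(is.finite(Z))) stop("non-finite conditioning state")
  ops <- model_ops()
  tr <- trans_forward(ops, params$trans, Z, params$mixture_K, params$latent_dim)
  d <- params$latent_dim
  list(
    weights = if (tr$K == 1L) matrix(1, nrow(Z), 1L) else exp(tr$logw),
    means = tr$mu, vars = tr$var,
    log_density = function(z) {
      Zq <- if (is.matrix(z)) z else matrix(z, ncol = d)
      if (nrow(Z) == 1L && nrow(Zq) > 1L) {
        trq <- list(logw = if (tr$K > 1L)
                      matrix(tr$logw, nrow(Zq), ncol(tr$logw), byrow = TRUE),
                    mu = lapply(tr$mu, function(m) matrix(m, nrow(Zq), d, byrow = TRUE)),
                    var = lapply(tr$var, function(v) matrix(v, nrow(Zq), d, byrow = TRUE)),
                    K = tr$K)
        as.numeric(mixture_logdens(ops, trq, Zq))
      } else {
        as.numeric(mixture_logdens(ops, tr, Zq))
      }
    },
    sample = function(n) {
      stopifnot(nrow(Z) == 1L)
      w <- if (tr$K == 1L) 1 else exp(tr$logw[1L, ])
      comp <- sample.int(tr$K, n, replace = TRUE, prob = w)
      out <- matrix(0, n, d)
      for (i in seq_len(n)) {
        k <- comp[i]
        out[i, ] <- stats::rnorm(d, mean = tr$mu[[k]][1L, ],
                                 sd = sqrt(tr$var[[k]][1L, ]))
      }
      out
    }
  )
}

#' Emitter distribution p(y_t | z_t)
#'
#' @param z d-vector or n x d matrix of latent states.
#' @param params a \code{\link{generative_params}} object.
#' @return For the Gaussian family: list with \code{mean}, \code{var}
#'   (n x obs_dim) and \code{log_density(y)}. For the multinomial family:
#'   list with per-feature bin \code{log_probs} (n x obs_dim*bins) and
#'   \code{log_density(y)}.
#' @export
emitter_distribution <- function(z, params) {
  d <- params$latent_dim
  Z <- if (is.matrix(z)) z else matrix(z, ncol = d)
  if (ncol(Z) != d) stop("latent dimension mismatch: expected ", d)
  ops <- model_ops()
  if (params$emitter_family == "gaussian") {
    e <- emit_forward_gauss(ops, params$emit, Z, params$obs_dim)
    list(
      mean = e$mu, var = e$var,
      log_density = function(y) {
        Y <- if (is.matrix(y)) y else matrix(y, ncol = params$obs_dim)
        if (ncol(Y) != params$obs_dim) stop("observation dimension mismatch")
        as.numeric(emit_logdens(ops, params, params$emit, Z, Y))
      }
    )
  } else {
    logits <- mlp_fwd(ops, params$emit, Z)
    list(
      logits = logits,
      log_density = function(y) {
        Y <- if (is.matrix(y)) y else matrix(y, ncol = params$obs_dim)
        as.numeric(emit_logdens(ops, params, params$emit, Z, Y))
      }
    )
  }
}

#' Joint log-probability of a latent/observation trajectory
#'
#' log p(z_0) + log p(y_0|z_0) + sum_t [ log p(y_t|z_t) + log p(z_t|z_{t-1}) ].
#'
#' @param y (T+1) x obs_dim observation matrix.
#' @param z (T+1) x d latent matrix.
#' @param params a \code{\link{generative_params}} object.
#' @return Scalar log-probability in nats.
#' @export
joint_log_prob <- function(y, z, params) {
  y <- obs_matrix(y)
  z <- as_mat(z)
  if (nrow(y) != nrow(z)) stop("length mismatch: y has ", nrow(y),
                               " rows, z has ", nrow(z))
  ops <- model_ops()
  n <- nrow(z)
  pm <- prior_moments(ops, params$prior)
  lp <- as.numeric(gauss_logdens_rows(
    ops, matrix(pm$mu, 1L), matrix(pm$var, 1L), z[1L, , drop = FALSE]))
  lp <- lp + sum(as.numeric(emit_logdens(ops, params, params$emit, z, y)))
  if (n > 1L) {
    tr <- trans_forward(ops, params$trans, z[-n, , drop = FALSE],
                        params$mixture_K, params$latent_dim)
    lp <- lp + sum(as.numeric(mixture_logdens(ops, tr, z[-1L, , drop = FALSE])))
  }
  lp
}

#' Ancestral sampling from the generative model
#'
#' Draws z_0 from the initial prior, propagates through the transition
#' mixture, and emits observations (Gaussian family: mean + noise;
#' multinomial family: bin midpoints).
#'
#' @param params a \code{\link{generative_params}} object.
#' @param T_len number of steps after time 0.
#' @param seed integer seed.
#' @return List with \code{z} ((T+1) x d) and \code{y} ((T+1) x obs_dim).
#' @export
sample_trajectory <- function(params, T_len, seed = 1L) {
  stopifnot(T_len >= 0)
  set.seed(seed)
  d <- params$latent_dim
  p <- params$obs_dim
  z <- matrix(0, T_len + 1L, d)
  y <- matrix(0, T_len + 1L, p)
  pr <- initial_prior(params)
  z[1L, ] <- pr$sample(1L)
  if (T_len > 0) for (t in 2:(T_len + 1L)) {
    z[t, ] <- transition_distribution(z[t - 1L, ], params)$sample(1L)
  }
  ops <- model_ops()
  if (params$emitter_family == "gaussian") {
    e <- emit_forward_gauss(ops, params$emit, z, p)
    y <- e$mu + matrix(stats::rnorm(length(e$mu)), nrow(e$mu)) * sqrt(e$var)
  } else {
    logits <- mlp_fwd(ops, params$emit, z)
    B <- params$bins
    for (t in seq_len(T_len + 1L)) {
      for (f in seq_len(p)) {
        lf <- logits[t, (f - 1L) * B + seq_len(B)]
        pf <- exp(lf - max(lf)); pf <- pf / sum(pf)
        y[t, f] <- (sample.int(B, 1L, prob = pf) - 0.5) / B
      }
    }
  }
  list(z = z, y = y)
}
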