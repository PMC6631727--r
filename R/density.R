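# Continuous normalizing-flow density estimation over latent samples and
# thresholded normal-region extraction.
#
# The flow integrates dz/ds = f(z, s) from the data (s = 0) to a standard
# normal base (s = 1) with fixed-step RK4. f is a single-hidden-layer tanh
# network, which keeps the divergence (trace of the Jacobian) exact and
# cheap: with f = W2 tanh(Wz z + ws s + b1) + b2 the trace is
# (1 - h^2) %*% c with c_h = sum_i Wz[i,h] W2[h,i]. The log-density follows
# the instantaneous change of variables,
# log p(z) = log N(z(1); 0, I) + int_0^1 tr(df/dz) ds.

#' Initialise a continuous normalizing-flow density model
#'
#' The dynamics network starts at zero output (identity flow), so the
#' initial density is exactly the standard-normal base. Uses the current
#' RNG state for the input-side weights.
#'
#' @param d latent dimension.
#' @param hidden hidden width of the dynamics network.
#' @param n_steps fixed RK4 steps over the unit integration interval.
#' @return Object of class \code{density_model}.
#' @export
density_model <- function(d = 2L, hidden = 48L, n_steps = 40L) {
  d <- as.integer(d)
  structure(list(
    d = d, hidden = as.integer(hidden), n_steps = as.integer(n_steps),
    pp = list(Wz = glorot(d, hidden), ws = matrix(0, 1L, hidden),
              b1 = matrix(0, 1L, hidden),
              W2 = matrix(0, hidden, d), b2 = matrix(0, 1L, d)),
    fitted = FALSE
  ), class = "density_model")
}

# dynamics network and exact trace at (Z, s): list(f = n x d, tr = n x 1)
cnf_dynamics <- function(ops, pp, Z, s, with_trace = TRUE) {
  u <- ops$addb(ops$addb(ops$mm(Z, pp$Wz), pp$b1), ops$scale(pp$ws, s))
  h <- ops$tanh(u)
  f <- ops$addb(ops$mm(h, pp$W2), pp$b2)
  if (!with_trace) return(list(f = f))
  cvec <- ops$colsum(ops$mul(pp$Wz, ops$t(pp$W2))) # 1 x hidden
  dtanh <- ops$addc(ops$neg(ops$square(h)), 1)
  list(f = f, tr = ops$mm(dtanh, ops$t(cvec)))
}

# RK4 integration of the augmented state (z, log-det accumulator).
# direction +1: data -> base over s in [0, 1]; -1: base -> data.
cnf_integrate <- function(ops, pp, Z, n_steps, direction = 1,
                          with_trace = TRUE) {
  hstep <- direction / n_steps
  s <- if (direction > 0) 0 else 1
  n <- nrow(ops$value(Z))
  ell <- if (with_trace) ops$const(matrix(0, n, 1L)) else NULL
  for (i in seq_len(n_steps)) {
    k1 <- cnf_dynamics(ops, pp, Z, s, with_trace)
    z2 <- ops$add(Z, ops$scale(k1$f, hstep / 2))
    k2 <- cnf_dynamics(ops, pp, z2, s + hstep / 2, with_trace)
    z3 <- ops$add(Z, ops$scale(k2$f, hstep / 2))
    k3 <- cnf_dynamics(ops, pp, z3, s + hstep / 2, with_trace)
    z4 <- ops$add(Z, ops$scale(k3$f, hstep))
    k4 <- cnf_dynamics(ops, pp, z4, s + hstep, with_trace)
    incr <- ops$add(ops$add(k1$f, ops$scale(ops$add(k2$f, k3$f), 2)), k4$f)
    Z <- ops$add(Z, ops$scale(incr, hstep / 6))
    if (with_trace) {
      tincr <- ops$add(ops$add(k1$tr, ops$scale(ops$add(k2$tr, k3$tr), 2)), k4$tr)
      ell <- ops$add(ell, ops$scale(tincr, hstep / 6))
    }
    s <- s + hstep
  }
  list(Z = Z, ell = ell)
}

# log-density graph: n x 1 node
cnf_logdens_graph <- function(ops, pp, Zc, d, n_steps) {
  res <- cnf_integrate(ops, pp, Zc, n_steps, direction = 1)
  base <- ops$scale(ops$rowsum(ops$addc(ops$square(res$Z), LOG2PI)), -0.5)
  ops$add(base, res$ell)
}

#' Log-density under a flow model
#'
#' Integrates the sample to the base space, tracking the exact divergence
#' term along the path.
#'
#' @param model a \code{\link{density_model}}.
#' @param z d-vector or n x d matrix of evaluation points.
#' @return Numeric vector of log-densities in nats.
#' @export
log_density <- function(model, z) {
  Z <- if (is.matrix(z)) z else matrix(z, ncol = model$d)
  stopifnot(all(is.finite(Z)), ncol(Z) == model$d)
  ops <- model_ops()
  out <- as.numeric(cnf_logdens_graph(ops, model$pp, Z, model$d, model$n_steps))
  if (any(!is.finite(out))) stop("flow integration produced non-finite log-density")
  out
}

#' Sample from a flow model
#'
#' Draws from the standard-normal base and integrates backwards to data
#' space. Uses the current RNG state.
#'
#' @param model a \code{\link{density_model}}.
#' @param n number of samples.
#' @return n x d matrix.
#' @export
sample_density <- function(model, n) {
  Zb <- matrix(stats::rnorm(n * model$d), n, model$d)
  ops <- model_ops()
  res <- cnf_integrate(ops, model$pp, Zb, model$n_steps, direction = -1,
                       with_trace = FALSE)
  res$Z
}

#' Fit a flow density to latent samples
#'
#' Maximises the sample log-likelihood under the change-of-variables
#' objective by Adam on minibatches. Reproducible under \code{seed}.
#'
#' @param latent_samples n x d matrix (n >= 100) of latent points, e.g.
#'   filtered means pooled over a cohort.
#' @param config list overriding defaults: \code{hidden} (48),
#'   \code{n_steps} (40), \code{n_iter} (400), \code{batch_size} (256),
#'   \code{lr} (0.01), \code{seed} (1).
#' @return A fitted \code{\link{density_model}} with a \code{loss} trace.
#' @export
fit_density <- function(latent_samples, config = list()) {
  X <- as.matrix(latent_samples)
  if (nrow(X) < 100L) stop("need at least 100 latent samples, got ", nrow(X))
  cfg <- utils::modifyList(
    list(hidden = 48L, n_steps = 40L, n_iter = 400L, batch_size = 256L,
         lr = 0.01, seed = 1L), config)
  set.seed(cfg$seed)
  d <- ncol(X)
  model <- density_model(d, cfg$hidden, cfg$n_steps)
  pp <- model$pp
  opt <- adam_init(pp, lr = cfg$lr)
  n <- nrow(X)
  losses <- numeric(cfg$n_iter)
  for (it in seq_len(cfg$n_iter)) {
    idx <- sample.int(n, min(cfg$batch_size, n))
    tp <- ad_tape()
    ops <- model_ops(tp)
    pl <- par_leaf(tp, pp)
    ld <- cnf_logdens_graph(ops, pl, ad_const(tp, X[idx, , drop = FALSE]),
                            d, cfg$n_steps)
    loss <- ad_scale(tp, ad_sum(tp, ld), -1 / length(idx))
    if (!is.finite(ad_value(tp, loss)[1L])) {
      stop("density fit diverged: non-finite loss at iteration ", it)
    }
    ad_backward(tp, loss)
    pp <- adam_step(opt, pp, par_grads(tp, pl))
    losses[it] <- ad_value(tp, loss)[1L]
  }
  model$pp <- pp
  model$fitted <- TRUE
  model$loss <- losses
  model
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model> d=%d hidden=%d rk4_steps=%d %s\n",
              x$d, x$hidden, x$n_steps,
              if (x$fitted) "(fitted)" else "(identity init)"))
  invisible(x)
}

#' Normal region of a fitted density
#'
#' Thresholds the density so that the requested probability mass of the
#' model's own samples falls inside: the threshold is the empirical
#' (1 - mass) quantile of the density at fresh model samples. Membership is
#' \code{p(z) >= c}; raising the threshold never adds members.
#'
#' @param model a fitted \code{\link{density_model}}.
#' @param mass coverage probability in (0, 1), e.g. 0.95.
#' @param n_samples model samples used to calibrate the threshold.
#' @param seed integer seed for the calibration draws.
#' @return Object of class \code{normal_region} with the density threshold
#'   \code{c} and the model.
#' @export
normal_region <- function(model, mass, n_samples = 4000L, seed = 1L) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("mass must be a single probability in (0, 1)")
  }
  set.seed(seed)
  S <- sample_density(model, n_samples)
  dens <- sort(exp(log_density(model, S)))
  # order statistic such that a fraction `mass` of the model's own samples
  # sits at or above the threshold; as mass -> 1 this is the least dense
  # sample
  k <- max(1L, min(n_samples, floor((1 - mass) * n_samples) + 1L))
  structure(list(c = dens[k], mass = mass, model = model),
            class = "normal_region")
}

#' Region membership
#'
#' @param region a \code{\link{normal_region}}.
#' @param z d-vector or n x d matrix.
#' @return Logical vector: density at z at least the region threshold.
#' @export
contains <- function(region, z) {
  stopifnot(inherits(region, "normal_region"))
  exp(log_density(region$model, z)) >= region$c
}

#' @export
print.normal_region <- function(x, ...) {
  cat(sprintf("<normal_region> mass=%.3f threshold=%.4g\n", x$mass, x$c))
  invisible(x)
}

#' Evaluate the density on a regular grid
#'
#' Convenience for contour plots of 2-D latent densities.
#'
#' @param model a \code{\link{density_model}} with d = 2.
#' @param lim half-width of the square grid.
#' @param n grid points per axis.
#' @return Data frame with columns \code{z1}, \code{z2}, \code{log_density}.
#' @export
density_grid <- function(model, lim = 4, n = 100L) {
  stopifnot(model$d == 2L)
  g <- seq(-lim, lim, length.out = n)
  pts <- as.matrix(expand.grid(z1 = g, z2 = g))
  data.frame(z1 = pts[, 1L], z2 = pts[, 2L],
             log_density = log_density(model, pts))
}
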