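# Network layers on top of the ad tape.
#
# Forward passes are written once against an "ops" interpreter. ops_num()
# executes them directly on matrices (inference); ops_tape(tp) records them on
# a tape (training). This guarantees the filtering/inference path computes
# exactly the function that was trained.

num_lse_rows <- function(A) {
  m <- apply(A, 1L, max)
  matrix(m + log(rowSums(exp(A - m))), ncol = 1L)
}

#' Forward-pass interpreters
#'
#' \code{ops_num} evaluates network forwards on plain matrices;
#' \code{ops_tape} records the same operations on an autodiff tape.
#'
#' @param tp tape from \code{\link{ad_tape}}.
#' @return A list of primitive operations consumed by the layer forwards.
#' @keywords internal
#' @export
ops_num <- function() {
  list(
    tape = FALSE,
    const = as_mat,
    value = identity,
    mm = function(a, b) a %*% b,
    add = `+`,
    sub = `-`,
    addb = function(a, b) a + matrix(b, nrow(a), ncol(a), byrow = TRUE),
    mul = `*`,
    div = `/`,
    scale = function(a, s) a * s,
    addc = function(a, s) a + s,
    tanh = tanh,
    sigmoid = stats::plogis,
    softplus = softplus,
    exp = exp,
    log = log,
    sqrt = sqrt,
    square = function(a) a * a,
    sum = function(a) matrix(sum(a), 1L, 1L),
    rowsum = function(a) matrix(rowSums(a), ncol = 1L),
    cbind = function(...) cbind(...),
    cols = function(a, idx) a[, idx, drop = FALSE],
    rows = function(a, idx) a[idx, , drop = FALSE],
    rbind = function(...) rbind(...),
    lse_rows = num_lse_rows,
    t = t,
    colsum = function(a) matrix(colSums(a), 1L),
    neg = function(a) -a
  )
}

#' @rdname ops_num
#' @export
ops_tape <- function(tp) {
  list(
    tape = TRUE,
    const = function(x) ad_const(tp, x),
    value = function(id) ad_value(tp, id),
    mm = function(a, b) ad_mm(tp, a, b),
    add = function(a, b) ad_add(tp, a, b),
    sub = function(a, b) ad_sub(tp, a, b),
    addb = function(a, b) ad_addb(tp, a, b),
    mul = function(a, b) ad_mul(tp, a, b),
    div = function(a, b) ad_div(tp, a, b),
    scale = function(a, s) ad_scale(tp, a, s),
    addc = function(a, s) ad_addc(tp, a, s),
    tanh = function(a) ad_tanh(tp, a),
    sigmoid = function(a) ad_sigmoid(tp, a),
    softplus = function(a) ad_softplus(tp, a),
    exp = function(a) ad_exp(tp, a),
    log = function(a) ad_log(tp, a),
    sqrt = function(a) ad_sqrt(tp, a),
    square = function(a) ad_square(tp, a),
    sum = function(a) ad_sum(tp, a),
    rowsum = function(a) ad_rowsum(tp, a),
    cbind = function(...) ad_cbind(tp, ...),
    cols = function(a, idx) ad_cols(tp, a, idx),
    rows = function(a, idx) ad_rows(tp, a, idx),
    rbind = function(...) ad_rbind(tp, ...),
    lse_rows = function(a) ad_lse_rows(tp, a),
    t = function(a) ad_t(tp, a),
    colsum = function(a) ad_colsum(tp, a),
    neg = function(a) ad_neg(tp, a)
  )
}

# --- parameter containers ---------------------------------------------------

# Walk a nested parameter list, applying f to every numeric matrix and
# leaving other fields (activation names etc.) untouched.
par_map <- function(p, f) {
  if (is.list(p)) lapply(p, par_map, f = f)
  else if (is.numeric(p)) f(p)
  else p
}

# n-ary zip over parallel nested parameter lists
par_zip <- function(f, ...) {
  ps <- list(...)
  if (is.list(ps[[1L]])) {
    out <- vector("list", length(ps[[1L]]))
    names(out) <- names(ps[[1L]])
    for (i in seq_along(ps[[1L]])) {
      out[[i]] <- do.call(par_zip, c(list(f), lapply(ps, `[[`, i)))
    }
    out
  } else if (is.numeric(ps[[1L]])) {
    do.call(f, ps)
  } else {
    ps[[1L]]
  }
}

# Register every matrix in a parameter list as a tape leaf; returns the same
# structure with node handles in place of matrices.
par_leaf <- function(tp, p) par_map(p, function(x) ad_leaf(tp, as_mat(x)))

# Collect gradients for a leafed parameter structure after ad_backward().
par_grads <- function(tp, ids) par_map(ids, function(id) ad_grad(tp, id))

par_count <- function(p) {
  n <- 0L
  par_map(p, function(x) { n <<- n + length(x); x })
  n
}

glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

# --- multilayer perceptron --------------------------------------------------

#' Multilayer perceptron parameters and forward pass
#'
#' \code{mlp_init} draws Glorot-normal weights (uses the current RNG state;
#' seed with \code{set.seed} for reproducibility). \code{hidden} may be
#' \code{integer(0)} for a purely linear map. \code{mlp_fwd} applies the
#' network under either interpreter; hidden layers use tanh.
#'
#' @param d_in,d_out input and output widths.
#' @param hidden integer vector of hidden-layer widths.
#' @param out_bias optional numeric vector initialising the output bias.
#' @param ops interpreter from \code{\link{ops_num}} or \code{\link{ops_tape}}.
#' @param pp parameter list (or its tape-leafed counterpart).
#' @param X input node/matrix, rows are cases.
#' @keywords internal
#' @export
mlp_init <- function(d_in, hidden, d_out, out_bias = NULL) {
  dims <- c(d_in, hidden, d_out)
  L <- length(dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  names(W) <- paste0("W", seq_len(L))
  names(b) <- paste0("b", seq_len(L))
  for (l in seq_len(L)) {
    W[[l]] <- glorot(dims[l], dims[l + 1L])
    b[[l]] <- matrix(0, 1L, dims[l + 1L])
  }
  if (!is.null(out_bias)) b[[L]] <- matrix(out_bias, 1L, d_out)
  list(W = W, b = b)
}

#' @rdname mlp_init
#' @export
mlp_fwd <- function(ops, pp, X) {
  L <- length(pp$W)
  h <- X
  for (l in seq_len(L)) {
    h <- ops$addb(ops$mm(h, pp$W[[l]]), pp$b[[l]])
    if (l < L) h <- ops$tanh(h)
  }
  h
}

# --- gated recurrent unit ---------------------------------------------------

#' Gated recurrent unit cell
#'
#' Standard GRU with reset gate r, update gate u and candidate state c:
#' \code{h' = (1-u)*h + u*c}. Used by the encoder running backwards in time.
#'
#' @param d_in,d_h input and hidden widths.
#' @param ops interpreter.
#' @param pp parameter list from \code{gru_init} (or tape-leafed).
#' @param x input node/matrix (rows are cases).
#' @param h previous hidden state node/matrix.
#' @keywords internal
#' @export
gru_init <- function(d_in, d_h) {
  list(
    Wr = glorot(d_in, d_h), Ur = glorot(d_h, d_h), br = matrix(0, 1L, d_h),
    Wu = glorot(d_in, d_h), Uu = glorot(d_h, d_h), bu = matrix(0, 1L, d_h),
    Wc = glorot(d_in, d_h), Uc = glorot(d_h, d_h), bc = matrix(0, 1L, d_h)
  )
}

#' @rdname gru_init
#' @export
gru_cell <- function(ops, pp, x, h) {
  r <- ops$sigmoid(ops$addb(ops$add(ops$mm(x, pp$Wr), ops$mm(h, pp$Ur)), pp$br))
  u <- ops$sigmoid(ops$addb(ops$add(ops$mm(x, pp$Wu), ops$mm(h, pp$Uu)), pp$bu))
  c_ <- ops$tanh(ops$addb(ops$add(ops$mm(x, pp$Wc),
                                  ops$mm(ops$mul(r, h), pp$Uc)), pp$bc))
  one_minus_u <- ops$addc(ops$neg(u), 1)
  ops$add(ops$mul(one_minus_u, h), ops$mul(u, c_))
}

# --- Adam optimiser ---------------------------------------------------------

#' Adam optimiser over nested parameter lists
#'
#' @param p nested parameter list (matrices at the leaves).
#' @param lr learning rate.
#' @param beta1,beta2,eps standard Adam moment/stability constants.
#' @return \code{adam_init}: an environment holding optimiser state;
#'   \code{adam_step}: the updated parameter list.
#' @keywords internal
#' @export
adam_init <- function(p, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- par_map(p, function(x) array(0, dim(as_mat(x))))
  st$v <- par_map(p, function(x) array(0, dim(as_mat(x))))
  st
}

#' @rdname adam_init
#' @param st optimiser state.
#' @param g gradient structure parallel to \code{p}.
#' @export
adam_step <- function(st, p, g) {
  st$t <- st$t + 1L
  st$m <- par_zip(function(m, gi) st$b1 * m + (1 - st$b1) * gi, st$m, g)
  st$v <- par_zip(function(v, gi) st$b2 * v + (1 - st$b2) * gi * gi, st$v, g)
  c1 <- 1 / (1 - st$b1^st$t)
  c2 <- 1 / (1 - st$b2^st$t)
  par_zip(function(x, m, v) x - st$lr * (m * c1) / (sqrt(v * c2) + st$eps),
          p, st$m, st$v)
}
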