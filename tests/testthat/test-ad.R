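# The reverse-mode tape must agree with central finite differences on a
# graph that exercises every primitive the model forwards use.

test_that("tape gradients match central differences across all primitives", {
  composite_loss <- function(W1, W2, b, ops = ldmf:::model_ops(), tp = NULL) {
    lf <- function(x) if (is.null(tp)) x else ad_leaf(tp, x)
    cf <- function(x) if (is.null(tp)) x else ad_const(tp, x)
    w1 <- lf(W1); w2 <- lf(W2); bb <- lf(b)
    X <- cf(matrix(seq(-1, 1, length.out = 12), 4, 3))
    h <- ops$tanh(ops$addb(ops$mm(X, w1), bb))
    h <- ops$sigmoid(h)
    h2 <- ops$softplus(ops$mm(h, w2))
    s <- ops$cbind(ops$square(h2), ops$sqrt(ops$addc(h2, 2)))
    s <- ops$cols(s, c(1L, 3L))
    s <- ops$rows(ops$rbind(s, ops$scale(s, 0.5)), c(1L, 3L, 5L))
    r <- ops$mul(s, ops$exp(ops$scale(s, 0.1)))
    r <- ops$div(r, ops$addc(ops$square(s), 1))
    l1 <- ops$lse_rows(r)
    l2 <- ops$rowsum(ops$log(ops$addc(ops$square(r), 1)))
    l3 <- ops$subcol(r, l1)
    l4 <- ops$mulcol(l3, l2)
    tt <- ops$colsum(ops$t(ops$add(l4, ops$sub(r, l3))))
    ops$sum(tt)
  }
  set.seed(7)
  for (rep in 1:3) {
    W1 <- matrix(rnorm(6, sd = 0.5), 3, 2)
    W2 <- matrix(rnorm(4, sd = 0.5), 2, 2)
    b <- matrix(rnorm(2, sd = 0.2), 1, 2)
    tp <- ad_tape()
    ops <- ldmf:::model_ops(tp)
    ids <- list(W1 = NULL, W2 = NULL, b = NULL)
    # run with leaves
    w1 <- ad_leaf(tp, W1); w2 <- ad_leaf(tp, W2); bb <- ad_leaf(tp, b)
    loss <- local({
      X <- ad_const(tp, matrix(seq(-1, 1, length.out = 12), 4, 3))
      h <- ops$tanh(ops$addb(ops$mm(X, w1), bb))
      h <- ops$sigmoid(h)
      h2 <- ops$softplus(ops$mm(h, w2))
      s <- ops$cbind(ops$square(h2), ops$sqrt(ops$addc(h2, 2)))
      s <- ops$cols(s, c(1L, 3L))
      s <- ops$rows(ops$rbind(s, ops$scale(s, 0.5)), c(1L, 3L, 5L))
      r <- ops$mul(s, ops$exp(ops$scale(s, 0.1)))
      r <- ops$div(r, ops$addc(ops$square(s), 1))
      l1 <- ops$lse_rows(r)
      l2 <- ops$rowsum(ops$log(ops$addc(ops$square(r), 1)))
      l3 <- ops$subcol(r, l1)
      l4 <- ops$mulcol(l3, l2)
      tt <- ops$colsum(ops$t(ops$add(l4, ops$sub(r, l3))))
      ops$sum(tt)
    })
    ad_backward(tp, loss)
    num_loss <- function(W1, W2, b) {
      as.numeric(composite_loss(W1, W2, b))
    }
    h <- 1e-5
    for (nm in c("W1", "W2", "b")) {
      M <- get(nm)
      gid <- switch(nm, W1 = w1, W2 = w2, b = bb)
      G <- ad_grad(tp, gid)
      for (i in seq_along(M)) {
        Mp <- M; Mp[i] <- Mp[i] + h
        Mm <- M; Mm[i] <- Mm[i] - h
        args_p <- list(W1 = W1, W2 = W2, b = b); args_p[[nm]] <- Mp
        args_m <- list(W1 = W1, W2 = W2, b = b); args_m[[nm]] <- Mm
        num <- (do.call(num_loss, args_p) - do.call(num_loss, args_m)) / (2 * h)
        expect_close(G[i], num, tol = 1e-5)
      }
    }
  }
})

test_that("numeric and tape interpreters produce identical forward values", {
  set.seed(21)
  pp <- mlp_init(4, c(6, 5), 3)
  X <- matrix(rnorm(20), 5, 4)
  plain <- mlp_fwd(ldmf:::model_ops(), pp, X)
  tp <- ad_tape()
  taped <- ad_value(tp, mlp_fwd(ldmf:::model_ops(tp), ldmf:::par_leaf(tp, pp),
                                ad_const(tp, X)))
  expect_identical(plain, taped)
})

test_that("gru cell matches a hand-rolled recurrence and adam descends", {
  set.seed(3)
  pp <- gru_init(3, 4)
  x <- matrix(rnorm(6), 2, 3)
  h0 <- matrix(0, 2, 4)
  out <- gru_cell(ldmf:::model_ops(), pp, x, h0)
  sig <- stats::plogis
  r <- sig(x %*% pp$Wr + h0 %*% pp$Ur + matrix(pp$br, 2, 4, byrow = TRUE))
  u <- sig(x %*% pp$Wu + h0 %*% pp$Uu + matrix(pp$bu, 2, 4, byrow = TRUE))
  cc <- tanh(x %*% pp$Wc + (r * h0) %*% pp$Uc + matrix(pp$bc, 2, 4, byrow = TRUE))
  expect_close(out, (1 - u) * h0 + u * cc, tol = 1e-12)

  # adam: quadratic loss decreases
  p <- list(w = matrix(c(5, -3), 1, 2))
  opt <- adam_init(p, lr = 0.1)
  for (i in 1:200) p <- adam_step(opt, p, list(w = 2 * p$w))
  expect_lt(sum(p$w^2), 1e-2)
})
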