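# Reverse-mode automatic differentiation on dense matrices.
#
# A tape records every intermediate value during a forward pass; nodes are
# integer handles into the tape. Node records live in a hashed environment
# (R lists suffer copy-on-write at every push), each holding the value, a
# needs-gradient flag, and the backward closure. ad_backward() replays the
# tape in reverse, accumulating gradients only for nodes that transitively
# depend on a parameter leaf. All values are numeric matrices; scalars are
# 1x1.

#' Create an empty autodiff tape
#'
#' The tape is the record of one forward computation. Create a fresh tape per
#' training step.
#'
#' @return An environment holding the node records.
#' @keywords internal
#' @export
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$nodes <- new.env(hash = TRUE, size = 8192L, parent = emptyenv())
  tp
}

# record: list(value, need, bp)
ad_push <- function(tp, value, need, bp = NULL) {
  n <- tp$n + 1L
  assign(as.character(n), list(value, need, bp), envir = tp$nodes)
  tp$n <- n
  n
}

ad_node <- function(tp, id) get(as.character(id), envir = tp$nodes)

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Tape leaves
#'
#' \code{ad_leaf} registers a differentiable input (a parameter);
#' \code{ad_const} registers data that requires no gradient.
#'
#' @param tp tape from \code{\link{ad_tape}}.
#' @param x numeric matrix or vector (vectors become 1-row matrices).
#' @return Integer node handle.
#' @keywords internal
#' @export
ad_leaf <- function(tp, x) ad_push(tp, as_mat(x), TRUE)

#' @rdname ad_leaf
#' @export
ad_const <- function(tp, x) ad_push(tp, as_mat(x), FALSE)

#' @rdname ad_leaf
#' @param id node handle.
#' @export
ad_value <- function(tp, id) ad_node(tp, id)[[1L]]

ad_acc <- function(tp, id, g) {
  if (!ad_node(tp, id)[[2L]]) return(invisible(NULL))
  key <- as.character(id)
  cur <- get0(key, envir = tp$g)
  assign(key, if (is.null(cur)) g else cur + g, envir = tp$g)
  invisible(NULL)
}

#' Run the backward pass
#'
#' Seeds the gradient of \code{loss} (which must be 1x1) with 1 and sweeps
#' the tape in reverse. Gradients are then available via \code{\link{ad_grad}}.
#'
#' @param tp tape.
#' @param loss node handle of a scalar node.
#' @keywords internal
#' @export
ad_backward <- function(tp, loss) {
  stopifnot(length(ad_value(tp, loss)) == 1L)
  tp$g <- new.env(hash = TRUE, size = 8192L, parent = emptyenv())
  assign(as.character(loss), matrix(1, 1L, 1L), envir = tp$g)
  for (i in seq.int(loss, 1L)) {
    key <- as.character(i)
    rec <- get(key, envir = tp$nodes)
    bp <- rec[[3L]]
    if (!is.null(bp)) {
      g <- get0(key, envir = tp$g)
      if (!is.null(g)) bp(g)
    }
  }
  invisible(NULL)
}

#' @rdname ad_backward
#' @param id node handle.
#' @return Gradient matrix (zeros if the node never received gradient).
#' @export
ad_grad <- function(tp, id) {
  g <- get0(as.character(id), envir = tp$g)
  if (is.null(g)) array(0, dim(ad_value(tp, id))) else g
}

# --- primitive operations ---------------------------------------------------

#' Tape operations
#'
#' Matrix primitives recorded on the tape: matrix product, elementwise
#' arithmetic, broadcast bias addition, nonlinearities, reductions, column
#' binding/slicing, transpose and row-wise log-sum-exp. Each returns a new
#' node handle.
#'
#' @param tp tape.
#' @param a,b node handles.
#' @name ad-ops
#' @keywords internal
NULL

#' @rdname ad-ops
#' @export
ad_mm <- function(tp, a, b) {
  na <- ad_node(tp, a); nb <- ad_node(tp, b)
  A <- na[[1L]]; B <- nb[[1L]]
  need <- na[[2L]] || nb[[2L]]
  ad_push(tp, A %*% B, need, if (need) function(g) {
    ad_acc(tp, a, g %*% t(B))
    ad_acc(tp, b, crossprod(A, g))
  })
}

#' @rdname ad-ops
#' @export
ad_add <- function(tp, a, b) {
  na <- ad_node(tp, a); nb <- ad_node(tp, b)
  need <- na[[2L]] || nb[[2L]]
  ad_push(tp, na[[1L]] + nb[[1L]], need, if (need) function(g) {
    ad_acc(tp, a, g); ad_acc(tp, b, g)
  })
}

#' @rdname ad-ops
#' @export
ad_sub <- function(tp, a, b) {
  na <- ad_node(tp, a); nb <- ad_node(tp, b)
  need <- na[[2L]] || nb[[2L]]
  ad_push(tp, na[[1L]] - nb[[1L]], need, if (need) function(g) {
    ad_acc(tp, a, g); ad_acc(tp, b, -g)
  })
}

# bias is a 1 x k row vector broadcast over the rows of a
#' @rdname ad-ops
#' @export
ad_addb <- function(tp, a, b) {
  na <- ad_node(tp, a); nb <- ad_node(tp, b)
  A <- na[[1L]]; bv <- nb[[1L]]
  need <- na[[2L]] || nb[[2L]]
  ad_push(tp, A + matrix(bv, nrow(A), ncol(A), byrow = TRUE), need,
          if (need) function(g) {
            ad_acc(tp, a, g)
            ad_acc(tp, b, matrix(colSums(g), 1L))
          })
}

#' @rdname ad-ops
#' @export
ad_mul <- function(tp, a, b) {
  na <- ad_node(tp, a); nb <- ad_node(tp, b)
  A <- na[[1L]]; B <- nb[[1L]]
  need <- na[[2L]] || nb[[2L]]
  ad_push(tp, A * B, need, if (need) function(g) {
    ad_acc(tp, a, g * B); ad_acc(tp, b, g * A)
  })
}

#' @rdname ad-ops
#' @export
ad_div <- function(tp, a, b) {
  na <- ad_node(tp, a); nb <- ad_node(tp, b)
  A <- na[[1L]]; B <- nb[[1L]]
  need <- na[[2L]] || nb[[2L]]
  ad_push(tp, A / B, need, if (need) function(g) {
    ad_acc(tp, a, g / B); ad_acc(tp, b, -g * A / (B * B))
  })
}

#' @rdname ad-ops
#' @param s numeric scalar.
#' @export
ad_scale <- function(tp, a, s) {
  na <- ad_node(tp, a)
  need <- na[[2L]]
  ad_push(tp, na[[1L]] * s, need,
          if (need) function(g) ad_acc(tp, a, g * s))
}

#' @rdname ad-ops
#' @export
ad_addc <- function(tp, a, s) {
  na <- ad_node(tp, a)
  need <- na[[2L]]
  ad_push(tp, na[[1L]] + s, need, if (need) function(g) ad_acc(tp, a, g))
}

#' @rdname ad-ops
#' @export
ad_tanh <- function(tp, a) {
  na <- ad_node(tp, a)
  V <- tanh(na[[1L]])
  need <- na[[2L]]
  ad_push(tp, V, need, if (need) function(g) ad_acc(tp, a, g * (1 - V * V)))
}

#' @rdname ad-ops
#' @export
ad_sigmoid <- function(tp, a) {
  na <- ad_node(tp, a)
  V <- stats::plogis(na[[1L]])
  need <- na[[2L]]
  ad_push(tp, V, need, if (need) function(g) ad_acc(tp, a, g * V * (1 - V)))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

#' @rdname ad-ops
#' @export
ad_softplus <- function(tp, a) {
  na <- ad_node(tp, a)
  A <- na[[1L]]
  need <- na[[2L]]
  ad_push(tp, softplus(A), need, if (need) function(g) {
    ad_acc(tp, a, g * stats::plogis(A))
  })
}

#' @rdname ad-ops
#' @export
ad_exp <- function(tp, a) {
  na <- ad_node(tp, a)
  V <- exp(na[[1L]])
  need <- na[[2L]]
  ad_push(tp, V, need, if (need) function(g) ad_acc(tp, a, g * V))
}

#' @rdname ad-ops
#' @export
ad_log <- function(tp, a) {
  na <- ad_node(tp, a)
  A <- na[[1L]]
  need <- na[[2L]]
  ad_push(tp, log(A), need, if (need) function(g) ad_acc(tp, a, g / A))
}

#' @rdname ad-ops
#' @export
ad_sqrt <- function(tp, a) {
  na <- ad_node(tp, a)
  V <- sqrt(na[[1L]])
  need <- na[[2L]]
  ad_push(tp, V, need, if (need) function(g) ad_acc(tp, a, g * 0.5 / V))
}

#' @rdname ad-ops
#' @export
ad_square <- function(tp, a) {
  na <- ad_node(tp, a)
  A <- na[[1L]]
  need <- na[[2L]]
  ad_push(tp, A * A, need, if (need) function(g) ad_acc(tp, a, 2 * g * A))
}

#' @rdname ad-ops
#' @export
ad_sum <- function(tp, a) {
  na <- ad_node(tp, a)
  A <- na[[1L]]
  need <- na[[2L]]
  ad_push(tp, matrix(sum(A), 1L, 1L), need, if (need) function(g) {
    ad_acc(tp, a, array(g[1L], dim(A)))
  })
}

#' @rdname ad-ops
#' @export
ad_rowsum <- function(tp, a) {
  na <- ad_node(tp, a)
  A <- na[[1L]]
  need <- na[[2L]]
  ad_push(tp, matrix(rowSums(A), ncol = 1L), need, if (need) function(g) {
    ad_acc(tp, a, matrix(g, nrow(A), ncol(A)))
  })
}

#' @rdname ad-ops
#' @param ... node handles to bind column-wise.
#' @export
ad_cbind <- function(tp, ...) {
  ids <- c(...)
  recs <- lapply(ids, ad_node, tp = tp)
  vals <- lapply(recs, `[[`, 1L)
  widths <- vapply(vals, ncol, 1L)
  need <- any(vapply(recs, `[[`, TRUE, 2L))
  ad_push(tp, do.call(cbind, vals), need, if (need) function(g) {
    at <- 0L
    for (j in seq_along(ids)) {
      ad_acc(tp, ids[j], g[, at + seq_len(widths[j]), drop = FALSE])
      at <- at + widths[j]
    }
  })
}

#' @rdname ad-ops
#' @param idx integer column indices.
#' @export
ad_cols <- function(tp, a, idx) {
  na <- ad_node(tp, a)
  A <- na[[1L]]
  need <- na[[2L]]
  ad_push(tp, A[, idx, drop = FALSE], need, if (need) function(g) {
    G <- array(0, dim(A))
    G[, idx] <- G[, idx] + g
    ad_acc(tp, a, G)
  })
}

# row-wise log-sum-exp over columns -> n x 1
#' @rdname ad-ops
#' @export
ad_lse_rows <- function(tp, a) {
  na <- ad_node(tp, a)
  A <- na[[1L]]
  m <- apply(A, 1L, max)
  E <- exp(A - m)
  s <- rowSums(E)
  need <- na[[2L]]
  ad_push(tp, matrix(m + log(s), ncol = 1L), need, if (need) function(g) {
    ad_acc(tp, a, (E / s) * matrix(g, nrow(A), ncol(A)))
  })
}

#' @rdname ad-ops
#' @export
ad_t <- function(tp, a) {
  na <- ad_node(tp, a)
  need <- na[[2L]]
  ad_push(tp, t(na[[1L]]), need, if (need) function(g) ad_acc(tp, a, t(g)))
}

#' @rdname ad-ops
#' @export
ad_colsum <- function(tp, a) {
  na <- ad_node(tp, a)
  A <- na[[1L]]
  need <- na[[2L]]
  ad_push(tp, matrix(colSums(A), 1L), need, if (need) function(g) {
    ad_acc(tp, a, matrix(g, nrow(A), ncol(A), byrow = TRUE))
  })
}

#' @rdname ad-ops
#' @export
ad_rbind <- function(tp, ...) {
  ids <- c(...)
  recs <- lapply(ids, ad_node, tp = tp)
  vals <- lapply(recs, `[[`, 1L)
  heights <- vapply(vals, nrow, 1L)
  need <- any(vapply(recs, `[[`, TRUE, 2L))
  ad_push(tp, do.call(rbind, vals), need, if (need) function(g) {
    at <- 0L
    for (j in seq_along(ids)) {
      ad_acc(tp, ids[j], g[at + seq_len(heights[j]), , drop = FALSE])
      at <- at + heights[j]
    }
  })
}

#' @rdname ad-ops
#' @export
ad_rows <- function(tp, a, idx) {
  na <- ad_node(tp, a)
  A <- na[[1L]]
  need <- na[[2L]]
  ad_push(tp, A[idx, , drop = FALSE], need, if (need) function(g) {
    G <- array(0, dim(A))
    G[idx, ] <- G[idx, ] + g
    ad_acc(tp, a, G)
  })
}

#' @rdname ad-ops
#' @export
ad_neg <- function(tp, a) ad_scale(tp, a, -1)

#' @rdname ad-ops
#' @export
ad_mean <- function(tp, a) ad_scale(tp, ad_sum(tp, a), 1 / length(ad_value(tp, a)))
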