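#' @title Reverse-mode automatic differentiation
#'
#' @description
#' A small tape-based autodiff engine over dense R arrays, sufficient to
#' train the attention backbone and detection head on CPU. Values are plain
#' numeric arrays; each operation records a node on a global tape with a
#' backward closure. `ad_backward()` seeds the output gradient and replays
#' the tape in reverse. Only what the models need is implemented: matrix and
#' batched matrix products, elementwise arithmetic and activations, softmax
#' and layer normalisation with fused gradients, row gathers with
#' scatter-add (which express padding, cyclic shifts, window partitioning,
#' up-sampling and im2col convolution lowering), concatenation, and
#' reductions.
#'
#' Gradient correctness is established by finite-difference checks in the
#' test suite rather than by construction.
#'
#' @name autodiff
NULL

.sf_tape <- new.env(parent = emptyenv())
.sf_tape$nodes <- list()
.sf_tape$n <- 0L

#' Reset the autodiff tape
#'
#' Discards all recorded nodes. Call between training iterations; parameter
#' arrays live outside the tape and are re-wrapped as leaves each forward
#' pass.
#' @export
ad_reset <- function() {
  .sf_tape$nodes <- list()
  .sf_tape$n <- 0L
  invisible(NULL)
}

new_node <- function(value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  .sf_tape$n <- .sf_tape$n + 1L
  n$id <- .sf_tape$n
  .sf_tape$nodes[[n$id]] <- n
  class(n) <- "ad_node"
  n
}

#' Create a leaf node
#'
#' @param value numeric array/matrix/vector.
#' @return an `ad_node` whose `$grad` is populated after [ad_backward()].
#' @export
ad_leaf <- function(value) new_node(value)

#' @export
print.ad_node <- function(x, ...) {
  d <- dim(x$value)
  cat("<ad_node id=", x$id, " dim=", paste(if (is.null(d)) length(x$value) else d,
                                           collapse = "x"), ">\n", sep = "")
  invisible(x)
}

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar node
#'
#' @param node the loss node (length-1 value).
#' @export
ad_backward <- function(node) {
  stopifnot(length(node$value) == 1L)
  node$grad <- 1
  for (i in seq(node$id, 1L)) {
    nd <- .sf_tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
  }
  invisible(NULL)
}

val <- function(x) if (inherits(x, "ad_node")) x$value else x

# ---- arithmetic -------------------------------------------------------------

#' Elementwise and linear-algebra operations on tape nodes
#'
#' These mirror the obvious array operations; see the package vignette for
#' the catalogue. All take and return `ad_node`s.
#'
#' @param a,b input nodes (or plain arrays for the constant argument of the
#'   few ops that allow one).
#' @name ad_ops
NULL

#' @rdname ad_ops
#' @export
ad_add <- function(a, b) {
  new_node(a$value + b$value, list(a, b), function(n) {
    acc_grad(n$parents[[1L]], n$grad)
    acc_grad(n$parents[[2L]], n$grad)
  })
}

#' @rdname ad_ops
#' @export
ad_sub <- function(a, b) {
  new_node(a$value - b$value, list(a, b), function(n) {
    acc_grad(n$parents[[1L]], n$grad)
    acc_grad(n$parents[[2L]], -n$grad)
  })
}

#' @rdname ad_ops
#' @export
ad_mul <- function(a, b) {
  new_node(a$value * b$value, list(a, b), function(n) {
    acc_grad(n$parents[[1L]], n$grad * n$parents[[2L]]$value)
    acc_grad(n$parents[[2L]], n$grad * n$parents[[1L]]$value)
  })
}

#' @rdname ad_ops
#' @export
ad_div <- function(a, b) {
  new_node(a$value / b$value, list(a, b), function(n) {
    acc_grad(n$parents[[1L]], n$grad / n$parents[[2L]]$value)
    acc_grad(n$parents[[2L]],
             -n$grad * n$parents[[1L]]$value / n$parents[[2L]]$value^2)
  })
}

#' @rdname ad_ops
#' @param k a plain numeric constant.
#' @export
ad_scale <- function(a, k) {
  new_node(a$value * k, list(a), function(n) acc_grad(n$parents[[1L]], n$grad * k))
}

#' Multiply an array node by a scalar node
#'
#' @param a array node.
#' @param s length-1 node (e.g. a learnable per-level scale).
#' @export
ad_mul_snode <- function(a, s) {
  new_node(a$value * as.numeric(s$value), list(a, s), function(n) {
    acc_grad(n$parents[[1L]], n$grad * as.numeric(n$parents[[2L]]$value))
    acc_grad(n$parents[[2L]], sum(n$grad * n$parents[[1L]]$value))
  })
}

#' @rdname ad_ops
#' @export
ad_add_const <- function(a, k) {
  new_node(a$value + k, list(a), function(n) acc_grad(n$parents[[1L]], n$grad))
}

#' Add a bias vector along the last dimension
#'
#' `a` is a matrix (n x C) or 3-D array (..., C); `bias` a length-C node.
#' @param a,bias nodes.
#' @export
ad_add_bias <- function(a, bias) {
  av <- a$value
  C <- length(bias$value)
  v <- av + rep(bias$value, each = length(av) / C)
  new_node(v, list(a, bias), function(n) {
    acc_grad(n$parents[[1L]], n$grad)
    g <- n$grad
    acc_grad(n$parents[[2L]], colSums(matrix(g, ncol = C)))
  })
}

#' @rdname ad_ops
#' @export
ad_matmul <- function(a, b) {
  new_node(a$value %*% b$value, list(a, b), function(n) {
    acc_grad(n$parents[[1L]], n$grad %*% t(n$parents[[2L]]$value))
    acc_grad(n$parents[[2L]], crossprod(n$parents[[1L]]$value, n$grad))
  })
}

#' Batched matrix product over the first array dimension
#'
#' `a` is (B, n, m) and `b` (B, m, p) (or (B, p, m) with
#' `transpose_b = TRUE`); returns (B, n, p).
#' @param a,b 3-D array nodes.
#' @param transpose_b multiply with the per-batch transpose of `b`.
#' @export
ad_bmm <- function(a, b, transpose_b = FALSE) {
  av <- a$value; bv <- b$value
  B <- dim(av)[1L]; n <- dim(av)[2L]; m <- dim(av)[3L]
  p <- if (transpose_b) dim(bv)[2L] else dim(bv)[3L]
  out <- array(0, c(B, n, p))
  for (i in seq_len(B)) {
    A <- matrix(av[i, , ], n, m)
    Bm <- if (transpose_b) t(matrix(bv[i, , ], p, m)) else matrix(bv[i, , ], m, p)
    out[i, , ] <- A %*% Bm
  }
  new_node(out, list(a, b), function(nd) {
    g <- nd$grad
    av <- nd$parents[[1L]]$value; bv <- nd$parents[[2L]]$value
    ga <- array(0, dim(av)); gb <- array(0, dim(bv))
    for (i in seq_len(B)) {
      G <- matrix(g[i, , ], n, p)
      A <- matrix(av[i, , ], n, m)
      if (transpose_b) {
        Bm <- matrix(bv[i, , ], p, m)          # used as t(Bm)
        ga[i, , ] <- G %*% Bm
        gb[i, , ] <- crossprod(G, A)
      } else {
        Bm <- matrix(bv[i, , ], m, p)
        ga[i, , ] <- G %*% t(Bm)
        gb[i, , ] <- crossprod(A, G)
      }
    }
    acc_grad(nd$parents[[1L]], ga)
    acc_grad(nd$parents[[2L]], gb)
  })
}

# ---- shape ------------------------------------------------------------------

#' @rdname ad_ops
#' @param dims target dimensions.
#' @export
ad_reshape <- function(a, dims) {
  v <- a$value
  od <- dim(v)
  dim(v) <- dims
  new_node(v, list(a), function(n) {
    g <- n$grad
    if (is.null(od)) dim(g) <- NULL else dim(g) <- od
    acc_grad(n$parents[[1L]], g)
  })
}

#' @rdname ad_ops
#' @param perm dimension permutation, as in [aperm()].
#' @export
ad_aperm <- function(a, perm) {
  inv <- order(perm)
  new_node(aperm(a$value, perm), list(a), function(n) {
    acc_grad(n$parents[[1L]], aperm(n$grad, inv))
  })
}

#' Gather rows of a matrix, with zero-padding rows
#'
#' `idx` indexes rows of `a`; entries equal to 0 produce all-zero rows.
#' The backward pass scatter-adds gradients to the source rows. This is the
#' workhorse lowering for spatial padding, cyclic shifts, window
#' partitioning and its inverse, nearest-neighbour up-sampling and im2col.
#'
#' @param a matrix node (n x C).
#' @param idx integer vector with values in `0:n`.
#' @export
ad_gather_rows <- function(a, idx) {
  av <- a$value
  C <- ncol(av)
  out <- matrix(0, length(idx), C)
  nz <- idx > 0L
  out[nz, ] <- av[idx[nz], , drop = FALSE]
  new_node(out, list(a), function(n) {
    g <- n$grad
    src <- n$parents[[1L]]
    gs <- matrix(0, nrow(src$value), C)
    if (any(nz)) {
      agg <- rowsum(g[nz, , drop = FALSE], group = idx[nz])
      gs[as.integer(rownames(agg)), ] <- agg
    }
    acc_grad(src, gs)
  })
}

#' Concatenate matrix nodes column-wise
#'
#' @param nodes list of matrix nodes with equal row counts.
#' @export
ad_concat_cols <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  v <- do.call(cbind, lapply(nodes, function(n) n$value))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  new_node(v, nodes, function(n) {
    for (i in seq_along(n$parents)) {
      acc_grad(n$parents[[i]], n$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

#' Select columns of a matrix node
#'
#' @param a matrix node.
#' @param j integer column indices.
#' @export
ad_index_cols <- function(a, j) {
  nc <- ncol(a$value)
  new_node(a$value[, j, drop = FALSE], list(a), function(n) {
    g <- matrix(0, nrow(n$parents[[1L]]$value), nc)
    g[, j] <- g[, j] + n$grad
    acc_grad(n$parents[[1L]], g)
  })
}

# ---- activations ------------------------------------------------------------

#' @rdname ad_ops
#' @export
ad_relu <- function(a) {
  m <- a$value > 0
  new_node(a$value * m, list(a), function(n) acc_grad(n$parents[[1L]], n$grad * m))
}

#' @rdname ad_ops
#' @export
ad_gelu <- function(a) {
  x <- a$value
  cdf <- stats::pnorm(x)
  new_node(x * cdf, list(a), function(n) {
    acc_grad(n$parents[[1L]], n$grad * (cdf + x * stats::dnorm(x)))
  })
}

#' @rdname ad_ops
#' @export
ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  new_node(s, list(a), function(n) acc_grad(n$parents[[1L]], n$grad * s * (1 - s)))
}

#' @rdname ad_ops
#' @export
ad_exp <- function(a) {
  e <- exp(a$value)
  new_node(e, list(a), function(n) acc_grad(n$parents[[1L]], n$grad * e))
}

#' @rdname ad_ops
#' @param eps clamp floor for the logarithm argument.
#' @export
ad_log <- function(a, eps = 0) {
  x <- pmax(a$value, eps)
  new_node(log(x), list(a), function(n) {
    g <- n$grad / x
    if (eps > 0) g[a$value < eps] <- 0
    acc_grad(n$parents[[1L]], g)
  })
}

#' @rdname ad_ops
#' @export
ad_sqrt <- function(a) {
  s <- sqrt(a$value)
  new_node(s, list(a), function(n) acc_grad(n$parents[[1L]], n$grad / (2 * s)))
}

#' @rdname ad_ops
#' @export
ad_atan <- function(a) {
  new_node(atan(a$value), list(a), function(n) {
    acc_grad(n$parents[[1L]], n$grad / (1 + n$parents[[1L]]$value^2))
  })
}

#' @rdname ad_ops
#' @export
ad_pmax <- function(a, b) {
  m <- a$value >= b$value
  new_node(pmax(a$value, b$value), list(a, b), function(n) {
    acc_grad(n$parents[[1L]], n$grad * m)
    acc_grad(n$parents[[2L]], n$grad * !m)
  })
}

#' @rdname ad_ops
#' @export
ad_pmin <- function(a, b) {
  m <- a$value <= b$value
  new_node(pmin(a$value, b$value), list(a, b), function(n) {
    acc_grad(n$parents[[1L]], n$grad * m)
    acc_grad(n$parents[[2L]], n$grad * !m)
  })
}

#' @rdname ad_ops
#' @export
ad_clamp_min <- function(a, k) {
  m <- a$value >= k
  new_node(pmax(a$value, k), list(a), function(n) {
    acc_grad(n$parents[[1L]], n$grad * m)
  })
}

# ---- fused layers -----------------------------------------------------------

#' Softmax over the last dimension
#'
#' Accepts a matrix (n x m) or a 3-D array (B, n, m); the softmax runs over
#' the final index. Adding a constant per row leaves the output unchanged
#' (the maximum is subtracted internally).
#' @param a node.
#' @export
ad_softmax <- function(a) {
  v <- a$value
  d <- dim(v)
  m <- d[length(d)]
  x <- matrix(v, ncol = m)              # leading dims contiguous, column-major
  x <- x - x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x)
  p <- e / rowSums(e)
  pv <- array(p, d)
  new_node(pv, list(a), function(n) {
    g <- matrix(n$grad, ncol = m)
    gp <- p * (g - rowSums(g * p))
    dim(gp) <- d
    acc_grad(n$parents[[1L]], gp)
  })
}

#' Layer normalisation over the last dimension
#'
#' @param a matrix node (n x C).
#' @param gamma,beta length-C parameter nodes.
#' @param eps numerical floor inside the square root (default `1e-5`).
#' @export
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  C <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2L, gamma$value, `*`)
  out <- sweep(out, 2L, beta$value, `+`)
  new_node(out, list(a, gamma, beta), function(n) {
    g <- n$grad
    acc_grad(n$parents[[2L]], colSums(g * xhat))
    acc_grad(n$parents[[3L]], colSums(g))
    dxhat <- sweep(g, 2L, n$parents[[2L]]$value, `*`)
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    acc_grad(n$parents[[1L]], dx)
  })
}

#' Tile a per-head bias over windows
#'
#' `b` is (heads, n, n); the result is (times * heads, n, n) with batch
#' index `(w - 1) * heads + h`, matching the attention batch layout. The
#' backward pass sums gradients over the tiles.
#' @param b 3-D node.
#' @param times number of windows.
#' @export
ad_tile_batch <- function(b, times) {
  bv <- b$value
  heads <- dim(bv)[1L]; n1 <- dim(bv)[2L]; n2 <- dim(bv)[3L]
  idx <- rep(seq_len(heads), times = times)
  out <- bv[idx, , , drop = FALSE]
  new_node(out, list(b), function(nd) {
    # batch = h + heads*(w-1): reshape to (heads, times, n1*n2), sum over w
    g <- nd$grad
    dim(g) <- c(heads, times, n1 * n2)
    gb <- colSums(aperm(g, c(2L, 1L, 3L)))     # sum over the tile dimension
    dim(gb) <- c(heads, n1, n2)
    acc_grad(nd$parents[[1L]], gb)
  })
}

# ---- reductions -------------------------------------------------------------

#' @rdname ad_ops
#' @export
ad_sum <- function(a) {
  new_node(sum(a$value), list(a), function(n) {
    g <- array(n$grad, if (is.null(dim(a$value))) length(a$value) else dim(a$value))
    if (is.null(dim(a$value))) g <- as.vector(g)
    acc_grad(n$parents[[1L]], g)
  })
}

#' @rdname ad_ops
#' @export
ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$value))

#' Weighted sum with constant weights
#'
#' `sum(a * w)` for a constant weight array `w` of the same shape.
#' @param a node.
#' @param w numeric array.
#' @export
ad_dot_const <- function(a, w) {
  new_node(sum(a$value * w), list(a), function(n) {
    acc_grad(n$parents[[1L]], n$grad * w)
  })
}
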