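#' @title Hierarchical multi-window attention backbone
#'
#' @description
#' A four-stage hierarchical vision backbone. The input image is split into
#' 4x4 patches (48 values per patch token), linearly embedded to `C`
#' channels, and processed by pairs of transformer blocks in which windowed
#' multi-head self-attention runs in three parallel branches with window
#' sizes 7, 9 and 11; the branch outputs (each full-channel) are
#' concatenated and projected back to `C`. The second block of every pair
#' cyclically shifts the token grid by half a window in each branch before
#' windowing (shifted multi-window attention), with an additive mask
#' preventing attention across tokens that were not neighbours before the
#' shift. Patch-merging layers between stages halve the grid and double the
#' channels, so stage outputs have strides 4, 8, 16 and 32 with channels
#' `C_1..C_4`. Attention is `Softmax(Q K^T / sqrt(d) + B) V` with a
#' learnable relative-position bias table of size `(2X-1)^2` per head and
#' window size.
#'
#' Token maps are stored row-major: the token at grid row `r`, column `c`
#' is matrix row `(r - 1) * w + c`.
#'
#' @name mw_swin_backbone
NULL

# ---- variant configuration --------------------------------------------------

#' Architecture variant specification
#'
#' The three published-scale variants share channels `[96, 192, 384, 768]`,
#' head dimension 32, window sizes `[7, 9, 11]` and MLP expansion 4, and
#' differ only in stage depths: S `[2,2,2,2]`, B `[2,2,6,2]`, L
#' `[2,2,18,2]`. The `tiny` variant (channels `[16,32,64,128]`, head
#' dimension 8) exists for CPU-scale tests and training smoke runs.
#'
#' @param name one of `"S"`, `"B"`, `"L"`, `"tiny"`.
#' @param sr_mode spatial-reduction mode for the post-attention map:
#'   `"identity"` (default; preserves the stage-resolution contract) or
#'   `list(type = "bottleneck", r = <int>)`, which mixes `r x r` token
#'   blocks through a linear bottleneck and restores the grid by
#'   nearest-neighbour replication (resolution is always preserved).
#' @return list of class `"variant_spec"` with per-stage `channels`,
#'   `depths`, `head_dim`, `window_sizes`, `mlp_ratio`, `patch_size`.
#' @export
variant_spec <- function(name = c("B", "S", "L", "tiny"), sr_mode = "identity") {
  name <- match.arg(name)
  depths <- switch(name,
                   S = c(2L, 2L, 2L, 2L),
                   B = c(2L, 2L, 6L, 2L),
                   L = c(2L, 2L, 18L, 2L),
                   tiny = c(2L, 2L, 2L, 2L))
  channels <- if (name == "tiny") c(16L, 32L, 64L, 128L)
              else c(96L, 192L, 384L, 768L)
  head_dim <- if (name == "tiny") 8L else 32L
  stopifnot(all(channels %% head_dim == 0L), all(depths %% 2L == 0L))
  structure(list(name = name, patch_size = 4L, channels = channels,
                 depths = depths, head_dim = head_dim,
                 window_sizes = c(7L, 9L, 11L), mlp_ratio = 4L,
                 sr_mode = sr_mode),
            class = "variant_spec")
}

# truncated normal on [-2 sd, 2 sd] (transformer init convention)
trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

tn_mat <- function(nr, nc, sd = 0.02) matrix(trunc_normal(nr * nc, sd), nr, nc)

# ---- nested parameter plumbing ----------------------------------------------

# recurse over parallel nested lists, applying f at (non-list, non-NULL) leaves
nested_map <- function(f, ...) {
  args <- list(...)
  a <- args[[1L]]
  if (is.null(a)) return(NULL)
  if (is.list(a) && !inherits(a, "ad_node")) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      # out[i] <- list(...) keeps NULL results as slots instead of deleting
      out[i] <- list(do.call(nested_map, c(list(f), lapply(args, `[[`, i))))
    }
    return(out)
  }
  do.call(f, args)
}

# wrap every numeric leaf of a parameter list as an autodiff leaf node
params_to_nodes <- function(params) nested_map(ad_leaf, unclass(params))

# read values / grads back out of a node-valued parameter list
nodes_to_values <- function(np) nested_map(function(n) n$value, np)
nodes_to_grads <- function(np) {
  nested_map(function(n) if (is.null(n$grad)) n$value * 0 else n$grad, np)
}

# ---- parameter construction -------------------------------------------------

init_block_params <- function(C, spec) {
  heads <- C %/% spec$head_dim
  branches <- lapply(spec$window_sizes, function(X) {
    list(Wqkv = tn_mat(C, 3L * C), bqkv = numeric(3L * C),
         bias_table = tn_mat((2L * X - 1L)^2, heads))
  })
  sr <- NULL
  if (is.list(spec$sr_mode) && identical(spec$sr_mode$type, "bottleneck")) {
    r <- spec$sr_mode$r
    sr <- list(W = tn_mat(r * r * C, C), b = numeric(C))
  }
  list(
    ln1 = list(gamma = rep(1, C), beta = numeric(C)),
    attn = list(branches = branches,
                proj = list(W = tn_mat(length(spec$window_sizes) * C, C),
                            b = numeric(C))),
    sr = sr,
    ln2 = list(gamma = rep(1, C), beta = numeric(C)),
    mlp = list(W1 = tn_mat(C, spec$mlp_ratio * C),
               b1 = numeric(spec$mlp_ratio * C),
               W2 = tn_mat(spec$mlp_ratio * C, C), b2 = numeric(C))
  )
}

#' Instantiate backbone parameters
#'
#' All weights are drawn truncated-normal(0.02), biases zero, layer-norm
#' scales one; the draw is governed entirely by `seed`.
#'
#' @param spec a [variant_spec()].
#' @param seed integer seed.
#' @return nested parameter list (class `"backbone_params"`, with the spec
#'   attached as attribute `"spec"`).
#' @export
init_backbone <- function(spec, seed = 1L) {
  with_local_seed(seed, {
    C <- spec$channels
    params <- list(
      patch_embed = list(W = tn_mat(48L, C[1L]), b = numeric(C[1L])),
      stages = lapply(1:4, function(i) {
        st <- list(blocks = lapply(seq_len(spec$depths[i]), function(j)
          init_block_params(C[i], spec)))
        if (i < 4L) {
          st$merge <- list(ln = list(gamma = rep(1, 4L * C[i]),
                                     beta = numeric(4L * C[i])),
                           W = tn_mat(4L * C[i], 2L * C[i]))
        }
        st
      }),
      out_norms = lapply(1:4, function(i)
        list(gamma = rep(1, C[i]), beta = numeric(C[i])))
    )
    structure(params, class = "backbone_params", spec = spec)
  })
}

#' Count learnable parameters
#'
#' `count_parameters()` is the closed form; `count_parameters_actual()` sums
#' the instantiated arrays. The two agree exactly (tested). The closed form
#' optionally includes the detection neck and head (FPN laterals and
#' smoothers, two convolution towers, prediction layers and per-level
#' scales), since published totals for comparable detectors count the full
#' model.
#'
#' @param spec a [variant_spec()].
#' @param include_head include FPN + detection head parameters.
#' @param head list of head hyperparameters (`channels`, `n_convs`,
#'   `n_classes`), defaulting to the standard anchor-free head.
#' @return numeric parameter count.
#' @export
count_parameters <- function(spec, include_head = TRUE,
                             head = list(channels = 256L, n_convs = 4L,
                                         n_classes = 1L)) {
  C <- as.numeric(spec$channels)
  heads <- C / spec$head_dim
  a <- spec$mlp_ratio
  total <- 48 * C[1L] + C[1L]                      # patch embedding
  for (i in 1:4) {
    Ci <- C[i]
    per_block <-
      2 * Ci +                                     # ln1
      sum(vapply(spec$window_sizes, function(X)
        Ci * 3 * Ci + 3 * Ci + (2 * X - 1)^2 * heads[i], numeric(1))) +
      length(spec$window_sizes) * Ci * Ci + Ci +   # branch-concat projection
      2 * Ci +                                     # ln2
      Ci * a * Ci + a * Ci + a * Ci * Ci + Ci      # mlp
    if (is.list(spec$sr_mode) && identical(spec$sr_mode$type, "bottleneck")) {
      r <- spec$sr_mode$r
      per_block <- per_block + r * r * Ci * Ci + Ci
    }
    total <- total + spec$depths[i] * per_block
    if (i < 4L) total <- total + 8 * Ci + 4 * Ci * 2 * Ci  # merge ln + proj
    total <- total + 2 * Ci                        # output norm
  }
  if (include_head) {
    P <- head$channels; ncv <- head$n_convs; ncl <- head$n_classes
    total <- total +
      sum((C[2:4]) * P + P) +                      # lateral 1x1
      3 * (9 * P * P + P) +                        # P3-P5 3x3 smoothing
      2 * (9 * P * P + P) +                        # P6, P7 stride-2 3x3
      2 * ncv * (9 * P * P + P + 2 * P) +          # cls + reg towers (+ norm)
      (9 * P * ncl + ncl) +                        # classification logits
      (9 * P * 1 + 1) +                            # centerness
      (9 * P * 4 + 4) +                            # ltrb regression
      5                                            # per-level scales
  }
  total
}

#' @rdname count_parameters
#' @param params a parameter list (backbone or full model).
#' @export
count_parameters_actual <- function(params) {
  total <- 0
  nested_map(function(x) { total <<- total + length(x); NULL }, unclass(params))
  total
}

# ---- index helpers (plain integer vectors driving ad_gather_rows) -----------

# row-major token index of grid (h, w): row (r-1)*w + c
idx_pad <- function(h, w, hp, wp) {
  r <- rep(seq_len(hp), each = wp); c_ <- rep(seq_len(wp), times = hp)
  ifelse(r <= h & c_ <= w, (r - 1L) * w + c_, 0L)
}

idx_crop <- function(hp, wp, h, w) {
  r <- rep(seq_len(h), each = w); c_ <- rep(seq_len(w), times = h)
  (r - 1L) * wp + c_
}

# cyclic roll: output (r, c) takes input ((r - dy - 1) mod h + 1, ...)
idx_roll <- function(h, w, dy, dx) {
  r <- rep(seq_len(h), each = w); c_ <- rep(seq_len(w), times = h)
  sr <- ((r - dy - 1L) %% h) + 1L
  sc <- ((c_ - dx - 1L) %% w) + 1L
  (sr - 1L) * w + sc
}

# partition padded grid (hp, wp) into X x X windows; output row order:
# window-major (row-major over windows), row-major token order inside,
# i.e. output row t + (wi - 1) * X^2.
idx_window_partition <- function(hp, wp, X) {
  nwx <- wp %/% X
  out <- integer(hp * wp)
  pos <- 0L
  for (wy in seq_len(hp %/% X)) for (wx in seq_len(nwx)) {
    for (i in seq_len(X)) {
      base <- ((wy - 1L) * X + i - 1L) * wp + (wx - 1L) * X
      out[(pos + 1L):(pos + X)] <- base + seq_len(X)
      pos <- pos + X
    }
  }
  out
}

idx_window_reverse <- function(hp, wp, X) {
  fwd <- idx_window_partition(hp, wp, X)
  inv <- integer(length(fwd))
  inv[fwd] <- seq_along(fwd)
  inv
}

# relative-position index for an X x X window: (X^2 x X^2) values in
# 1..(2X-1)^2, row = query token, col = key token (row-major token order)
relative_position_index <- function(X) {
  r <- rep(seq_len(X), each = X); c_ <- rep(seq_len(X), times = X)
  dr <- outer(r, r, `-`) + X - 1L
  dc <- outer(c_, c_, `-`) + X - 1L
  dr * (2L * X - 1L) + dc + 1L
}

# Shifted-window region ids on the ROLLED padded (hp, wp) canvas: the
# standard three-band scheme per axis (interior, window remainder, shift
# strip) indexed by post-roll position, with padding tokens (original
# position beyond h, w, tracked through the roll) given a unique id so they
# can only attend each other. Token order, length hp*wp.
shift_region_ids <- function(h, w, hp, wp, X, s) {
  band <- function(np) {
    ids <- rep(1L, np)
    if (X <= np) ids[(np - X + 1L):np] <- 2L
    if (s >= 1L) ids[(np - s + 1L):np] <- 3L
    ids
  }
  hb <- band(hp); wb <- band(wp)
  r <- rep(seq_len(hp), each = wp); c_ <- rep(seq_len(wp), times = hp)
  ids <- (hb[r] - 1L) * 3L + wb[c_]
  pad_orig <- r > h | c_ > w
  pad_rolled <- if (s > 0L) pad_orig[idx_roll(hp, wp, -s, -s)] else pad_orig
  ids[pad_rolled] <- 99L
  ids
}

# ---- public pure operations -------------------------------------------------

#' Partition an image into 4x4 patch tokens
#'
#' Each non-overlapping 4x4 RGB patch is flattened to a 48-vector
#' (4 * 4 * 3 = 48). The image height and width must be divisible by 4
#' (callers pad first; [backbone_forward()] pads to a multiple of 32).
#'
#' @param image H x W x 3 numeric array.
#' @param patch_size patch side length (default 4).
#' @return list with `x` ((H/4 * W/4) x 48 matrix, row-major token order),
#'   `h`, `w` (token-grid dims).
#' @export
patch_partition <- function(image, patch_size = 4L) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) stop("image must be H x W x 3")
  H <- d[1L]; W <- d[2L]; P <- patch_size
  if (H %% P != 0L || W %% P != 0L) {
    stop("image dims must be divisible by the patch size; pad first")
  }
  h <- H %/% P; w <- W %/% P
  x <- matrix(0, h * w, P * P * 3L)
  # feature order within a patch: channel fastest, then patch col, patch row
  for (pr in seq_len(P)) for (pc in seq_len(P)) for (ch in 1:3) {
    col <- ch + (pc - 1L) * 3L + (pr - 1L) * 3L * P
    sub <- image[seq(pr, H, by = P), seq(pc, W, by = P), ch]  # h x w
    x[, col] <- as.vector(t(sub))                             # row-major tokens
  }
  list(x = x, h = h, w = w)
}

#' Linear token embedding
#'
#' Projects 48-channel patch tokens to the embedding width with a single
#' affine map shared across positions.
#'
#' @param tokens list as returned by [patch_partition()].
#' @param W 48 x C weight matrix.
#' @param b length-C bias.
#' @return token list with `x` of width `C`.
#' @export
linear_embed <- function(tokens, W, b) {
  if (ncol(tokens$x) != nrow(W)) stop("channel mismatch in linear embedding")
  list(x = sweep(tokens$x %*% W, 2L, b, `+`), h = tokens$h, w = tokens$w)
}

#' Partition a token grid into windows (and back)
#'
#' The grid is zero-padded bottom/right to multiples of `X` and tiled into
#' `ceiling(h/X) * ceiling(w/X)` windows. `window_reverse()` undoes the
#' tiling and crops the padding, so reverse(partition(x)) is the identity.
#'
#' @param tokens token list (`x`, `h`, `w`).
#' @param X window side length.
#' @return `window_partition()`: list with `windows` (array nW x X^2 x C),
#'   `hp`, `wp` (padded dims), `real` (nW x X^2 logical marking non-padding
#'   tokens), plus the original `h`, `w`, `X`.
#' @export
window_partition <- function(tokens, X) {
  h <- tokens$h; w <- tokens$w; C <- ncol(tokens$x)
  hp <- ceiling(h / X) * X; wp <- ceiling(w / X) * X
  padded <- matrix(0, hp * wp, C)
  keep <- idx_pad(h, w, hp, wp)
  padded[keep > 0L, ] <- tokens$x[keep[keep > 0L], , drop = FALSE]
  pidx <- idx_window_partition(hp, wp, X)
  part <- padded[pidx, , drop = FALSE]
  nW <- (hp %/% X) * (wp %/% X)
  arr <- array(0, c(nW, X * X, C))
  for (i in seq_len(nW)) arr[i, , ] <- part[((i - 1L) * X * X + 1L):(i * X * X), ]
  real <- keep[pidx] > 0L
  list(windows = arr, hp = hp, wp = wp, h = h, w = w, X = X,
       real = matrix(real, nW, X * X, byrow = TRUE))
}

#' @rdname window_partition
#' @param part result of [window_partition()] (with possibly modified
#'   `windows` values).
#' @export
window_reverse <- function(part) {
  X <- part$X; nW <- dim(part$windows)[1L]; C <- dim(part$windows)[3L]
  flat <- matrix(0, nW * X * X, C)
  for (i in seq_len(nW)) {
    flat[((i - 1L) * X * X + 1L):(i * X * X), ] <- part$windows[i, , ]
  }
  grid <- flat[idx_window_reverse(part$hp, part$wp, X), , drop = FALSE]
  keep <- idx_crop(part$hp, part$wp, part$h, part$w)
  list(x = grid[keep, , drop = FALSE], h = part$h, w = part$w)
}

#' Scaled dot-product attention with additive bias and mask
#'
#' `Softmax(Q K^T / sqrt(d) + B + mask) V` computed per batch slice. Rows of
#' the softmax weight matrix sum to 1 over unmasked entries.
#'
#' @param Q,K,V arrays (B, n, d).
#' @param bias optional (B, n, n) additive bias (relative-position bias).
#' @param mask optional (B, n, n) additive mask (0 or large negative).
#' @return array (B, n, d).
#' @export
attention <- function(Q, K, V, bias = NULL, mask = NULL) {
  B <- dim(Q)[1L]; n <- dim(Q)[2L]; d <- dim(Q)[3L]
  out <- array(0, c(B, n, dim(V)[3L]))
  for (i in seq_len(B)) {
    qi <- matrix(Q[i, , ], n, d)
    ki <- matrix(K[i, , ], dim(K)[2L], d)
    logits <- qi %*% t(ki) / sqrt(d)
    if (!is.null(bias)) logits <- logits + matrix(bias[i, , ], n)
    if (!is.null(mask)) logits <- logits + matrix(mask[i, , ], n)
    logits <- logits - apply(logits, 1L, max)
    wgt <- exp(logits); wgt <- wgt / rowSums(wgt)
    out[i, , ] <- wgt %*% matrix(V[i, , ], dim(V)[2L], dim(V)[3L])
  }
  out
}

# ---- autodiff forward pieces (parameters are node-valued lists) -------------

# persistent cache of window indices and masks, keyed by geometry only
.branch_cache <- new.env(parent = emptyenv())

# compose two gather index vectors (0 = zero row) into one
compose_idx <- function(outer_idx, inner_idx) {
  out <- integer(length(outer_idx))
  nz <- outer_idx > 0L
  out[nz] <- inner_idx[outer_idx[nz]]
  out
}

branch_geometry <- function(h, w, X, s, heads) {
  key <- paste(h, w, X, s, heads, sep = "_")
  got <- .branch_cache[[key]]
  if (!is.null(got)) return(got)
  hp <- ceiling(h / X) * X; wp <- ceiling(w / X) * X
  part <- idx_window_partition(hp, wp, X)
  nW <- (hp %/% X) * (wp %/% X)
  ids <- shift_region_ids(h, w, hp, wp, X, s)  # already in rolled layout
  idw <- matrix(ids[part], X * X, nW)          # token-major within window
  mask <- array(0, c(nW, X * X, X * X))
  for (i in seq_len(nW)) {
    mask[i, , ] <- (outer(idw[, i], idw[, i], `!=`)) * -1e9
  }
  maskB <- mask[rep(seq_len(nW), each = heads), , , drop = FALSE]
  pad <- idx_pad(h, w, hp, wp)
  gather_in <- if (s > 0L) {
    compose_idx(part, compose_idx(idx_roll(hp, wp, -s, -s), pad))
  } else compose_idx(part, pad)
  rev <- idx_window_reverse(hp, wp, X)
  crop <- idx_crop(hp, wp, h, w)
  gather_out <- if (s > 0L) {
    compose_idx(crop, compose_idx(idx_roll(hp, wp, s, s), rev))
  } else compose_idx(crop, rev)
  out <- list(hp = hp, wp = wp, nW = nW, gather_in = gather_in,
              gather_out = gather_out, maskB = maskB,
              rel = as.vector(relative_position_index(X)))
  .branch_cache[[key]] <- out
  out
}

# one windowed-attention branch on an (h*w x C) node; returns same-shape node
branch_attention_ad <- function(x, h, w, C, X, shift, heads, br, cache) {
  d <- C %/% heads
  s <- if (shift) X %/% 2L else 0L
  cc <- branch_geometry(h, w, X, s, heads)
  n2 <- X * X; nW <- cc$nW
  xw <- ad_gather_rows(x, cc$gather_in)                   # (nW*n2, C), t fastest
  qkv <- ad_add_bias(ad_matmul(xw, br$Wqkv), br$bqkv)     # (nW*n2, 3C)
  split_heads <- function(m) {
    m <- ad_reshape(m, c(n2, nW, d, heads))
    m <- ad_aperm(m, c(4L, 2L, 1L, 3L))                   # (heads, nW, n2, d)
    ad_reshape(m, c(heads * nW, n2, d))                   # batch = h + heads*(w-1)
  }
  Q <- split_heads(ad_index_cols(qkv, 1:C))
  K <- split_heads(ad_index_cols(qkv, (C + 1L):(2L * C)))
  V <- split_heads(ad_index_cols(qkv, (2L * C + 1L):(3L * C)))
  logits <- ad_scale(ad_bmm(Q, K, transpose_b = TRUE), 1 / sqrt(d))
  bias <- ad_gather_rows(br$bias_table, cc$rel)           # (n2*n2, heads)
  bias <- ad_aperm(ad_reshape(bias, c(n2, n2, heads)), c(3L, 1L, 2L))
  logits <- ad_add(logits, ad_tile_batch(bias, nW))
  logits <- ad_add_const(logits, cc$maskB)
  attn <- ad_softmax(logits)
  out <- ad_bmm(attn, V)                                  # (heads*nW, n2, d)
  out <- ad_reshape(out, c(heads, nW, n2, d))
  out <- ad_aperm(out, c(3L, 2L, 4L, 1L))                 # (n2, nW, d, heads)
  out <- ad_reshape(out, c(n2 * nW, d * heads))           # head concat -> C
  ad_gather_rows(out, cc$gather_out)                      # (h*w, C)
}

# multi-window attention sublayer (three branches, concat, project)
mw_attention_ad <- function(x, h, w, C, spec, bp, shift, cache) {
  heads <- C %/% spec$head_dim
  outs <- lapply(seq_along(spec$window_sizes), function(k) {
    branch_attention_ad(x, h, w, C, spec$window_sizes[k], shift, heads,
                        bp$attn$branches[[k]], cache)
  })
  cat3 <- ad_concat_cols(outs)
  ad_add_bias(ad_matmul(cat3, bp$attn$proj$W), bp$attn$proj$b)
}

spatial_reduce_ad <- function(x, h, w, C, spec, bp) {
  mode <- spec$sr_mode
  if (identical(mode, "identity")) return(x)
  if (is.list(mode) && identical(mode$type, "bottleneck")) {
    r <- mode$r
    if (r == 1L) {
      return(ad_add_bias(ad_matmul(x, bp$sr$W), bp$sr$b))
    }
    hp <- ceiling(h / r) * r; wp <- ceiling(w / r) * r
    xp <- ad_gather_rows(x, idx_pad(h, w, hp, wp))
    pidx <- idx_window_partition(hp, wp, r)
    grp <- ad_gather_rows(xp, pidx)                             # (nB*r2, C)
    nB <- (hp %/% r) * (wp %/% r); r2 <- r * r
    grp <- ad_reshape(grp, c(r2, nB, C))
    grp <- ad_aperm(grp, c(2L, 1L, 3L))                         # (nB, r2, C)
    grp <- ad_reshape(grp, c(nB, r2 * C))
    mixed <- ad_add_bias(ad_matmul(grp, bp$sr$W), bp$sr$b)      # (nB, C)
    restored <- ad_gather_rows(mixed, rep(seq_len(nB), each = r2))
    back <- ad_gather_rows(restored, order(pidx))               # undo partition
    return(ad_gather_rows(back, idx_crop(hp, wp, h, w)))
  }
  stop("unknown sr_mode")
}

block_forward_ad <- function(x, h, w, C, spec, bp, shift, cache) {
  a <- ad_layernorm(x, bp$ln1$gamma, bp$ln1$beta)
  a <- mw_attention_ad(a, h, w, C, spec, bp, shift, cache)
  z <- ad_add(a, x)
  z <- spatial_reduce_ad(z, h, w, C, spec, bp)
  m <- ad_layernorm(z, bp$ln2$gamma, bp$ln2$beta)
  m <- ad_add_bias(ad_matmul(m, bp$mlp$W1), bp$mlp$b1)
  m <- ad_gelu(m)
  m <- ad_add_bias(ad_matmul(m, bp$mlp$W2), bp$mlp$b2)
  ad_add(m, z)
}

patch_merge_ad <- function(x, h, w, C, mp) {
  hp <- h + h %% 2L; wp <- w + w %% 2L
  xp <- ad_gather_rows(x, idx_pad(h, w, hp, wp))
  grp <- ad_gather_rows(xp, idx_window_partition(hp, wp, 2L))  # (nB*4, C)
  nB <- (hp %/% 2L) * (wp %/% 2L)
  grp <- ad_reshape(grp, c(4L, nB, C))
  grp <- ad_aperm(grp, c(2L, 1L, 3L))
  grp <- ad_reshape(grp, c(nB, 4L * C))
  grp <- ad_layernorm(grp, mp$ln$gamma, mp$ln$beta)
  list(x = ad_matmul(grp, mp$W), h = hp %/% 2L, w = wp %/% 2L)
}

# full backbone on node-valued params; image already padded to mult of 32
backbone_forward_ad <- function(image, np, spec, cache) {
  tk <- patch_partition(image, spec$patch_size)
  x <- ad_add_bias(ad_matmul(ad_leaf(tk$x), np$patch_embed$W), np$patch_embed$b)
  h <- tk$h; w <- tk$w
  feats <- vector("list", 4L)
  for (i in 1:4) {
    C <- spec$channels[i]
    for (j in seq_len(spec$depths[i])) {
      x <- block_forward_ad(x, h, w, C, spec, np$stages[[i]]$blocks[[j]],
                            shift = (j %% 2L == 0L), cache)
    }
    on <- np$out_norms[[i]]
    feats[[i]] <- list(x = ad_layernorm(x, on$gamma, on$beta), h = h, w = w)
    if (i < 4L) {
      mg <- patch_merge_ad(x, h, w, C, np$stages[[i]]$merge)
      x <- mg$x; h <- mg$h; w <- mg$w
    }
  }
  feats
}

pad_image_32 <- function(image) {
  d <- dim(image)
  Hp <- as.integer(ceiling(d[1L] / 32) * 32)
  Wp <- as.integer(ceiling(d[2L] / 32) * 32)
  if (Hp != d[1L] || Wp != d[2L]) {
    padded <- array(0, c(Hp, Wp, 3L))
    padded[seq_len(d[1L]), seq_len(d[2L]), ] <- image
    image <- padded
  }
  image
}

#' Forward pass through the backbone
#'
#' Pads the image bottom/right to a multiple of 32, partitions into patch
#' tokens, embeds, and runs the four stages, returning the four
#' layer-normalised stage outputs at strides 4, 8, 16, 32.
#'
#' @param image H x W x 3 numeric array (H, W at least 32).
#' @param params [init_backbone()] parameters.
#' @return list with `features` (list of 4 token lists `x`, `h`, `w`),
#'   `padded_h`, `padded_w`.
#' @export
backbone_forward <- function(image, params) {
  spec <- attr(params, "spec")
  d <- dim(image)
  if (d[1L] < 32L || d[2L] < 32L) stop("image must be at least 32 x 32")
  image <- pad_image_32(image)
  ad_reset()
  np <- params_to_nodes(params)
  feats <- backbone_forward_ad(image, np, spec, new.env(parent = emptyenv()))
  out <- lapply(feats, function(f) list(x = f$x$value, h = f$h, w = f$w))
  ad_reset()
  list(features = out, padded_h = dim(image)[1L], padded_w = dim(image)[2L])
}

#' Multi-window attention sublayer (plain-array wrapper)
#'
#' Applies the three-branch (shifted) multi-window attention of one block to
#' a token map, using the supplied block parameters. Exposed mainly for
#' testing against dense-attention oracles; training uses the same code
#' through the autodiff path.
#'
#' @param tokens token list (`x`, `h`, `w`).
#' @param spec a [variant_spec()] (supplies window sizes and head dim).
#' @param block_params one element of `params$stages[[i]]$blocks`.
#' @param shift use the shifted variant (second block of each pair).
#' @return token list with the attention sublayer output (no residual, no
#'   layer norm: just the windowed-attention + projection map).
#' @export
mw_msa <- function(tokens, spec, block_params, shift = FALSE) {
  ad_reset()
  C <- ncol(tokens$x)
  bp <- params_to_nodes(block_params)
  out <- mw_attention_ad(ad_leaf(tokens$x), tokens$h, tokens$w, C, spec, bp,
                         shift, new.env(parent = emptyenv()))
  res <- list(x = out$value, h = tokens$h, w = tokens$w)
  ad_reset()
  res
}

#' @rdname mw_msa
#' @export
smw_msa <- function(tokens, spec, block_params) {
  mw_msa(tokens, spec, block_params, shift = TRUE)
}

#' Spatial-reduction module (plain wrapper)
#'
#' Identity by default; in bottleneck mode mixes `r x r` token blocks
#' through a linear map and restores the grid by replication, so the output
#' grid always equals the input grid.
#'
#' @inheritParams mw_msa
#' @export
spatial_reduce <- function(tokens, spec, block_params) {
  if (identical(spec$sr_mode, "identity")) return(tokens)
  ad_reset()
  bp <- params_to_nodes(block_params)
  out <- spatial_reduce_ad(ad_leaf(tokens$x), tokens$h, tokens$w,
                           ncol(tokens$x), spec, bp)
  res <- list(x = out$value, h = tokens$h, w = tokens$w)
  ad_reset()
  res
}

#' One pair of consecutive blocks (plain wrapper)
#'
#' Runs the plain and shifted blocks in sequence:
#' attention -> residual -> spatial reduction -> MLP -> residual, twice.
#'
#' @inheritParams mw_msa
#' @param block_params_pair list of two block-parameter sets.
#' @export
block_pair_forward <- function(tokens, spec, block_params_pair) {
  ad_reset()
  C <- ncol(tokens$x)
  cache <- new.env(parent = emptyenv())
  x <- ad_leaf(tokens$x)
  x <- block_forward_ad(x, tokens$h, tokens$w, C, spec,
                        params_to_nodes(block_params_pair[[1L]]), FALSE, cache)
  x <- block_forward_ad(x, tokens$h, tokens$w, C, spec,
                        params_to_nodes(block_params_pair[[2L]]), TRUE, cache)
  res <- list(x = x$value, h = tokens$h, w = tokens$w)
  ad_reset()
  res
}

#' Patch merging (plain wrapper)
#'
#' Concatenates each 2x2 token group (4C channels), layer-normalises and
#' projects to 2C; grid dims halve (odd dims are padded first).
#'
#' @param tokens token list.
#' @param merge_params `params$stages[[i]]$merge`.
#' @export
patch_merge <- function(tokens, merge_params) {
  ad_reset()
  mp <- params_to_nodes(merge_params)
  out <- patch_merge_ad(ad_leaf(tokens$x), tokens$h, tokens$w,
                        ncol(tokens$x), mp)
  res <- list(x = out$x$value, h = out$h, w = out$w)
  ad_reset()
  res
}
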