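#' @title Anchor-free detection head
#'
#' @description
#' A fully-convolutional one-stage detector in the FCOS mould: a feature
#' pyramid (P3-P7, strides 8-128) built from the backbone's stride-8/16/32
#' outputs, per-location classification / center-ness / ltrb-regression
#' predictions from two shared convolution towers, positive-sample
#' assignment by box membership with per-level regression ranges and a
#' smallest-area tie-break, and a three-part training loss
#' `L = L_cls / N_pos + lambda1 * L_ctr / N_pos + lambda2 * L_reg / N_pos`
#' with focal classification loss, binary cross-entropy center-ness loss and
#' a selectable IoU-family regression loss (iou, giou, ciou or wiou).
#'
#' Convolutions are lowered to im2col gathers plus matrix products so that
#' the same autodiff engine trains backbone and head end to end.
#'
#' @name fcos_detector
NULL

fpn_strides <- function() c(8L, 16L, 32L, 64L, 128L)

# FCOS per-level regression ranges (max ltrb distance handled by each level)
default_regress_ranges <- function() {
  list(c(0, 64), c(64, 128), c(128, 256), c(256, 512), c(512, Inf))
}

#' Loss / inference configuration
#'
#' @param reg_loss regression loss family: `"wiou"` (default), `"iou"`,
#'   `"giou"` or `"ciou"`.
#' @param lambda1,lambda2 balance weights for the center-ness and regression
#'   terms (both default 1, the FCOS settings).
#' @param focal_alpha,focal_gamma focal-loss parameters (0.25, 2).
#' @param wiou_normalize normalise the WIoU distance term by the enclosing
#'   diagonal (see [wiou_loss()]); default `FALSE` (as printed).
#' @param score_thr,nms_iou,pre_nms_top,max_det inference thresholds.
#' @return list of class `"loss_config"`.
#' @export
loss_config <- function(reg_loss = c("wiou", "iou", "giou", "ciou"),
                        lambda1 = 1, lambda2 = 1,
                        focal_alpha = 0.25, focal_gamma = 2,
                        wiou_normalize = FALSE,
                        score_thr = 0.05, nms_iou = 0.6,
                        pre_nms_top = 1000L, max_det = 100L) {
  structure(list(reg_loss = match.arg(reg_loss), lambda1 = lambda1,
                 lambda2 = lambda2, focal_alpha = focal_alpha,
                 focal_gamma = focal_gamma, wiou_normalize = wiou_normalize,
                 score_thr = score_thr, nms_iou = nms_iou,
                 pre_nms_top = as.integer(pre_nms_top),
                 max_det = as.integer(max_det)),
            class = "loss_config")
}

# ---- parameters -------------------------------------------------------------

conv_param <- function(cin, cout, k = 3L, sd = 0.02, bias0 = 0) {
  list(W = tn_mat(k * k * cin, cout, sd), b = rep(bias0, cout))
}

# tower conv + per-location channel normalisation (the GN role in FCOS)
tower_param <- function(cin, cout) {
  c(conv_param(cin, cout),
    list(gamma = rep(1, cout), beta = numeric(cout)))
}

#' Instantiate detector (FPN + head) parameters
#'
#' @param spec backbone [variant_spec()] (supplies input channel widths).
#' @param channels pyramid width (256 for full-size variants, smaller for
#'   tiny).
#' @param n_convs tower depth (4 for full size).
#' @param n_classes number of foreground classes (1: spike).
#' @param seed integer seed.
#' @return nested parameter list (class `"detector_params"`).
#' @export
init_detector <- function(spec, channels = NULL, n_convs = NULL,
                          n_classes = 1L, seed = 1L) {
  if (is.null(channels)) channels <- if (spec$name == "tiny") 32L else 256L
  if (is.null(n_convs)) n_convs <- if (spec$name == "tiny") 2L else 4L
  P <- channels
  with_local_seed(seed, {
    params <- list(
      lateral = lapply(spec$channels[2:4], function(Ci)
        list(W = tn_mat(Ci, P), b = numeric(P))),
      smooth = lapply(1:3, function(i) conv_param(P, P)),
      p6 = conv_param(P, P),
      p7 = conv_param(P, P),
      cls_tower = lapply(seq_len(n_convs), function(i) tower_param(P, P)),
      reg_tower = lapply(seq_len(n_convs), function(i) tower_param(P, P)),
      # focal-prior bias: start every location at ~1% foreground probability
      cls_pred = conv_param(P, n_classes, bias0 = -log(99)),
      ctr_pred = conv_param(P, 1L),
      reg_pred = conv_param(P, 4L),
      scales = rep(1, 5)
    )
    structure(params, class = "detector_params", channels = P,
              n_convs = n_convs, n_classes = n_classes)
  })
}

#' Full detection model
#'
#' Bundles backbone and detector parameters with their configuration.
#'
#' @param variant variant name (`"S"`, `"B"`, `"L"`, `"tiny"`).
#' @param seed integer seed for all weight draws.
#' @param sr_mode passed to [variant_spec()].
#' @param n_classes foreground classes.
#' @return list of class `"spike_model"` with `spec`, `backbone`, `detector`.
#' @export
init_spike_model <- function(variant = "tiny", seed = 1L,
                             sr_mode = "identity", n_classes = 1L) {
  spec <- variant_spec(variant, sr_mode = sr_mode)
  structure(list(spec = spec,
                 backbone = init_backbone(spec, seed = seed),
                 detector = init_detector(spec, n_classes = n_classes,
                                          seed = seed + 1L)),
            class = "spike_model")
}

#' Save / load a model checkpoint
#'
#' Standard R serialisation with the variant specification embedded; a
#' loaded checkpoint restores an identical model.
#'
#' @param model a `spike_model`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "spike_model")) stop("not a spike_model checkpoint: ", path)
  model
}

# ---- convolution lowering ---------------------------------------------------

# im2col gather index for k x k conv, same-padding, given stride.
# Output rows ordered: output position fastest (row-major grid), tap major.
conv_idx_cache <- new.env(parent = emptyenv())
conv_gather_idx <- function(h, w, k, stride) {
  key <- paste(h, w, k, stride, sep = "_")
  got <- conv_idx_cache[[key]]
  if (!is.null(got)) return(got)
  pad <- (k - 1L) %/% 2L
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  ro <- rep(seq_len(ho), each = wo); co <- rep(seq_len(wo), times = ho)
  idx <- integer(ho * wo * k * k)
  pos <- 0L
  for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
    sr <- (ro - 1L) * stride + dr + 1L - pad
    sc <- (co - 1L) * stride + dc + 1L - pad
    v <- ifelse(sr >= 1L & sr <= h & sc >= 1L & sc <= w, (sr - 1L) * w + sc, 0L)
    idx[(pos + 1L):(pos + ho * wo)] <- v
    pos <- pos + ho * wo
  }
  out <- list(idx = idx, ho = ho, wo = wo, k2 = k * k)
  conv_idx_cache[[key]] <- out
  out
}

ad_conv <- function(x, h, w, p, k = 3L, stride = 1L) {
  cin <- ncol(x$value)
  ci <- conv_gather_idx(h, w, k, stride)
  g <- ad_gather_rows(x, ci$idx)                      # (ho*wo*k2, cin)
  g <- ad_reshape(g, c(ci$ho * ci$wo, ci$k2, cin))
  g <- ad_aperm(g, c(1L, 3L, 2L))
  g <- ad_reshape(g, c(ci$ho * ci$wo, cin * ci$k2))   # col = c + cin*(t-1)
  out <- ad_add_bias(ad_matmul(g, p$W), p$b)
  list(x = out, h = ci$ho, w = ci$wo)
}

# nearest-neighbour 2x upsample from (hc, wc) to (hf, wf)
ad_upsample2 <- function(x, hc, wc, hf, wf) {
  r <- rep(seq_len(hf), each = wf); c_ <- rep(seq_len(wf), times = hf)
  sr <- pmin((r + 1L) %/% 2L, hc); sc <- pmin((c_ + 1L) %/% 2L, wc)
  ad_gather_rows(x, (sr - 1L) * wc + sc)
}

# ---- feature pyramid --------------------------------------------------------

# dp: node-valued detector params; feats: list of 4 token lists (nodes)
build_pyramid_ad <- function(feats, dp) {
  f <- feats[2:4]
  lat <- lapply(1:3, function(i)
    ad_add_bias(ad_matmul(f[[i]]$x, dp$lateral[[i]]$W), dp$lateral[[i]]$b))
  h <- vapply(f, function(t) t$h, integer(1))
  w <- vapply(f, function(t) t$w, integer(1))
  # top-down pathway
  td5 <- lat[[3L]]
  td4 <- ad_add(lat[[2L]], ad_upsample2(td5, h[3L], w[3L], h[2L], w[2L]))
  td3 <- ad_add(lat[[1L]], ad_upsample2(td4, h[2L], w[2L], h[1L], w[1L]))
  p3 <- ad_conv(td3, h[1L], w[1L], dp$smooth[[1L]])
  p4 <- ad_conv(td4, h[2L], w[2L], dp$smooth[[2L]])
  p5 <- ad_conv(td5, h[3L], w[3L], dp$smooth[[3L]])
  p6 <- ad_conv(p5$x, p5$h, p5$w, dp$p6, stride = 2L)
  p7 <- ad_conv(ad_relu(p6$x), p6$h, p6$w, dp$p7, stride = 2L)
  levels <- list(p3, p4, p5, p6, p7)
  strides <- fpn_strides()
  lapply(1:5, function(i)
    list(x = levels[[i]]$x, h = levels[[i]]$h, w = levels[[i]]$w,
         stride = strides[i]))
}

#' Build the feature pyramid (plain wrapper)
#'
#' Lateral 1x1 projections of the stride-8/16/32 backbone outputs, top-down
#' nearest-neighbour summation, 3x3 smoothing (P3-P5), and stride-2 3x3
#' convolutions for P6 and P7. All levels share the pyramid channel width.
#'
#' @param features list of four backbone token lists (from
#'   [backbone_forward()]; levels 2-4 are used).
#' @param det_params [init_detector()] parameters.
#' @return list of 5 levels, each `x` (tokens x channels), `h`, `w`,
#'   `stride`.
#' @export
build_pyramid <- function(features, det_params) {
  ad_reset()
  dp <- params_to_nodes(det_params)
  featn <- lapply(features, function(f) list(x = ad_leaf(f$x), h = f$h, w = f$w))
  pyr <- build_pyramid_ad(featn, dp)
  out <- lapply(pyr, function(p) list(x = p$x$value, h = p$h, w = p$w,
                                      stride = p$stride))
  ad_reset()
  out
}

# head on one pyramid level -> cls/ctr logits and positive ltrb (image units)
head_forward_ad <- function(level, dp, level_idx) {
  x <- level$x; h <- level$h; w <- level$w
  ct <- x
  for (p in dp$cls_tower) {
    cv <- ad_conv(ct, h, w, p)
    ct <- ad_relu(ad_layernorm(cv$x, p$gamma, p$beta))
  }
  rt <- x
  for (p in dp$reg_tower) {
    rv <- ad_conv(rt, h, w, p)
    rt <- ad_relu(ad_layernorm(rv$x, p$gamma, p$beta))
  }
  cls <- ad_conv(ct, h, w, dp$cls_pred)$x
  ctr <- ad_conv(rt, h, w, dp$ctr_pred)$x
  raw <- ad_conv(rt, h, w, dp$reg_pred)$x
  sc <- ad_index_cols(ad_reshape(dp$scales, c(1L, 5L)), level_idx)
  ltrb <- ad_scale(ad_exp(ad_mul_snode(raw, sc)), level$stride)
  list(cls = cls, ctr = ctr, ltrb = ltrb, h = h, w = w, stride = level$stride)
}

model_forward_ad <- function(image, bn, dn, spec, cache) {
  feats <- backbone_forward_ad(image, bn, spec, cache)
  pyr <- build_pyramid_ad(feats, dn)
  lapply(seq_along(pyr), function(i) head_forward_ad(pyr[[i]], dn, i))
}

#' End-to-end forward pass of the detection model
#'
#' @param image H x W x 3 array.
#' @param model a `spike_model`.
#' @return list of 5 per-level outputs with plain-matrix `cls`, `ctr`
#'   (logits), `ltrb` (decoded positive distances in pixels), `h`, `w`,
#'   `stride`, plus attributes `padded_h`, `padded_w`.
#' @export
model_forward <- function(image, model) {
  image <- pad_image_32(image)
  ad_reset()
  bn <- params_to_nodes(model$backbone)
  dn <- params_to_nodes(model$detector)
  outs <- model_forward_ad(image, bn, dn, model$spec,
                           new.env(parent = emptyenv()))
  res <- lapply(outs, function(o)
    list(cls = o$cls$value, ctr = o$ctr$value, ltrb = o$ltrb$value,
         h = o$h, w = o$w, stride = o$stride))
  ad_reset()
  attr(res, "padded_h") <- dim(image)[1L]
  attr(res, "padded_w") <- dim(image)[2L]
  res
}

# ---- assignment -------------------------------------------------------------

#' Feature-map locations of one pyramid level
#'
#' Cell `(row r, col c)` at stride `s` maps to the image point
#' `((c-1)s + s/2, (r-1)s + s/2)`, in row-major order matching the token
#' layout.
#'
#' @param h,w level grid dims.
#' @param stride level stride.
#' @return (h*w) x 2 matrix of `(x, y)` locations.
#' @export
generate_locations <- function(h, w, stride) {
  r <- rep(seq_len(h), each = w); c_ <- rep(seq_len(w), times = h)
  cbind(x = (c_ - 1) * stride + stride / 2, y = (r - 1) * stride + stride / 2)
}

#' Assign training targets to pyramid locations
#'
#' A location is positive when it falls inside at least one ground-truth box
#' (boundary counts as inside) and the largest of its four side distances
#' lies within the level's regression range; among multiple containing
#' boxes, the one with the smallest area wins (first in input order on
#' ties). Positives receive ltrb and center-ness targets. With no ground
#' truth everything is negative and `n_pos` is clamped to 1 for loss
#' normalisation.
#'
#' @param level_dims list of per-level lists with `h`, `w`, `stride`.
#' @param gt_boxes m x 4 box matrix (may have zero rows).
#' @param regress_ranges per-level `(lo, hi]` ranges for the max ltrb
#'   distance.
#' @return list of class `"assignment"`: per-level `labels` (0/1 vector),
#'   `targets` (n x 4), `ctr_targets`, `gt_index`, `locations`; plus global
#'   `n_pos` (clamped) and `n_pos_raw`.
#' @export
assign_targets <- function(level_dims, gt_boxes,
                           regress_ranges = default_regress_ranges()) {
  if (length(gt_boxes)) gt_boxes <- as_box_matrix(gt_boxes)
  m <- if (length(gt_boxes)) nrow(gt_boxes) else 0L
  areas <- if (m) box_area(gt_boxes) else numeric()
  levels <- vector("list", length(level_dims))
  n_pos <- 0L
  for (li in seq_along(level_dims)) {
    ld <- level_dims[[li]]
    loc <- generate_locations(ld$h, ld$w, ld$stride)
    n <- nrow(loc)
    labels <- integer(n)
    targets <- matrix(0, n, 4L)
    ctr <- numeric(n)
    gtix <- integer(n)
    if (m) {
      rng <- regress_ranges[[li]]
      best_area <- rep(Inf, n)
      for (g in seq_len(m)) {
        l <- loc[, 1L] - gt_boxes[g, 1L]; t <- loc[, 2L] - gt_boxes[g, 2L]
        r <- gt_boxes[g, 3L] - loc[, 1L]; b <- gt_boxes[g, 4L] - loc[, 2L]
        mn <- pmin(l, t, r, b); mx <- pmax(l, t, r, b)
        ok <- mn >= 0 & mx > rng[1L] & mx <= rng[2L] & areas[g] < best_area
        if (any(ok)) {
          best_area[ok] <- areas[g]
          labels[ok] <- 1L
          gtix[ok] <- g
          targets[ok, ] <- cbind(l, t, r, b)[ok, , drop = FALSE]
        }
      }
      pos <- labels == 1L
      if (any(pos)) ctr[pos] <- centerness(targets[pos, , drop = FALSE])
      n_pos <- n_pos + sum(pos)
    }
    levels[[li]] <- list(labels = labels, targets = targets, ctr_targets = ctr,
                         gt_index = gtix, locations = loc,
                         stride = ld$stride)
  }
  structure(list(levels = levels, n_pos_raw = n_pos, n_pos = max(n_pos, 1L)),
            class = "assignment")
}

# ---- losses -----------------------------------------------------------------

# focal loss sum over a logits node given 0/1 target vector (constant)
focal_loss_sum_ad <- function(logits, targets, alpha, gamma) {
  stopifnot(gamma == 2)  # (1-p)^gamma realised as a product; gamma = 2 fixed
  p <- ad_sigmoid(logits)
  omp <- ad_add_const(ad_scale(p, -1), 1)
  logp <- ad_log(p, eps = 1e-12)
  log1mp <- ad_log(omp, eps = 1e-12)
  pos <- ad_mul(ad_mul(omp, omp), logp)
  neg <- ad_mul(ad_mul(p, p), log1mp)
  ad_add(ad_dot_const(pos, -alpha * targets),
         ad_dot_const(neg, -(1 - alpha) * (1 - targets)))
}

bce_sum_ad <- function(logits, targets) {
  p <- ad_sigmoid(logits)
  omp <- ad_add_const(ad_scale(p, -1), 1)
  ad_add(ad_dot_const(ad_log(p, eps = 1e-12), -targets),
         ad_dot_const(ad_log(omp, eps = 1e-12), -(1 - targets)))
}

# IoU-family loss sum over positives; pred/tg are (k x 4) ltrb (node/const)
reg_loss_sum_ad <- function(pred, tg, cfg) {
  k <- nrow(tg)
  ones <- rep(1, k)
  cl <- function(j) ad_index_cols(pred, j)
  l <- cl(1L); t <- cl(2L); r <- cl(3L); b <- cl(4L)
  gl <- ad_leaf(tg[, 1L, drop = FALSE]); gt_ <- ad_leaf(tg[, 2L, drop = FALSE])
  gr <- ad_leaf(tg[, 3L, drop = FALSE]); gb <- ad_leaf(tg[, 4L, drop = FALSE])
  wp <- ad_add(l, r); hp <- ad_add(t, b)
  wg <- tg[, 1L] + tg[, 3L]; hg <- tg[, 2L] + tg[, 4L]
  # both boxes contain the location: intersection splits per side
  iw <- ad_add(ad_pmin(l, gl), ad_pmin(r, gr))
  ih <- ad_add(ad_pmin(t, gt_), ad_pmin(b, gb))
  inter <- ad_mul(iw, ih)
  area_p <- ad_mul(wp, hp)
  union <- ad_sub(ad_add_const(area_p, wg * hg), inter)
  iou <- ad_div(inter, union)
  loss_iou <- ad_add_const(ad_scale(iou, -1), 1)          # 1 - IoU per row
  if (cfg$reg_loss == "iou") return(ad_dot_const(loss_iou, ones))
  cw <- ad_add(ad_pmax(l, gl), ad_pmax(r, gr))            # enclosing box
  ch <- ad_add(ad_pmax(t, gt_), ad_pmax(b, gb))
  if (cfg$reg_loss == "giou") {
    carea <- ad_mul(cw, ch)
    giou <- ad_sub(iou, ad_div(ad_sub(carea, union), carea))
    return(ad_dot_const(ad_add_const(ad_scale(giou, -1), 1), ones))
  }
  # center offsets: (r - l) - (r* - l*) halved
  dx <- ad_scale(ad_sub(ad_sub(r, l), ad_leaf(matrix(tg[, 3L] - tg[, 1L]))), 0.5)
  dy <- ad_scale(ad_sub(ad_sub(b, t), ad_leaf(matrix(tg[, 4L] - tg[, 2L]))), 0.5)
  d2 <- ad_add(ad_mul(dx, dx), ad_mul(dy, dy))
  dar <- ad_sub(ad_atan(ad_div(wp, hp)), ad_leaf(matrix(atan(wg / hg))))
  v <- ad_scale(ad_mul(dar, dar), 4 / pi^2)
  if (cfg$reg_loss == "ciou") {
    c2 <- ad_add(ad_mul(cw, cw), ad_mul(ch, ch))
    # alpha treated as a constant during differentiation
    alpha_const <- {
      vv <- v$value; ii <- iou$value
      ifelse(vv > 0, vv / ((1 - ii) + vv), 0)
    }
    term <- ad_add(loss_iou, ad_div(d2, c2))
    return(ad_add(ad_dot_const(term, ones), ad_dot_const(v, alpha_const)))
  }
  # wiou: 1 - IoU + psi * ||centers||^2 (optionally /c^2)
  dist <- if (cfg$wiou_normalize) {
    ad_div(d2, ad_add(ad_mul(cw, cw), ad_mul(ch, ch)))
  } else d2
  ad_dot_const(ad_add(loss_iou, ad_mul(v, dist)), ones)
}

compute_losses_ad <- function(outputs, assignment, cfg) {
  n_pos <- assignment$n_pos
  cls_terms <- list(); k <- 0L
  ctr_logits <- list(); ctr_t <- list()
  pred_rows <- list(); tg_rows <- list()
  for (li in seq_along(outputs)) {
    o <- outputs[[li]]
    lv <- assignment$levels[[li]]
    cls_terms[[li]] <- focal_loss_sum_ad(o$cls, matrix(lv$labels, ncol = 1L),
                                         cfg$focal_alpha, cfg$focal_gamma)
    pos <- which(lv$labels == 1L)
    if (length(pos)) {
      ctr_logits[[length(ctr_logits) + 1L]] <- ad_gather_rows(o$ctr, pos)
      ctr_t[[length(ctr_t) + 1L]] <- lv$ctr_targets[pos]
      pred_rows[[length(pred_rows) + 1L]] <- ad_gather_rows(o$ltrb, pos)
      tg_rows[[length(tg_rows) + 1L]] <- lv$targets[pos, , drop = FALSE]
    }
  }
  l_cls <- Reduce(ad_add, cls_terms)
  if (length(ctr_logits)) {
    ctr_all <- if (length(ctr_logits) > 1L) {
      # stack level-wise positives row-wise via gather-free concat
      n_each <- vapply(ctr_logits, function(x) nrow(x$value), integer(1))
      stack_rows <- function(nodes) {
        # concat along rows using ad_concat_cols on transposes is wasteful;
        # emulate with successive gathers into one index space
        total <- sum(vapply(nodes, function(x) nrow(x$value), integer(1)))
        Reduce(ad_add, lapply(seq_along(nodes), function(i) {
          prev <- if (i == 1L) 0L else sum(n_each[seq_len(i - 1L)])
          idx <- integer(total)
          idx[(prev + 1L):(prev + n_each[i])] <- seq_len(n_each[i])
          ad_gather_rows(nodes[[i]], idx)
        }))
      }
      stack_rows(ctr_logits)
    } else ctr_logits[[1L]]
    l_ctr <- bce_sum_ad(ctr_all, unlist(ctr_t))
    pred_all <- if (length(pred_rows) > 1L) {
      n_each2 <- vapply(pred_rows, function(x) nrow(x$value), integer(1))
      total <- sum(n_each2)
      Reduce(ad_add, lapply(seq_along(pred_rows), function(i) {
        prev <- if (i == 1L) 0L else sum(n_each2[seq_len(i - 1L)])
        idx <- integer(total)
        idx[(prev + 1L):(prev + n_each2[i])] <- seq_len(n_each2[i])
        ad_gather_rows(pred_rows[[i]], idx)
      }))
    } else pred_rows[[1L]]
    l_reg <- reg_loss_sum_ad(pred_all, do.call(rbind, tg_rows), cfg)
  } else {
    l_ctr <- ad_leaf(0)
    l_reg <- ad_leaf(0)
  }
  l_cls_n <- ad_scale(l_cls, 1 / n_pos)
  l_ctr_n <- ad_scale(l_ctr, 1 / n_pos)
  l_reg_n <- ad_scale(l_reg, 1 / n_pos)
  total <- ad_add(l_cls_n,
                  ad_add(ad_scale(l_ctr_n, cfg$lambda1),
                         ad_scale(l_reg_n, cfg$lambda2)))
  list(total = total, l_cls = l_cls_n, l_ctr = l_ctr_n, l_reg = l_reg_n)
}

#' Compute the detection training loss
#'
#' Plain wrapper around the autodiff loss: focal classification loss over
#' all pyramid locations, binary cross-entropy center-ness loss over
#' positives, and the configured IoU-family regression loss over positives,
#' each normalised by the (clamped) positive count and combined with the
#' balance weights.
#'
#' @param outputs per-level head outputs (as from [model_forward()], plain
#'   matrices).
#' @param assignment an [assign_targets()] result for the same level dims.
#' @param cfg a [loss_config()].
#' @return list of class `"loss_breakdown"`: `total`, `l_cls`, `l_ctr`,
#'   `l_reg`, `n_pos`.
#' @export
compute_losses <- function(outputs, assignment, cfg = loss_config()) {
  ad_reset()
  nodes <- lapply(outputs, function(o)
    list(cls = ad_leaf(o$cls), ctr = ad_leaf(o$ctr), ltrb = ad_leaf(o$ltrb),
         h = o$h, w = o$w, stride = o$stride))
  ls <- compute_losses_ad(nodes, assignment, cfg)
  out <- list(total = as.numeric(ls$total$value),
              l_cls = as.numeric(ls$l_cls$value),
              l_ctr = as.numeric(ls$l_ctr$value),
              l_reg = as.numeric(ls$l_reg$value),
              n_pos = assignment$n_pos)
  ad_reset()
  class(out) <- "loss_breakdown"
  out
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss total %.4f = cls %.4f + ctr %.4f + reg %.4f (n_pos %d)\n",
              x$total, x$l_cls, x$l_ctr, x$l_reg, x$n_pos))
  invisible(x)
}

# ---- inference --------------------------------------------------------------

#' Greedy non-maximum suppression
#'
#' @param boxes n x 4 matrix.
#' @param scores length-n scores.
#' @param iou_thr suppression threshold.
#' @return integer indices of kept boxes, by descending score.
#' @export
nms <- function(boxes, scores, iou_thr = 0.6) {
  if (!length(scores)) return(integer())
  boxes <- as_box_matrix(boxes)
  o <- order(-scores)
  keep <- integer()
  while (length(o)) {
    i <- o[1L]
    keep <- c(keep, i)
    o <- o[-1L]
    if (!length(o)) break
    ious <- box_iou(boxes[rep(i, length(o)), , drop = FALSE],
                    boxes[o, , drop = FALSE])
    o <- o[ious <= iou_thr]
  }
  keep
}

#' Decode head outputs into scored detections
#'
#' Per-location score is `sigmoid(cls) * sigmoid(ctr)`; locations below the
#' score threshold are dropped, the top `pre_nms_top` per level survive to
#' decoding, boxes are clipped to the image, and class-wise NMS keeps at
#' most `max_det` detections.
#'
#' @param outputs per-level head outputs (plain, from [model_forward()]).
#' @param cfg a [loss_config()].
#' @param image_size `c(height, width)` for clipping (defaults to the
#'   padded size recorded on `outputs`).
#' @return data frame with `x0`, `y0`, `x1`, `y1`, `score`, `class_id`.
#' @export
detect <- function(outputs, cfg = loss_config(), image_size = NULL) {
  if (is.null(image_size)) {
    image_size <- c(attr(outputs, "padded_h"), attr(outputs, "padded_w"))
  }
  all_boxes <- matrix(numeric(), 0L, 4L)
  all_scores <- numeric(); all_cls <- integer()
  for (o in outputs) {
    loc <- generate_locations(o$h, o$w, o$stride)
    pc <- 1 / (1 + exp(-o$cls))
    pctr <- as.numeric(1 / (1 + exp(-o$ctr)))
    for (cl in seq_len(ncol(pc))) {
      sc <- pc[, cl] * pctr
      sel <- which(sc >= cfg$score_thr)
      if (!length(sel)) next
      if (length(sel) > cfg$pre_nms_top) {
        sel <- sel[order(-sc[sel])[seq_len(cfg$pre_nms_top)]]
      }
      bx <- decode_ltrb(loc[sel, , drop = FALSE], o$ltrb[sel, , drop = FALSE])
      bx[, c(1L, 3L)] <- pmin(pmax(bx[, c(1L, 3L)], 0), image_size[2L])
      bx[, c(2L, 4L)] <- pmin(pmax(bx[, c(2L, 4L)], 0), image_size[1L])
      ok <- bx[, 3L] > bx[, 1L] & bx[, 4L] > bx[, 2L]
      all_boxes <- rbind(all_boxes, bx[ok, , drop = FALSE])
      all_scores <- c(all_scores, sc[sel][ok])
      all_cls <- c(all_cls, rep(cl, sum(ok)))
    }
  }
  if (!length(all_scores)) {
    return(data.frame(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), score = numeric(), class_id = integer()))
  }
  keep <- integer()
  for (cl in unique(all_cls)) {
    ii <- which(all_cls == cl)
    keep <- c(keep, ii[nms(all_boxes[ii, , drop = FALSE], all_scores[ii],
                           cfg$nms_iou)])
  }
  keep <- keep[order(-all_scores[keep])]
  keep <- keep[seq_len(min(length(keep), cfg$max_det))]
  data.frame(x0 = all_boxes[keep, 1L], y0 = all_boxes[keep, 2L],
             x1 = all_boxes[keep, 3L], y1 = all_boxes[keep, 4L],
             score = all_scores[keep], class_id = all_cls[keep])
}
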