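# Independent oracles used across the suite. Each is written as plain,
# naive code (loops, enumeration, rasterization) so that it shares no
# structure with the package implementation it checks.

# -- fine-grid rasterization IoU ---------------------------------------------
raster_iou <- function(a, b, n = 1500L) {
  x0 <- min(a[1], b[1]); x1 <- max(a[3], b[3])
  y0 <- min(a[2], b[2]); y1 <- max(a[4], b[4])
  xs <- seq(x0, x1, length.out = n)
  ys <- seq(y0, y1, length.out = n)
  ina <- outer(ys, xs, function(y, x) x >= a[1] & x <= a[3] & y >= a[2] & y <= a[4])
  inb <- outer(ys, xs, function(y, x) x >= b[1] & x <= b[3] & y >= b[2] & y <= b[4])
  sum(ina & inb) / sum(ina | inb)
}

# -- dense attention oracle ---------------------------------------------------
# full-map multi-head attention for one branch, plain loops
dense_attention_oracle <- function(x, Wqkv, bqkv, head_dim) {
  C <- ncol(x)
  heads <- C / head_dim
  qkv <- sweep(x %*% Wqkv, 2, bqkv, `+`)
  out <- matrix(0, nrow(x), C)
  for (h in seq_len(heads)) {
    cols <- (h - 1) * head_dim + seq_len(head_dim)
    Q <- qkv[, cols, drop = FALSE]
    K <- qkv[, C + cols, drop = FALSE]
    V <- qkv[, 2 * C + cols, drop = FALSE]
    L <- Q %*% t(K) / sqrt(head_dim)
    L <- L - apply(L, 1, max)
    P <- exp(L) / rowSums(exp(L))
    out[, cols] <- P %*% V
  }
  out
}

# -- shifted-window per-token neighbourhood oracle ---------------------------
# recomputes every token's attention over its true shifted-window peer set
shifted_attention_oracle <- function(x, h, w, X, Wqkv, bqkv, bias_table,
                                     head_dim, s = X %/% 2) {
  C <- ncol(x)
  heads <- C / head_dim
  hp <- ceiling(h / X) * X; wp <- ceiling(w / X) * X
  rolled_pos <- function(r, c) c(((r - 1 - s) %% hp) + 1, ((c - 1 - s) %% wp) + 1)
  win_of <- function(p) c(ceiling(p[1] / X), ceiling(p[2] / X))
  band <- function(p, np) if (p > np - s) 3 else if (p > np - X) 2 else 1
  region <- function(p) (band(p[1], hp) - 1) * 3 + band(p[2], wp)
  relidx <- function(pi, pj) {
    dr <- ((pi[1] - 1) %% X) - ((pj[1] - 1) %% X)
    dc <- ((pi[2] - 1) %% X) - ((pj[2] - 1) %% X)
    (dr + X - 1) * (2 * X - 1) + (dc + X - 1) + 1
  }
  qkv <- sweep(x %*% Wqkv, 2, bqkv, `+`)
  tokrow <- function(r, c) (r - 1) * w + c
  out <- matrix(0, h * w, C)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    me_p <- rolled_pos(r, c); me_w <- win_of(me_p); me_id <- region(me_p)
    peers <- list()
    for (rr in seq_len(h)) for (cc in seq_len(w)) {
      pp <- rolled_pos(rr, cc)
      if (all(win_of(pp) == me_w) && region(pp) == me_id) {
        peers[[length(peers) + 1]] <- c(rr, cc, pp)
      }
    }
    for (hh in seq_len(heads)) {
      cols <- (hh - 1) * head_dim + seq_len(head_dim)
      q <- qkv[tokrow(r, c), cols]
      kk <- t(sapply(peers, function(p) qkv[tokrow(p[1], p[2]), C + cols]))
      vv <- t(sapply(peers, function(p) qkv[tokrow(p[1], p[2]), 2 * C + cols]))
      bvec <- sapply(peers, function(p) bias_table[relidx(me_p, p[3:4]), hh])
      lg <- as.numeric(kk %*% q) / sqrt(head_dim) + bvec
      pw <- exp(lg - max(lg)); pw <- pw / sum(pw)
      out[tokrow(r, c), cols] <- as.numeric(t(vv) %*% pw)
    }
  }
  out
}

# a one-branch variant spec for oracle comparisons
single_branch_spec <- function(C, head_dim, X) {
  structure(list(name = "custom", patch_size = 4L, channels = rep(C, 4),
                 depths = rep(2L, 4), head_dim = head_dim,
                 window_sizes = as.integer(X), mlp_ratio = 4L,
                 sr_mode = "identity"),
            class = "variant_spec")
}

# -- brute-force 101-point AP -------------------------------------------------
# direct scan: for each recall level take the best precision at or beyond it
ap_101_oracle <- function(tp_flags, n_gt) {
  if (n_gt == 0 || length(tp_flags) == 0) return(0)
  tp <- cumsum(tp_flags); fp <- cumsum(!tp_flags)
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    ok <- which(rec >= r)
    total <- total + if (length(ok)) max(prec[ok]) else 0
  }
  total / 101
}

# -- independent COCO evaluator ----------------------------------------------
# naive loop implementation of the COCO protocol for one category
oracle_coco_eval <- function(det, gt, iou_thr, area_rng = c(0, Inf),
                             max_det = 100L) {
  imgs <- sort(unique(c(det$image_id, gt$image_id)))
  all_scores <- c(); all_tp <- c(); all_ignore <- c()
  n_gt_count <- 0
  one_iou <- function(a, b) {
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  for (im in imgs) {
    d <- det[det$image_id == im, , drop = FALSE]
    g <- gt[gt$image_id == im, , drop = FALSE]
    if (nrow(d)) {
      d <- d[order(-d$score), , drop = FALSE]
      d <- d[seq_len(min(nrow(d), max_det)), , drop = FALSE]
    }
    g_area <- (g$x1 - g$x0) * (g$y1 - g$y0)
    g_ignore <- g_area < area_rng[1] | g_area > area_rng[2]
    n_gt_count <- n_gt_count + sum(!g_ignore)
    g_order <- order(g_ignore)
    g_used <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(d))) {
      best <- iou_thr - 1e-10; match <- 0
      for (j in g_order) {
        if (g_used[j]) next
        if (match > 0 && !g_ignore[match] && g_ignore[j]) break
        iou <- one_iou(as.numeric(d[i, c("x0", "y0", "x1", "y1")]),
                       as.numeric(g[j, c("x0", "y0", "x1", "y1")]))
        if (iou < best) next
        best <- iou; match <- j
      }
      ig <- FALSE
      if (match > 0) {
        g_used[match] <- TRUE
        ig <- g_ignore[match]
      } else {
        d_area <- (d$x1[i] - d$x0[i]) * (d$y1[i] - d$y0[i])
        ig <- d_area < area_rng[1] | d_area > area_rng[2]
      }
      all_scores <- c(all_scores, d$score[i])
      all_tp <- c(all_tp, match > 0 && !ig)
      all_ignore <- c(all_ignore, ig)
    }
  }
  if (n_gt_count == 0) return(list(ap = 0, n_gt = 0))
  o <- order(-all_scores)
  keep <- !all_ignore[o]
  flags <- all_tp[o][keep]
  list(ap = ap_101_oracle(flags, n_gt_count), n_gt = n_gt_count)
}

oracle_coco_summary <- function(det, gt) {
  thrs <- seq(0.5, 0.95, by = 0.05)
  ap_all <- sapply(thrs, function(t) oracle_coco_eval(det, gt, t)$ap)
  ap_m <- sapply(thrs, function(t)
    oracle_coco_eval(det, gt, t, area_rng = c(32^2, 96^2))$ap)
  ap_l <- sapply(thrs, function(t)
    oracle_coco_eval(det, gt, t, area_rng = c(96^2, Inf))$ap)
  list(mAP = mean(ap_all), AP50 = ap_all[1], AP75 = ap_all[6],
       APm = mean(ap_m), APl = mean(ap_l))
}

# -- randomized toy detection datasets ---------------------------------------
make_toy_dataset <- function(seed) {
  set.seed(seed)
  n_img <- sample(3:8, 1)
  gt <- list(); det <- list()
  for (im in seq_len(n_img)) {
    ng <- sample(0:12, 1)
    if (ng) {
      x0 <- runif(ng, 0, 400); y0 <- runif(ng, 0, 400)
      w <- runif(ng, 10, 150); h <- runif(ng, 10, 150)
      gt[[length(gt) + 1]] <- data.frame(image_id = im, x0 = x0, y0 = y0,
                                         x1 = x0 + w, y1 = y0 + h)
    }
    nd <- sample(0:15, 1)
    if (nd) {
      x0 <- runif(nd, 0, 400); y0 <- runif(nd, 0, 400)
      w <- runif(nd, 8, 160); h <- runif(nd, 8, 160)
      det[[length(det) + 1]] <- data.frame(image_id = im, x0 = x0, y0 = y0,
                                           x1 = x0 + w, y1 = y0 + h,
                                           score = round(runif(nd), 3))
    }
  }
  g <- do.call(rbind, gt)
  jit <- g[sample(nrow(g), min(nrow(g), 10)), ]
  jit$x0 <- jit$x0 + rnorm(nrow(jit), 0, 4)
  jit$y0 <- jit$y0 + rnorm(nrow(jit), 0, 4)
  jit$x1 <- jit$x1 + rnorm(nrow(jit), 0, 4)
  jit$y1 <- jit$y1 + rnorm(nrow(jit), 0, 4)
  jit$score <- round(runif(nrow(jit), 0.5, 1), 3)
  list(gt = g, det = rbind(do.call(rbind, det), jit))
}

# -- random boxes / box pairs -------------------------------------------------
random_box <- function(lim = 100) {
  x0 <- runif(1, 0, lim); y0 <- runif(1, 0, lim)
  c(x0, y0, x0 + runif(1, 0.5, lim / 2), y0 + runif(1, 0.5, lim / 2))
}
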