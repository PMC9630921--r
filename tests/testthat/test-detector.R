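make_tiny_model <- function(seed = 1L) init_spike_model("tiny", seed = seed)

test_that("feature pyramid has the right shapes and channels", {
  model <- make_tiny_model(61)
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  feats <- backbone_forward(img, model$backbone)$features
  pyr <- build_pyramid(feats, model$detector)
  expect_equal(sapply(pyr, function(p) p$h), c(16, 8, 4, 2, 1))
  expect_equal(sapply(pyr, function(p) p$stride), c(8, 16, 32, 64, 128))
  expect_true(all(sapply(pyr, function(p) ncol(p$x)) == 32))
  # zero inputs with zero weights -> zero pyramid
  det0 <- nested_zero <- rapply(unclass(model$detector), function(x) x * 0,
                                how = "replace")
  attributes(det0) <- attributes(model$detector)
  featz <- lapply(feats, function(f) list(x = f$x * 0, h = f$h, w = f$w))
  pyr0 <- build_pyramid(featz, det0)
  expect_true(all(sapply(pyr0, function(p) max(abs(p$x))) == 0))
})

test_that("locations are cell centers mapped back to the image", {
  loc <- generate_locations(2L, 3L, 8)
  expect_equal(nrow(loc), 6L)
  expect_equal(unname(loc[1, ]), c(4, 4))
  expect_equal(unname(loc[2, ]), c(12, 4))
  expect_equal(unname(loc[4, ]), c(4, 12))
  # strictly inside the padded image
  loc2 <- generate_locations(16L, 16L, 8)
  expect_true(all(loc2 > 0 & loc2 < 128))
})

test_that("assignment: membership, ranges, min-area tie-break", {
  dims <- list(list(h = 16L, w = 16L, stride = 8L),
               list(h = 8L, w = 8L, stride = 16L))
  rngs <- default_regress_ranges()[1:2]
  # a location at a box center is positive with centerness 1
  gt <- rbind(c(26, 26, 30, 30))      # contains only the location (28,28)
  a <- assign_targets(dims, gt, rngs)
  lv <- a$levels[[1]]
  crow <- which(lv$locations[, 1] == 28 & lv$locations[, 2] == 28)
  expect_equal(lv$labels[crow], 1L)
  expect_equal(lv$ctr_targets[crow], 1)
  # locations outside every box are negative
  expect_equal(sum(lv$labels), 1L)    # only the containing cell is positive
  # nested boxes: the smaller wins
  gt2 <- rbind(c(0, 0, 48, 48), c(16, 16, 40, 40))
  a2 <- assign_targets(dims, gt2, rngs)
  lv2 <- a2$levels[[1]]
  inner <- which(lv2$locations[, 1] == 28 & lv2$locations[, 2] == 28)
  expect_equal(lv2$gt_index[inner], 2L)
  # empty gt: all negative, n_pos clamped to 1
  a3 <- assign_targets(dims, matrix(numeric(), 0, 4), rngs)
  expect_equal(a3$n_pos_raw, 0L)
  expect_equal(a3$n_pos, 1L)
  expect_true(all(a3$levels[[1]]$labels == 0))
})

test_that("whole-image gt: positives equal the enumeration oracle", {
  dims <- lapply(list(c(16, 16, 8), c(8, 8, 16), c(4, 4, 32), c(2, 2, 64),
                      c(1, 1, 128)),
                 function(v) list(h = v[1], w = v[2], stride = v[3]))
  gt <- rbind(c(0, 0, 128, 128))
  a <- assign_targets(dims, gt)
  rngs <- default_regress_ranges()
  expected <- 0L
  for (li in 1:5) {
    loc <- generate_locations(dims[[li]]$h, dims[[li]]$w, dims[[li]]$stride)
    for (i in seq_len(nrow(loc))) {
      l <- loc[i, 1]; t <- loc[i, 2]; r <- 128 - loc[i, 1]; b <- 128 - loc[i, 2]
      mx <- max(l, t, r, b)
      if (min(l, t, r, b) >= 0 && mx > rngs[[li]][1] && mx <= rngs[[li]][2]) {
        expected <- expected + 1L
      }
    }
  }
  expect_equal(a$n_pos_raw, expected)
  expect_gt(expected, 0L)
})

test_that("losses match a hand-computed two-location toy", {
  # one level, 1x2 grid at stride 8: locations (4,4) and (12,4)
  gt <- rbind(c(0, 0, 8, 8))
  dims <- list(list(h = 1L, w = 2L, stride = 8L))
  a <- assign_targets(dims, gt, list(c(0, 64)))
  expect_equal(a$levels[[1]]$labels, c(1L, 0L))
  expect_equal(a$n_pos, 1L)
  cls <- matrix(c(0.7, -0.4), 2, 1)
  ctr <- matrix(c(0.2, 0.1), 2, 1)
  ltrb <- rbind(c(3, 5, 2, 6), c(1, 1, 1, 1))
  outs <- list(list(cls = cls, ctr = ctr, ltrb = ltrb, h = 1L, w = 2L,
                    stride = 8L))
  lb <- compute_losses(outs, a, loss_config("wiou"))
  # scalar recomputation (independent arithmetic)
  sig <- function(x) 1 / (1 + exp(-x))
  p1 <- sig(0.7); p2 <- sig(-0.4)
  l_cls <- -0.25 * (1 - p1)^2 * log(p1) - 0.75 * p2^2 * log(1 - p2)
  # centerness target at (4,4) in (0,0,8,8) is 1
  l_ctr <- -log(sig(0.2))
  # decoded pred box (1,-1,6,10) vs gt (0,0,8,8)
  iw <- min(3, 4) + min(2, 4); ih <- min(5, 4) + min(6, 4)
  ap <- (3 + 2) * (5 + 6); ag <- 64
  inter <- iw * ih; iou <- inter / (ap + ag - inter)
  psi <- 4 / pi^2 * (atan(8 / 8) - atan(5 / 11))^2
  d2 <- ((2 - 3) / 2 - 0)^2 + ((6 - 5) / 2 - 0)^2
  l_reg <- 1 - iou + psi * d2
  expect_equal(lb$l_cls, l_cls, tolerance = 1e-10)
  expect_equal(lb$l_ctr, l_ctr, tolerance = 1e-10)
  expect_equal(lb$l_reg, l_reg, tolerance = 1e-10)
  expect_equal(lb$total, l_cls + l_ctr + l_reg, tolerance = 1e-10)
})

test_that("perfect predictions zero the regression loss; loss family only
           changes l_reg; equal aspect ratios make iou and wiou agree", {
  gt <- rbind(c(0, 0, 8, 8))
  dims <- list(list(h = 1L, w = 2L, stride = 8L))
  a <- assign_targets(dims, gt, list(c(0, 64)))
  perfect <- list(list(cls = matrix(c(20, -20), 2, 1),
                       ctr = matrix(c(20, 0), 2, 1),
                       ltrb = rbind(c(4, 4, 4, 4), c(1, 1, 1, 1)),
                       h = 1L, w = 2L, stride = 8L))
  lb <- compute_losses(perfect, a, loss_config("wiou"))
  expect_equal(lb$l_reg, 0, tolerance = 1e-12)
  expect_lt(lb$total, 1e-6)

  set.seed(62)
  # partial overlap (neither box contains the other) so every family differs
  rnd <- list(list(cls = matrix(rnorm(2), 2, 1), ctr = matrix(rnorm(2), 2, 1),
                   ltrb = rbind(c(2, 6, 1, 7), c(1, 1, 1, 1)),
                   h = 1L, w = 2L, stride = 8L))
  per <- lapply(c("iou", "giou", "ciou", "wiou"), function(v)
    compute_losses(rnd, a, loss_config(v)))
  for (i in 2:4) {
    expect_equal(per[[i]]$l_cls, per[[1]]$l_cls)
    expect_equal(per[[i]]$l_ctr, per[[1]]$l_ctr)
  }
  expect_false(isTRUE(all.equal(per[[1]]$l_reg, per[[2]]$l_reg)))
  # equal aspect ratio: pred ltrb symmetric square vs square gt
  sq <- list(list(cls = rnd[[1]]$cls, ctr = rnd[[1]]$ctr,
                  ltrb = rbind(c(2, 2, 2, 2), c(1, 1, 1, 1)),
                  h = 1L, w = 2L, stride = 8L))
  li <- compute_losses(sq, a, loss_config("iou"))
  lw <- compute_losses(sq, a, loss_config("wiou"))
  expect_equal(li$l_reg, lw$l_reg, tolerance = 1e-12)
})

test_that("loss is finite with gradients matching finite differences", {
  set.seed(63)
  gt <- rbind(c(2, 2, 30, 40), c(50, 10, 90, 60))
  dims <- list(list(h = 4L, w = 4L, stride = 8L),
               list(h = 2L, w = 2L, stride = 16L))
  a <- assign_targets(dims, gt, default_regress_ranges()[1:2])
  mk <- function() list(
    list(cls = matrix(rnorm(16), 16, 1), ctr = matrix(rnorm(16), 16, 1),
         ltrb = matrix(runif(64, 2, 40), 16, 4), h = 4L, w = 4L, stride = 8L),
    list(cls = matrix(rnorm(4), 4, 1), ctr = matrix(rnorm(4), 4, 1),
         ltrb = matrix(runif(16, 2, 60), 4, 4), h = 2L, w = 2L, stride = 16L))
  outs <- mk()
  cfg <- loss_config("wiou")
  lb <- compute_losses(outs, a, cfg)
  expect_true(is.finite(lb$total) && lb$total >= 0)

  fwd <- function(o) {
    ad_reset()
    nodes <- lapply(o, function(x)
      list(cls = ad_leaf(x$cls), ctr = ad_leaf(x$ctr), ltrb = ad_leaf(x$ltrb),
           h = x$h, w = x$w, stride = x$stride))
    ls <- spikeformer:::compute_losses_ad(nodes, a, cfg)
    list(loss = ls$total, nodes = nodes)
  }
  r <- fwd(outs)
  ad_backward(r$loss)
  eps <- 1e-6
  for (fld in c("cls", "ctr", "ltrb")) {
    g <- r$nodes[[1]][[fld]]$grad
    for (i in sample(length(outs[[1]][[fld]]), 3)) {
      op <- outs; op[[1]][[fld]][i] <- op[[1]][[fld]][i] + eps
      om <- outs; om[[1]][[fld]][i] <- om[[1]][[fld]][i] - eps
      gn <- (fwd(op)$loss$value - fwd(om)$loss$value) / (2 * eps)
      expect_lt(abs(g[i] - gn), 1e-5)
    }
  }
  ad_reset()
})

test_that("nms keeps the highest-scored of overlapping duplicates", {
  boxes <- rbind(c(0, 0, 10, 10), c(1, 1, 11, 11), c(50, 50, 60, 60))
  keep <- nms(boxes, c(0.9, 0.8, 0.7), iou_thr = 0.5)
  expect_equal(keep, c(1L, 3L))
  expect_equal(nms(matrix(numeric(), 0, 4), numeric()), integer())
})

test_that("detect decodes, thresholds, clips and suppresses", {
  # all scores below threshold -> nothing
  outs <- list(list(cls = matrix(-50, 4, 1), ctr = matrix(0, 4, 1),
                    ltrb = matrix(5, 4, 4), h = 2L, w = 2L, stride = 8L))
  attr(outs, "padded_h") <- 16L; attr(outs, "padded_w") <- 16L
  expect_equal(nrow(detect(outs)), 0L)
  # one dominant location -> exactly one detection with the decoded box
  cls <- matrix(-50, 4, 1); cls[1] <- 5
  outs2 <- list(list(cls = cls, ctr = matrix(5, 4, 1),
                     ltrb = rbind(c(2, 3, 4, 5), matrix(1, 3, 4)),
                     h = 2L, w = 2L, stride = 8L))
  attr(outs2, "padded_h") <- 16L; attr(outs2, "padded_w") <- 16L
  d <- detect(outs2)
  expect_equal(nrow(d), 1L)
  expect_equal(unname(as.numeric(d[1, 1:4])), c(4 - 2, 4 - 3, 4 + 4, 4 + 5))
  # duplicate high-IoU boxes collapse to the higher score
  # loc (4,4) -> (1,1,13,13); loc (12,4) -> (1.1,0.9,13.1,12.9)
  cls3 <- matrix(c(4, 3.9, -50, -50), 4, 1)
  outs3 <- list(list(cls = cls3, ctr = matrix(5, 4, 1),
                     ltrb = rbind(c(3, 3, 9, 9), c(10.9, 3.1, 1.1, 8.9),
                                  c(1, 1, 1, 1), c(1, 1, 1, 1)),
                     h = 2L, w = 2L, stride = 8L))
  attr(outs3, "padded_h") <- 16L; attr(outs3, "padded_w") <- 16L
  d3 <- detect(outs3)
  expect_equal(nrow(d3), 1L)
  expect_equal(d3$score[1], 1 / (1 + exp(-4)) * 1 / (1 + exp(-5)),
               tolerance = 1e-10)
})

test_that("checkpoint save/load roundtrips the model", {
  model <- make_tiny_model(64)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_identical(back$spec$name, "tiny")
  expect_identical(back$backbone, model$backbone)
  saveRDS(list(1), f)
  expect_error(load_checkpoint(f), "not a spike_model")
})
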