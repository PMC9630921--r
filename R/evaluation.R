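#' @title COCO-convention detection metrics
#'
#' @description
#' Precision/recall counting (`precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`), greedy IoU matching, 101-point-interpolated
#' average precision, and the COCO summary metrics mAP (IoU thresholds
#' 0.5:0.05:0.95), AP50, AP75 and the area-restricted APm / APl.
#'
#' Detections are data frames with columns `image_id`, `x0`, `y0`, `x1`,
#' `y1`, `score`; ground truth the same without `score`. A single foreground
#' class is assumed (the spike); ties in score are broken by insertion order,
#' deterministically.
#'
#' @name evaluation
NULL

coco_iou_thresholds <- function() seq(0.5, 0.95, by = 0.05)
coco_recall_grid <- function() seq(0, 1, by = 0.01)

# COCO object-area ranges (areas of ground-truth boxes, w*h in pixels^2).
coco_area_ranges <- function() {
  list(all = c(0, Inf), small = c(0, 32^2), medium = c(32^2, 96^2),
       large = c(96^2, Inf))
}

empty_det_frame <- function() {
  data.frame(image_id = integer(), x0 = numeric(), y0 = numeric(),
             x1 = numeric(), y1 = numeric(), score = numeric())
}

#' Greedy matching of detections to ground truth at one IoU threshold
#'
#' Detections (already sorted by descending score) are matched greedily: each
#' detection takes the unmatched ground-truth box of highest IoU among those
#' with IoU at or above the threshold; every ground-truth box can be matched
#' at most once. Ground-truth boxes flagged `ignore` never count as TP/FN;
#' detections matched to them (only possible when no countable box is
#' available) are excluded from TP/FP as in the COCO protocol.
#'
#' @param det n x 4 matrix of detection boxes, sorted by descending score.
#' @param gt m x 4 matrix of ground-truth boxes.
#' @param iou_thr IoU threshold in (0, 1].
#' @param gt_ignore logical vector of length m (default all `FALSE`).
#' @param det_ignore logical vector of length n: detections to exclude from
#'   TP/FP when unmatched (area-range filtering); default all `FALSE`.
#' @return list with `tp`, `fp`, `fn` counts, logical `tp_flags` and
#'   `ignore_flags` per detection (in the given order), and the matched gt
#'   index per detection (`match`, 0 when unmatched).
#' @export
match_at_threshold <- function(det, gt, iou_thr, gt_ignore = NULL,
                               det_ignore = NULL) {
  det <- if (length(det)) as_box_matrix(det) else matrix(numeric(), 0L, 4L)
  gt <- if (length(gt)) as_box_matrix(gt) else matrix(numeric(), 0L, 4L)
  nd <- nrow(det); ng <- nrow(gt)
  if (is.null(gt_ignore)) gt_ignore <- rep(FALSE, ng)
  if (is.null(det_ignore)) det_ignore <- rep(FALSE, nd)
  # countable gts first, stable within each group (COCO gt ordering)
  gt_order <- order(gt_ignore)
  iou <- if (nd && ng) box_iou_matrix(det, gt) else matrix(0, nd, ng)
  gt_matched <- integer(ng)
  det_match <- integer(nd)
  det_ig <- logical(nd)
  for (d in seq_len(nd)) {
    best <- iou_thr - 1e-10
    m <- 0L
    for (g in gt_order) {
      if (gt_matched[g] > 0L) next
      # once a countable match is held, stop when reaching ignored gts
      if (m > 0L && !gt_ignore[m] && gt_ignore[g]) break
      if (iou[d, g] < best) next
      best <- iou[d, g]
      m <- g
    }
    if (m == 0L) next
    det_match[d] <- m
    det_ig[d] <- gt_ignore[m]
    gt_matched[m] <- d
  }
  det_ig <- det_ig | (det_match == 0L & det_ignore)
  tp_flags <- det_match > 0L & !det_ig
  fp_flags <- det_match == 0L & !det_ig
  n_gt_countable <- sum(!gt_ignore)
  list(tp = sum(tp_flags), fp = sum(fp_flags),
       fn = n_gt_countable - sum(tp_flags),
       tp_flags = tp_flags, ignore_flags = det_ig, match = det_match)
}

#' Cumulative precision-recall curve
#'
#' Given per-detection TP/FP flags in descending-score order and the number
#' of ground-truth boxes, returns cumulative precision and recall at every
#' rank.
#'
#' @param tp_flags logical vector, `TRUE` for TP, in score order.
#' @param n_gt number of ground-truth boxes.
#' @return data frame with columns `recall`, `precision` (empty when
#'   `n_gt == 0` or there are no detections).
#' @export
precision_recall_curve <- function(tp_flags, n_gt) {
  if (n_gt == 0L || length(tp_flags) == 0L) {
    return(data.frame(recall = numeric(), precision = numeric()))
  }
  tp <- cumsum(tp_flags)
  fp <- cumsum(!tp_flags)
  data.frame(recall = tp / n_gt, precision = tp / (tp + fp))
}

#' 101-point interpolated average precision
#'
#' COCO convention: precision is first made monotone non-increasing in
#' recall, then sampled at the 101 recall values 0, 0.01, ..., 1 (0 where the
#' recall level is never reached); AP is the mean of the samples.
#'
#' @param curve data frame from [precision_recall_curve()].
#' @return a single number in `[0, 1]`; 0 for an empty curve.
#' @export
average_precision <- function(curve) {
  if (nrow(curve) == 0L) return(0)
  rc <- curve$recall
  pr <- curve$precision
  # monotone envelope from the right
  pr <- rev(cummax(rev(pr)))
  grid <- coco_recall_grid()
  idx <- findInterval(grid, rc, left.open = TRUE) + 1L  # first rc >= grid
  q <- ifelse(idx <= length(rc), pr[pmin(idx, length(rc))], 0)
  mean(q)
}

# One category, one area range, all images: flags over thresholds.
# Returns AP per IoU threshold.
eval_area_range <- function(det, gt, area_rng, max_det = 100L) {
  thrs <- coco_iou_thresholds()
  ids <- sort(unique(c(det$image_id, gt$image_id)))
  # per-image trimming to max_det, by descending score (stable)
  per_img <- lapply(ids, function(id) {
    d <- det[det$image_id == id, , drop = FALSE]
    if (nrow(d)) {
      o <- order(-d$score)
      d <- d[o, , drop = FALSE][seq_len(min(nrow(d), max_det)), , drop = FALSE]
    }
    g <- gt[gt$image_id == id, , drop = FALSE]
    g_area <- if (nrow(g)) box_area(as.matrix(g[, c("x0", "y0", "x1", "y1")])) else numeric()
    g_ig <- g_area < area_rng[1L] | g_area > area_rng[2L]
    d_area <- if (nrow(d)) box_area(as.matrix(d[, c("x0", "y0", "x1", "y1")])) else numeric()
    d_ig0 <- d_area < area_rng[1L] | d_area > area_rng[2L]
    list(det = d, gt = g, gt_ig = g_ig, det_ig0 = d_ig0)
  })
  n_gt <- sum(vapply(per_img, function(p) sum(!p$gt_ig), numeric(1)))
  ap <- numeric(length(thrs))
  curves <- vector("list", length(thrs))
  for (k in seq_along(thrs)) {
    flags <- list(); igs <- list(); scores <- list()
    for (p in per_img) {
      if (nrow(p$det) == 0L) next
      mm <- match_at_threshold(as.matrix(p$det[, c("x0", "y0", "x1", "y1")]),
                               if (nrow(p$gt)) as.matrix(p$gt[, c("x0", "y0", "x1", "y1")]) else NULL,
                               thrs[k], gt_ignore = p$gt_ig, det_ignore = p$det_ig0)
      flags[[length(flags) + 1L]] <- mm$tp_flags
      igs[[length(igs) + 1L]] <- mm$ignore_flags
      scores[[length(scores) + 1L]] <- p$det$score
    }
    flags <- unlist(flags); igs <- unlist(igs); scores <- unlist(scores)
    if (is.null(flags) || n_gt == 0L) { ap[k] <- 0; next }
    o <- order(-scores)  # stable: per-image insertion order breaks ties
    keep <- !igs[o]
    curve <- precision_recall_curve(flags[o][keep], n_gt)
    curves[[k]] <- curve
    ap[k] <- average_precision(curve)
  }
  list(ap = ap, n_gt = n_gt, curves = curves)
}

#' COCO-style metric summary
#'
#' Computes mAP (mean AP over IoU thresholds 0.5 to 0.95 in steps of 0.05),
#' AP50, AP75, and the area-restricted APm (ground-truth area in
#' `[32^2, 96^2]`) and APl (area above `96^2`), with at most 100 detections
#' per image. APs (small objects) is available behind `include_small`.
#'
#' @param detections data frame with columns `image_id`, `x0`, `y0`, `x1`,
#'   `y1`, `score`.
#' @param ground_truth data frame with columns `image_id`, `x0`, `y0`, `x1`,
#'   `y1`.
#' @param include_small also report APs for areas below `32^2`.
#' @param max_det per-image detection cap (COCO uses 100).
#' @return list of class `"coco_metrics"` with entries `mAP`, `AP50`,
#'   `AP75`, `APm`, `APl` (and `APs` when requested), plus `pr_curves`, the
#'   all-areas precision-recall curves indexed by IoU threshold.
#' @export
coco_summary <- function(detections, ground_truth, include_small = FALSE,
                         max_det = 100L) {
  if (is.null(detections) || nrow(detections) == 0L) detections <- empty_det_frame()
  if (nrow(ground_truth) == 0L) {
    warning("empty ground-truth set: metrics undefined, reported as 0")
    out <- list(mAP = 0, AP50 = 0, AP75 = 0, APm = 0, APl = 0,
                pr_curves = list())
    class(out) <- "coco_metrics"
    return(out)
  }
  rngs <- coco_area_ranges()
  all_res <- eval_area_range(detections, ground_truth, rngs$all, max_det)
  med_res <- eval_area_range(detections, ground_truth, rngs$medium, max_det)
  lrg_res <- eval_area_range(detections, ground_truth, rngs$large, max_det)
  thrs <- coco_iou_thresholds()
  ap_mean <- function(res) if (res$n_gt == 0L) NA_real_ else mean(res$ap)
  out <- list(
    mAP = mean(all_res$ap),
    AP50 = all_res$ap[which(abs(thrs - 0.5) < 1e-9)],
    AP75 = all_res$ap[which(abs(thrs - 0.75) < 1e-9)],
    APm = ap_mean(med_res),
    APl = ap_mean(lrg_res),
    pr_curves = stats::setNames(all_res$curves, sprintf("iou%.2f", thrs))
  )
  if (include_small) {
    sml_res <- eval_area_range(detections, ground_truth, rngs$small, max_det)
    out$APs <- ap_mean(sml_res)
  }
  class(out) <- "coco_metrics"
  out
}

#' @export
print.coco_metrics <- function(x, ...) {
  cat("COCO-style detection metrics\n")
  for (nm in c("mAP", "AP50", "AP75", "APm", "APl", "APs")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %-5s %.4f\n", nm, x[[nm]]))
  }
  invisible(x)
}
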