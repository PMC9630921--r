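#' @title Axis-aligned box arithmetic and IoU-family losses
#'
#' @description
#' Boxes are continuous axis-aligned rectangles `c(x0, y0, x1, y1)` with the
#' origin at the top-left corner, x growing rightward and y growing downward.
#' Area is `(x1 - x0) * (y1 - y0)`; there is no +1 pixel correction. All
#' functions below are vectorised: a single box may be a length-4 numeric
#' vector, and a set of boxes an n x 4 matrix (one box per row).
#'
#' @name box_geometry
NULL

# Coerce vector/matrix input to an n x 4 matrix.
as_box_matrix <- function(b) {
  if (is.null(dim(b))) {
    if (length(b) != 4L) stop("a box must have 4 coordinates (x0, y0, x1, y1)")
    b <- matrix(as.numeric(b), nrow = 1L)
  }
  b <- as.matrix(b)
  if (ncol(b) != 4L) stop("box matrix must have 4 columns (x0, y0, x1, y1)")
  storage.mode(b) <- "double"
  b
}

check_positive_area <- function(b, what = "box") {
  bad <- b[, 3L] <= b[, 1L] | b[, 4L] <= b[, 2L]
  if (any(bad)) {
    stop(sprintf("degenerate %s (non-positive width or height) at row %d",
                 what, which(bad)[1L]))
  }
  invisible(TRUE)
}

#' Box helpers
#'
#' `box_area()`, `box_center()`, `box_wh()` compute derived quantities of
#' axis-aligned boxes; `boxes_from_xywh()` / `boxes_to_xywh()` convert between
#' the corner convention used internally and the `(x, y, w, h)` annotation
#' vector (upper-left corner plus width/height) used by the annotation
#' formats.
#'
#' @param boxes length-4 vector or n x 4 matrix of `(x0, y0, x1, y1)` boxes.
#' @param xywh length-4 vector or n x 4 matrix of `(x, y, w, h)` rows.
#' @return `box_area()` a numeric vector of areas; `box_center()` an n x 2
#'   matrix of centers; `box_wh()` an n x 2 matrix of widths/heights;
#'   the converters an n x 4 matrix.
#' @export
box_area <- function(boxes) {
  b <- as_box_matrix(boxes)
  (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
}

#' @rdname box_area
#' @export
box_center <- function(boxes) {
  b <- as_box_matrix(boxes)
  cbind(x = (b[, 1L] + b[, 3L]) / 2, y = (b[, 2L] + b[, 4L]) / 2)
}

#' @rdname box_area
#' @export
box_wh <- function(boxes) {
  b <- as_box_matrix(boxes)
  cbind(w = b[, 3L] - b[, 1L], h = b[, 4L] - b[, 2L])
}

#' @rdname box_area
#' @export
boxes_from_xywh <- function(xywh) {
  m <- as_box_matrix(xywh)  # same shape requirements
  cbind(x0 = m[, 1L], y0 = m[, 2L], x1 = m[, 1L] + m[, 3L], y1 = m[, 2L] + m[, 4L])
}

#' @rdname box_area
#' @export
boxes_to_xywh <- function(boxes) {
  b <- as_box_matrix(boxes)
  cbind(x = b[, 1L], y = b[, 2L], w = b[, 3L] - b[, 1L], h = b[, 4L] - b[, 2L])
}

intersect_area <- function(a, b) {
  iw <- pmax(0, pmin(a[, 3L], b[, 3L]) - pmax(a[, 1L], b[, 1L]))
  ih <- pmax(0, pmin(a[, 4L], b[, 4L]) - pmax(a[, 2L], b[, 2L]))
  iw * ih
}

recycle_pair <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("box sets must have equal length (or one of them length 1)")
  list(a = a, b = b)
}

#' Intersection over union of paired boxes
#'
#' @param a,b boxes (length-4 vectors or n x 4 matrices, paired row-wise; one
#'   argument may be a single box which is recycled).
#' @return numeric vector of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  p <- recycle_pair(a, b)
  check_positive_area(p$a); check_positive_area(p$b)
  inter <- intersect_area(p$a, p$b)
  inter / (box_area(p$a) + box_area(p$b) - inter)
}

#' Cross IoU matrix between two box sets
#'
#' @param a n x 4 box matrix.
#' @param b m x 4 box matrix.
#' @return n x m matrix of pairwise IoU values.
#' @export
box_iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  x0 <- outer(a[, 1L], b[, 1L], pmax); y0 <- outer(a[, 2L], b[, 2L], pmax)
  x1 <- outer(a[, 3L], b[, 3L], pmin); y1 <- outer(a[, 4L], b[, 4L], pmin)
  inter <- pmax(0, x1 - x0) * pmax(0, y1 - y0)
  inter / (outer(box_area(a), box_area(b), `+`) - inter)
}

#' Generalized IoU of paired boxes
#'
#' IoU minus the fraction of the smallest enclosing box not covered by the
#' union: `GIoU = IoU - |C \ (A U B)| / |C|`, in `[-1, 1]`.
#'
#' @inheritParams box_iou
#' @return numeric vector of GIoU values.
#' @export
box_giou <- function(a, b) {
  p <- recycle_pair(a, b)
  check_positive_area(p$a); check_positive_area(p$b)
  inter <- intersect_area(p$a, p$b)
  union <- box_area(p$a) + box_area(p$b) - inter
  cw <- pmax(p$a[, 3L], p$b[, 3L]) - pmin(p$a[, 1L], p$b[, 1L])
  ch <- pmax(p$a[, 4L], p$b[, 4L]) - pmin(p$a[, 2L], p$b[, 2L])
  carea <- cw * ch
  inter / union - (carea - union) / carea
}

#' Aspect-ratio consistency penalty
#'
#' `psi = 4 / pi^2 * (atan(w_gt / h_gt) - atan(w_pr / h_pr))^2`, a value in
#' `[0, 1]` that is zero exactly when the two aspect ratios agree and
#' approaches 1 as one ratio collapses while the other explodes. Symmetric in
#' its arguments.
#'
#' @param pred,gt predicted and ground-truth boxes (paired, recycled as in
#'   [box_iou()]).
#' @return numeric vector of penalties in `[0, 1]`.
#' @export
aspect_penalty <- function(pred, gt) {
  p <- recycle_pair(pred, gt)
  check_positive_area(p$a, "pred"); check_positive_area(p$b, "gt")
  wp <- p$a[, 3L] - p$a[, 1L]; hp <- p$a[, 4L] - p$a[, 2L]
  wg <- p$b[, 3L] - p$b[, 1L]; hg <- p$b[, 4L] - p$b[, 2L]
  (4 / pi^2) * (atan(wg / hg) - atan(wp / hp))^2
}

#' WIoU loss with decomposition
#'
#' The wheat IoU loss couples the IoU overlap term with an aspect-ratio-
#' weighted squared center distance:
#' `loss = 1 - IoU(pred, gt) + psi * d2`, where `psi` is [aspect_penalty()]
#' and `d2` the squared Euclidean distance between box centers. As printed,
#' the distance term is the raw squared center distance in pixel units; with
#' `normalize = TRUE` it is divided by the squared diagonal of the smallest
#' enclosing box (a DIoU-style normalisation useful for training stability —
#' the unit definition remains the un-normalised one).
#'
#' Because `psi` multiplies the distance term, the loss reduces exactly to
#' `1 - IoU` whenever the two aspect ratios are equal, whatever the center
#' distance. That is a property of the printed formula and is preserved here.
#'
#' @inheritParams aspect_penalty
#' @param normalize divide the squared center distance by the squared
#'   enclosing-box diagonal (default `FALSE`, i.e. as printed).
#' @return a list of numeric vectors with components `iou`, `psi`,
#'   `center_dist_sq`, `loss` (class `"wiou_decomposition"`).
#' @export
wiou_loss <- function(pred, gt, normalize = FALSE) {
  p <- recycle_pair(pred, gt)
  check_positive_area(p$a, "pred"); check_positive_area(p$b, "gt")
  iou <- box_iou(p$a, p$b)
  psi <- aspect_penalty(p$a, p$b)
  cp <- box_center(p$a); cg <- box_center(p$b)
  d2 <- unname((cp[, 1L] - cg[, 1L])^2 + (cp[, 2L] - cg[, 2L])^2)
  dist_term <- d2
  if (normalize) {
    cw <- pmax(p$a[, 3L], p$b[, 3L]) - pmin(p$a[, 1L], p$b[, 1L])
    ch <- pmax(p$a[, 4L], p$b[, 4L]) - pmin(p$a[, 2L], p$b[, 2L])
    dist_term <- d2 / (cw^2 + ch^2)
  }
  structure(
    list(iou = iou, psi = psi, center_dist_sq = d2,
         loss = 1 - iou + psi * dist_term),
    class = "wiou_decomposition"
  )
}

#' CIoU loss of paired boxes
#'
#' `1 - IoU + d^2 / c^2 + alpha * v` with `d` the center distance, `c` the
#' enclosing-box diagonal, `v` the arctan aspect term (identical in form to
#' [aspect_penalty()]) and `alpha = v / ((1 - IoU) + v)`, treated as a
#' constant during differentiation.
#'
#' @inheritParams aspect_penalty
#' @return numeric vector of nonnegative loss values.
#' @export
ciou_loss <- function(pred, gt) {
  p <- recycle_pair(pred, gt)
  check_positive_area(p$a, "pred"); check_positive_area(p$b, "gt")
  iou <- box_iou(p$a, p$b)
  v <- aspect_penalty(p$a, p$b)
  cp <- box_center(p$a); cg <- box_center(p$b)
  d2 <- unname((cp[, 1L] - cg[, 1L])^2 + (cp[, 2L] - cg[, 2L])^2)
  cw <- pmax(p$a[, 3L], p$b[, 3L]) - pmin(p$a[, 1L], p$b[, 1L])
  ch <- pmax(p$a[, 4L], p$b[, 4L]) - pmin(p$a[, 2L], p$b[, 2L])
  c2 <- cw^2 + ch^2
  alpha <- ifelse(v > 0, v / ((1 - iou) + v), 0)
  1 - iou + d2 / c2 + alpha * v
}

#' Encode a box as distances to its four sides
#'
#' For a feature-map location `(x, y)` inside a box `(x0, y0, x1, y1)` the
#' regression target is the vector of distances `(l, t, r, b) =
#' (x - x0, y - y0, x1 - x, y1 - y)`. Locations on the box boundary are
#' treated as inside with a zero component; callers that require strictly
#' positive targets must filter beforehand (the assigner does).
#'
#' @param loc length-2 vector or n x 2 matrix of `(x, y)` locations.
#' @param box length-4 vector or n x 4 matrix of boxes (paired with `loc`,
#'   single box recycled).
#' @return n x 4 matrix with columns `l`, `t`, `r`, `b`.
#' @export
encode_ltrb <- function(loc, box) {
  if (is.null(dim(loc))) loc <- matrix(as.numeric(loc), nrow = 1L)
  b <- as_box_matrix(box)
  if (nrow(b) == 1L && nrow(loc) > 1L) b <- b[rep(1L, nrow(loc)), , drop = FALSE]
  if (nrow(loc) == 1L && nrow(b) > 1L) loc <- loc[rep(1L, nrow(b)), , drop = FALSE]
  out <- cbind(l = loc[, 1L] - b[, 1L], t = loc[, 2L] - b[, 2L],
               r = b[, 3L] - loc[, 1L], b = b[, 4L] - loc[, 2L])
  if (any(out < 0)) {
    stop("location lies outside the box; filter assignments before encoding")
  }
  out
}

#' Decode side distances back to a box
#'
#' Inverse of [encode_ltrb()]: `(x - l, y - t, x + r, y + b)`. A target of
#' all zeros decodes to a zero-area box at the location; such boxes are valid
#' output here but rejected by every loss.
#'
#' @param loc length-2 vector or n x 2 matrix of `(x, y)` locations.
#' @param target length-4 vector or n x 4 matrix of `(l, t, r, b)` distances,
#'   all nonnegative.
#' @return n x 4 box matrix.
#' @export
decode_ltrb <- function(loc, target) {
  if (is.null(dim(loc))) loc <- matrix(as.numeric(loc), nrow = 1L)
  tg <- as_box_matrix(target)
  if (any(tg < 0)) stop("regression target components must be nonnegative")
  if (nrow(loc) == 1L && nrow(tg) > 1L) loc <- loc[rep(1L, nrow(tg)), , drop = FALSE]
  cbind(x0 = loc[, 1L] - tg[, 1L], y0 = loc[, 2L] - tg[, 2L],
        x1 = loc[, 1L] + tg[, 3L], y1 = loc[, 2L] + tg[, 4L])
}

#' Center-ness of a regression target
#'
#' `sqrt(min(l, r) / max(l, r) * min(t, b) / max(t, b))`: 1 at the box
#' center, decaying to 0 at the box boundary. Targets with a zero component
#' score 0.
#'
#' @param target length-4 vector or n x 4 matrix of `(l, t, r, b)` distances.
#' @return numeric vector in `[0, 1]`.
#' @export
centerness <- function(target) {
  tg <- as_box_matrix(target)
  lr_min <- pmin(tg[, 1L], tg[, 3L]); lr_max <- pmax(tg[, 1L], tg[, 3L])
  tb_min <- pmin(tg[, 2L], tg[, 4L]); tb_max <- pmax(tg[, 2L], tg[, 4L])
  out <- numeric(nrow(tg))
  ok <- lr_max > 0 & tb_max > 0
  out[ok] <- sqrt((lr_min[ok] / lr_max[ok]) * (tb_min[ok] / tb_max[ok]))
  out
}
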