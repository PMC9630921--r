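#' @title Synthetic wheat-scene generation
#'
#' @description
#' A seeded generator of synthetic field scenes that stands in for an
#' unreleased wheat-spike dataset. Each scene is a textured background
#' (low-frequency colour noise plus a directional illumination gradient)
#' over which elongated, striped, rotated elliptical "spikes" are rendered
#' in random z-order, so that later spikes occlude earlier ones. The
#' returned boxes are the exact axis-aligned pixel extents of each rendered
#' spike mask (amodal: an occluded spike keeps its full-extent box, matching
#' common wheat-head annotation practice). Everything is deterministic given
#' the configuration and seed.
#'
#' @name synth
NULL

#' Synthetic scene configuration
#'
#' Defaults emulate dense field imagery: 20 to 80 spikes per image (typical
#' captioned densities run from the low twenties to the mid seventies),
#' elongated spikes whose length is roughly 8-18% of the image side with a
#' 3-5x length-to-width ratio, mostly-upright orientations with substantial
#' spread, a visible illumination gradient and unrestricted mutual
#' occlusion up to `max_overlap`.
#'
#' @param width,height image size in pixels.
#' @param count_range integer range (inclusive) for the number of spikes; a
#'   single value fixes the count.
#' @param length_range spike length range in pixels (default scales with the
#'   image side).
#' @param aspect_range length/width ratio range.
#' @param orientation_sd standard deviation (radians) of spike tilt around
#'   vertical.
#' @param illumination_strength fractional brightness swing of the linear
#'   illumination ramp (0 disables it).
#' @param texture_scale background noise cell size in pixels.
#' @param max_overlap maximum fraction of a new spike's mask that may already
#'   be covered by previously placed spikes (controls occlusion intensity).
#' @param max_retries placement retries per spike before failing.
#' @return a list of class `"synth_scene_config"`.
#' @export
synth_scene_config <- function(width = 512L, height = 512L,
                               count_range = c(20L, 80L),
                               length_range = NULL,
                               aspect_range = c(3, 5),
                               orientation_sd = 0.4,
                               illumination_strength = 0.25,
                               texture_scale = 32L,
                               max_overlap = 0.5,
                               max_retries = 50L) {
  if (is.null(length_range)) {
    side <- min(width, height)
    length_range <- c(0.08, 0.18) * side
  }
  if (length(count_range) == 1L) count_range <- rep(count_range, 2L)
  stopifnot(count_range[1L] >= 1L, count_range[2L] >= count_range[1L],
            width >= 32L, height >= 32L)
  structure(list(width = as.integer(width), height = as.integer(height),
                 count_range = as.integer(count_range),
                 length_range = length_range, aspect_range = aspect_range,
                 orientation_sd = orientation_sd,
                 illumination_strength = illumination_strength,
                 texture_scale = as.integer(texture_scale),
                 max_overlap = max_overlap,
                 max_retries = as.integer(max_retries)),
            class = "synth_scene_config")
}

# bilinear upsample of a coarse grid to h x w
upsample_grid <- function(g, h, w) {
  gh <- nrow(g); gw <- ncol(g)
  ry <- seq(1, gh, length.out = h)
  rx <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ry), gh - 1L); x0 <- pmin(floor(rx), gw - 1L)
  fy <- ry - y0; fx <- rx - x0
  a <- g[cbind(rep(y0, times = w), rep(x0, each = h))]
  b <- g[cbind(rep(y0, times = w), rep(x0 + 1L, each = h))]
  cc <- g[cbind(rep(y0 + 1L, times = w), rep(x0, each = h))]
  d <- g[cbind(rep(y0 + 1L, times = w), rep(x0 + 1L, each = h))]
  fy_m <- rep(fy, times = w); fx_m <- rep(fx, each = h)
  v <- a * (1 - fy_m) * (1 - fx_m) + cc * fy_m * (1 - fx_m) +
    b * (1 - fy_m) * fx_m + d * fy_m * fx_m
  matrix(v, h, w)
}

render_background <- function(cfg) {
  h <- cfg$height; w <- cfg$width
  base <- c(0.35, 0.42, 0.22)  # green-brown field tone
  gh <- max(2L, ceiling(h / cfg$texture_scale))
  gw <- max(2L, ceiling(w / cfg$texture_scale))
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    noise <- upsample_grid(matrix(stats::rnorm(gh * gw, 0, 0.05), gh, gw), h, w)
    fine <- matrix(stats::rnorm(h * w, 0, 0.015), h, w)
    img[, , ch] <- base[ch] + noise + fine
  }
  img
}

apply_illumination <- function(img, cfg) {
  s <- cfg$illumination_strength
  if (s <= 0) return(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  theta <- stats::runif(1, 0, 2 * pi)
  gx <- cos(theta); gy <- sin(theta)
  xs <- (seq_len(w) - 0.5) / w; ys <- (seq_len(h) - 0.5) / h
  t <- outer(ys, xs, function(y, x) gx * x + gy * y)
  t <- (t - min(t)) / max(max(t) - min(t), 1e-9)
  ramp <- 1 - s / 2 + s * t
  for (ch in 1:3) img[, , ch] <- img[, , ch] * ramp
  img
}

# Rasterize one spike; returns its pixel mask indices (within full image)
# and intensity modulation, or NULL if it does not fit.
sample_spike <- function(cfg) {
  L <- stats::runif(1, cfg$length_range[1L], cfg$length_range[2L])
  aspect <- stats::runif(1, cfg$aspect_range[1L], cfg$aspect_range[2L])
  Wd <- max(L / aspect, 2.5)
  theta <- stats::rnorm(1, 0, cfg$orientation_sd)
  # half-extents of the rotated ellipse's AABB
  ex <- sqrt((L / 2 * sin(theta))^2 + (Wd / 2 * cos(theta))^2)
  ey <- sqrt((L / 2 * cos(theta))^2 + (Wd / 2 * sin(theta))^2)
  if (2 * ex + 2 > cfg$width || 2 * ey + 2 > cfg$height) return(NULL)
  cx <- stats::runif(1, ex + 1, cfg$width - ex - 1)
  cy <- stats::runif(1, ey + 1, cfg$height - ey - 1)
  list(cx = cx, cy = cy, L = L, W = Wd, theta = theta, ex = ex, ey = ey)
}

rasterize_spike <- function(sp, cfg) {
  c0 <- max(1L, floor(sp$cx - sp$ex)); c1 <- min(cfg$width, ceiling(sp$cx + sp$ex))
  r0 <- max(1L, floor(sp$cy - sp$ey)); r1 <- min(cfg$height, ceiling(sp$cy + sp$ey))
  cols <- c0:c1; rows <- r0:r1
  px <- rep(cols - 0.5, each = length(rows)) - sp$cx
  py <- rep(rows - 0.5, times = length(cols)) - sp$cy
  u <- c(sin(sp$theta), -cos(sp$theta))   # along the spike axis
  v <- c(cos(sp$theta), sin(sp$theta))    # across
  a <- px * u[1L] + py * u[2L]
  b <- px * v[1L] + py * v[2L]
  inside <- (a / (sp$L / 2))^2 + (b / (sp$W / 2))^2 <= 1
  if (!any(inside)) return(NULL)
  rr <- rep(rows, times = length(cols))[inside]
  cc <- rep(cols, each = length(rows))[inside]
  # spikelet stripes along the axis + edge darkening across
  stripe <- 0.85 + 0.15 * sin(2 * pi * a[inside] / max(sp$L / 8, 3))
  edge <- 1 - 0.35 * (b[inside] / (sp$W / 2))^2
  list(rows = rr, cols = cc, shade = stripe * edge,
       box = c(min(cc) - 1, min(rr) - 1, max(cc), max(rr)))
}

#' Generate one synthetic annotated scene
#'
#' @param cfg a [synth_scene_config()].
#' @param seed integer seed; the same `(cfg, seed)` pair always returns a
#'   bitwise-identical scene.
#' @return list of class `"annotated_image"` with `image` (H x W x 3 array
#'   in `[0, 1]`), `boxes` (n x 4 matrix of exact mask extents), `width`,
#'   `height`, `seed`, and `masks_touch` (internal tightness check data).
#' @export
generate_scene <- function(cfg = synth_scene_config(), seed = 1L) {
  with_local_seed(seed, {
    img <- render_background(cfg)
    n <- if (cfg$count_range[1L] == cfg$count_range[2L]) cfg$count_range[1L]
         else sample(cfg$count_range[1L]:cfg$count_range[2L], 1L)
    occupied <- matrix(FALSE, cfg$height, cfg$width)
    boxes <- matrix(numeric(), 0L, 4L)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(cfg$max_retries)) {
        sp <- sample_spike(cfg)
        if (is.null(sp)) next
        ras <- rasterize_spike(sp, cfg)
        if (is.null(ras)) next
        idx <- cbind(ras$rows, ras$cols)
        if (mean(occupied[idx]) > cfg$max_overlap) next
        # per-spike colour: green->golden depending on maturity draw
        mat <- stats::runif(1)
        col0 <- (1 - mat) * c(0.45, 0.55, 0.25) + mat * c(0.78, 0.70, 0.38)
        col0 <- col0 + stats::rnorm(3, 0, 0.03)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[idx] <- pmin(pmax(col0[ch] * ras$shade, 0), 1)
          img[, , ch] <- plane
        }
        occupied[idx] <- TRUE
        boxes <- rbind(boxes, ras$box)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place spike ", i, " within bounds after ",
             cfg$max_retries, " retries; relax the configuration")
      }
    }
    img <- apply_illumination(img, cfg)
    img <- pmin(pmax(img, 0), 1)
    dimnames(boxes) <- NULL
    structure(list(image = img, boxes = boxes, width = cfg$width,
                   height = cfg$height, seed = seed),
              class = "annotated_image")
  })
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes one PPM image and one Pascal-VOC XML file per scene, a single COCO
#' JSON with all annotations, and a manifest JSON. Per-image seeds are
#' derived deterministically from the master seed, so regeneration with the
#' same arguments reproduces the files exactly.
#'
#' @param cfg a [synth_scene_config()].
#' @param n_images number of scenes.
#' @param out_dir output directory (created if missing).
#' @param master_seed master integer seed.
#' @return the manifest: list with `records` (per-image metadata incl. box
#'   counts and seeds) and file locations, invisibly written to
#'   `manifest.json`.
#' @export
generate_dataset <- function(cfg, n_images, out_dir, master_seed = 1L) {
  stopifnot(n_images >= 1L)
  img_dir <- file.path(out_dir, "images")
  ann_dir <- file.path(out_dir, "annotations")
  for (d in c(out_dir, img_dir, ann_dir)) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
      stop("cannot create output directory ", d)
    }
  }
  records <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    seed_i <- (master_seed + 7919L * i) %% 2147483629L
    scene <- generate_scene(cfg, seed = seed_i)
    fn <- sprintf("img_%04d.ppm", i)
    write_ppm(scene$image, file.path(img_dir, fn))
    rec <- list(id = i, file_name = fn, width = scene$width,
                height = scene$height, boxes = scene$boxes, seed = seed_i)
    write_labelimg_xml(rec, file.path(ann_dir, sprintf("img_%04d.xml", i)))
    records[[i]] <- rec
  }
  write_coco_json(records, file.path(out_dir, "coco.json"))
  manifest <- list(
    n_images = n_images, master_seed = master_seed,
    image_dir = "images", annotation_dir = "annotations",
    coco_json = "coco.json",
    records = lapply(records, function(r) {
      list(id = r$id, file_name = r$file_name, width = r$width,
           height = r$height, n_boxes = nrow(r$boxes), seed = r$seed)
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(manifest, list(full_records = records, dir = out_dir)))
}
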