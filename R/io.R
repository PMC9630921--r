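#' @title Annotation and image input/output
#'
#' @description
#' Readers and writers for the two annotation dialects used in wheat-head
#' detection work: per-image Pascal-VOC XML (the LabelImg dialect, storing
#' `xmin`/`ymin`/`xmax`/`ymax` per object) and a single COCO JSON file
#' (storing `bbox = [x, y, w, h]`, the upper-left-corner-plus-size vector).
#' VOC coordinates are taken verbatim, with no 1-pixel origin shift; this is
#' the documented dialect choice since downstream consumers disagree on it.
#'
#' Images are stored as binary PPM (P6), the one raster format base R can
#' read and write without additional libraries; any standard image tool can
#' convert to or from it.
#'
#' @name io
NULL

# ---- PPM (P6) ---------------------------------------------------------------

#' Write / read a binary PPM image
#'
#' @param img H x W x 3 numeric array with values in `[0, 1]`.
#' @param path file path (conventionally `.ppm`).
#' @return `read_ppm()` returns an H x W x 3 array in `[0, 1]`.
#' @export
write_ppm <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  px <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
  # interleave RGB per pixel, row-major
  arr <- aperm(array(px, dim(img)), c(3L, 2L, 1L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  writeBin(as.raw(as.vector(arr)), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
        if (length(c2) == 0L || c2 == "\n") break }; next }
      if (grepl("[[:space:]]", ch)) { if (length(tok)) break else next }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!identical(magic, "P6")) stop("not a binary PPM (P6) file: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  raw <- readBin(con, "raw", n = w * h * 3L)
  arr <- array(as.integer(raw), dim = c(3L, w, h))
  aperm(arr, c(3L, 2L, 1L)) / maxval
}

# ---- Pascal-VOC XML (LabelImg dialect) -------------------------------------

#' Write / read a LabelImg-style Pascal-VOC annotation file
#'
#' One XML file per image; each object holds a `bndbox` with
#' `xmin`/`ymin`/`xmax`/`ymax`, written verbatim from the box coordinates.
#'
#' @param record list with `file_name`, `width`, `height`, and `boxes` (an
#'   n x 4 matrix of `(x0, y0, x1, y1)` rows; may have zero rows).
#' @param path XML file path.
#' @param class_name object class label (default `"spike"`).
#' @return `read_labelimg_xml()` returns a record list as above (plus
#'   `classes`, the per-object labels).
#' @export
write_labelimg_xml <- function(record, path, class_name = "spike") {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", record$file_name)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(record$width))
  xml2::xml_add_child(size, "height", as.character(record$height))
  xml2::xml_add_child(size, "depth", "3")
  boxes <- record$boxes
  if (length(boxes)) {
    boxes <- as_box_matrix(boxes)
    for (i in seq_len(nrow(boxes))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", class_name)
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", format(boxes[i, 1L], digits = 17))
      xml2::xml_add_child(bb, "ymin", format(boxes[i, 2L], digits = 17))
      xml2::xml_add_child(bb, "xmax", format(boxes[i, 3L], digits = 17))
      xml2::xml_add_child(bb, "ymax", format(boxes[i, 4L], digits = 17))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_labelimg_xml
#' @export
read_labelimg_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed VOC XML in ", path, ": ",
                                           conditionMessage(e)))
  objs <- xml2::xml_find_all(doc, ".//object")
  get_num <- function(node, tag, i) {
    v <- xml2::xml_find_first(node, paste0("./bndbox/", tag))
    out <- suppressWarnings(as.numeric(xml2::xml_text(v)))
    if (is.na(out)) stop("missing/invalid <", tag, "> in ", path,
                         " at object ", i)
    out
  }
  boxes <- matrix(numeric(), 0L, 4L)
  classes <- character()
  for (i in seq_along(objs)) {
    o <- objs[[i]]
    b <- c(get_num(o, "xmin", i), get_num(o, "ymin", i),
           get_num(o, "xmax", i), get_num(o, "ymax", i))
    if (b[3L] <= b[1L] || b[4L] <= b[2L]) {
      stop("degenerate box (xmax <= xmin or ymax <= ymin) in ", path,
           " at object ", i)
    }
    boxes <- rbind(boxes, b)
    classes <- c(classes, xml2::xml_text(xml2::xml_find_first(o, "./name")))
  }
  dimnames(boxes) <- NULL
  list(
    file_name = xml2::xml_text(xml2::xml_find_first(doc, "./filename")),
    width = as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/width"))),
    height = as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/height"))),
    boxes = boxes, classes = classes
  )
}

# ---- COCO JSON --------------------------------------------------------------

#' Write / read COCO-format annotations
#'
#' The COCO `bbox` is `[x, y, w, h]` with `(x, y)` the upper-left corner;
#' boxes convert as `Box(x, y, x + w, y + h)`. A single category `"spike"`
#' with id 1 is written. Annotation ids are unique and contiguous.
#'
#' @param records list of image records (as in [read_labelimg_xml()], each
#'   additionally carrying an integer `id`).
#' @param path JSON file path.
#' @return `read_coco_json()` returns a list of records.
#' @export
write_coco_json <- function(records, path) {
  images <- lapply(records, function(r) {
    list(id = r$id, file_name = r$file_name, width = r$width, height = r$height)
  })
  anns <- list()
  aid <- 0L
  for (r in records) {
    boxes <- r$boxes
    if (!length(boxes)) next
    boxes <- as_box_matrix(boxes)
    for (i in seq_len(nrow(boxes))) {
      aid <- aid + 1L
      xywh <- boxes_to_xywh(boxes[i, ])
      anns[[aid]] <- list(id = aid, image_id = r$id, category_id = 1L,
                          bbox = as.numeric(xywh),
                          area = as.numeric(xywh[3L] * xywh[4L]),
                          iscrowd = 0L)
    }
  }
  out <- list(images = images, annotations = anns,
              categories = list(list(id = 1L, name = "spike")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco_json
#' @export
read_coco_json <- function(path) {
  d <- jsonlite::read_json(path)
  for (k in c("images", "annotations", "categories")) {
    if (is.null(d[[k]])) stop("COCO JSON missing required key '", k, "' in ", path)
  }
  recs <- lapply(d$images, function(im) {
    list(id = im$id, file_name = im$file_name,
         width = im$width, height = im$height,
         boxes = matrix(numeric(), 0L, 4L))
  })
  names(recs) <- vapply(d$images, function(im) as.character(im$id), character(1))
  for (a in d$annotations) {
    bb <- as.numeric(unlist(a$bbox))
    key <- as.character(a$image_id)
    recs[[key]]$boxes <- rbind(recs[[key]]$boxes, boxes_from_xywh(bb))
  }
  for (k in seq_along(recs)) dimnames(recs[[k]]$boxes) <- NULL
  unname(recs)
}

#' Export detections as COCO results JSON
#'
#' @param detections data frame with `image_id`, `x0`, `y0`, `x1`, `y1`,
#'   `score` columns.
#' @param path output JSON path.
#' @export
write_coco_results <- function(detections, path) {
  res <- lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    list(image_id = d$image_id, category_id = 1L,
         bbox = as.numeric(boxes_to_xywh(c(d$x0, d$y0, d$x1, d$y1))),
         score = d$score)
  })
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- Dataset split ----------------------------------------------------------

#' Random train/validation split
#'
#' Seeded shuffle; `floor(ratio * n)` records go to the training split, the
#' rest to validation. The two lists are disjoint and exhaustive.
#'
#' @param records list of image records.
#' @param ratio training fraction in (0, 1); default 0.8 (the conventional
#'   8:2 split).
#' @param seed integer seed for the shuffle.
#' @param strata optional character/integer vector (one entry per record):
#'   when given, the ratio is applied within each stratum (per-source
#'   splitting).
#' @return list with `train` and `validation` record lists.
#' @export
split_dataset <- function(records, ratio = 0.8, seed = 1L, strata = NULL) {
  n <- length(records)
  if (n == 0L) stop("cannot split an empty record list")
  stopifnot(ratio > 0, ratio < 1)
  idx_train <- integer()
  with_local_seed(seed, {
    if (is.null(strata)) strata <- rep(1L, n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      k <- floor(ratio * length(idx))
      idx_train <- c(idx_train, sample(idx)[seq_len(k)])
    }
  })
  idx_train <- sort(idx_train)
  list(train = records[idx_train],
       validation = records[setdiff(seq_len(n), idx_train)])
}

# Evaluate expr with a private RNG state; global stream untouched.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
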