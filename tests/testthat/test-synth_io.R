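small_cfg <- function(...) {
  synth_scene_config(width = 96L, height = 96L, count_range = c(4L, 8L), ...)
}

test_that("scene generation is deterministic and respects its contract", {
  cfg <- synth_scene_config(width = 128L, height = 128L,
                            count_range = 10L)    # fixed count
  sc <- generate_scene(cfg, seed = 5)
  expect_equal(nrow(sc$boxes), 10L)
  expect_true(all(sc$boxes[, 1] >= 0 & sc$boxes[, 2] >= 0 &
                  sc$boxes[, 3] <= 128 & sc$boxes[, 4] <= 128))
  expect_true(all(box_area(sc$boxes) > 0))
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  sc2 <- generate_scene(cfg, seed = 5)
  expect_identical(sc$image, sc2$image)
  expect_identical(sc$boxes, sc2$boxes)
  sc3 <- generate_scene(cfg, seed = 6)
  expect_false(identical(sc$image, sc3$image))
  # unplaceable spikes error out after bounded retries
  bad <- synth_scene_config(width = 40L, height = 40L, count_range = 2L,
                            length_range = c(200, 300), max_retries = 5L)
  expect_error(generate_scene(bad, seed = 1), "retries")
})

test_that("boxes are tight against the rendered spike mask", {
  cfg <- synth_scene_config(width = 96L, height = 96L, count_range = 1L,
                            illumination_strength = 0)
  for (seed in c(3, 4, 5)) {
    sc <- generate_scene(cfg, seed = seed)
    # replay the generator's RNG to reproduce the background alone
    bg <- spikeformer:::with_local_seed(seed,
      spikeformer:::render_background(cfg))
    changed <- which(apply(sc$image != bg, c(1, 2), any), arr.ind = TRUE)
    bx <- sc$boxes[1, ]
    cols <- range(changed[, 2]); rows <- range(changed[, 1])
    expect_lte(abs(bx[1] - (cols[1] - 1)), 1)
    expect_lte(abs(bx[2] - (rows[1] - 1)), 1)
    expect_lte(abs(bx[3] - cols[2]), 1)
    expect_lte(abs(bx[4] - rows[2]), 1)
  }
})

test_that("ppm write/read roundtrips at 8-bit precision", {
  img <- array(runif(20 * 30 * 3), c(20, 30, 3))
  f <- tempfile(fileext = ".ppm")
  write_ppm(img, f)
  back <- read_ppm(f)
  expect_equal(dim(back), dim(img))
  expect_equal(back, round(img * 255) / 255, tolerance = 1e-12)
  expect_error(read_ppm({ g <- tempfile(); writeLines("P3", g); g }), "P6")
})

test_that("VOC XML roundtrips exactly and validates its input", {
  set.seed(71)
  boxes <- cbind(runif(1000, 0, 400), runif(1000, 0, 400),
                 0, 0)
  boxes[, 3] <- boxes[, 1] + runif(1000, 0.5, 100)
  boxes[, 4] <- boxes[, 2] + runif(1000, 0.5, 100)
  rec <- list(file_name = "img.ppm", width = 512L, height = 512L,
              boxes = boxes)
  f <- tempfile(fileext = ".xml")
  write_labelimg_xml(rec, f)
  back <- read_labelimg_xml(f)
  expect_equal(back$boxes, unname(boxes), tolerance = 1e-12)
  expect_equal(back$file_name, "img.ppm")
  expect_equal(back$width, 512L)
  expect_true(all(back$classes == "spike"))
  # zero objects is valid
  f0 <- tempfile(fileext = ".xml")
  write_labelimg_xml(list(file_name = "e.ppm", width = 10L, height = 10L,
                          boxes = matrix(numeric(), 0, 4)), f0)
  expect_equal(nrow(read_labelimg_xml(f0)$boxes), 0L)
  # degenerate box in a file is a parse error naming the object
  bad <- tempfile(fileext = ".xml")
  writeLines(c("<annotation><filename>x</filename>",
               "<size><width>9</width><height>9</height></size>",
               "<object><name>spike</name><bndbox><xmin>5</xmin>",
               "<ymin>1</ymin><xmax>4</xmax><ymax>6</ymax></bndbox>",
               "</object></annotation>"), bad)
  expect_error(read_labelimg_xml(bad), "object 1")
  expect_error(read_labelimg_xml({ g <- tempfile(); writeLines("<a", g); g }),
               "malformed")
})

test_that("COCO JSON roundtrips with the xywh convention", {
  expect_equal(unname(boxes_from_xywh(c(1, 1, 4, 5))[1, ]), c(1, 1, 5, 6))
  set.seed(72)
  recs <- lapply(1:3, function(i) {
    n <- sample(2:6, 1)
    b <- cbind(runif(n, 0, 50), runif(n, 0, 50), 0, 0)
    b[, 3] <- b[, 1] + runif(n, 1, 30); b[, 4] <- b[, 2] + runif(n, 1, 30)
    list(id = i, file_name = sprintf("img_%d.ppm", i), width = 100L,
         height = 100L, boxes = b)
  })
  f <- tempfile(fileext = ".json")
  write_coco_json(recs, f)
  back <- read_coco_json(f)
  for (i in 1:3) expect_equal(back[[i]]$boxes, unname(recs[[i]]$boxes))
  # annotation ids unique and contiguous
  raw <- jsonlite::read_json(f)
  ids <- sapply(raw$annotations, `[[`, "id")
  expect_equal(sort(unlist(ids)), seq_along(ids))
  expect_error(read_coco_json({ g <- tempfile()
    jsonlite::write_json(list(images = list()), g); g }), "missing required")
})

test_that("dataset generation writes consistent files reproducibly", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_dataset(small_cfg(), 5, d1, master_seed = 11)
  m2 <- generate_dataset(small_cfg(), 5, d2, master_seed = 11)
  expect_equal(length(list.files(file.path(d1, "images"))), 5L)
  expect_equal(length(list.files(file.path(d1, "annotations"))), 5L)
  expect_true(file.exists(file.path(d1, "coco.json")))
  # regeneration with the same master seed gives identical bytes
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  # COCO box count equals the sum of per-image counts
  coco <- jsonlite::read_json(file.path(d1, "coco.json"))
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(length(coco$annotations),
               sum(sapply(manifest$records, `[[`, "n_boxes")))
  # VOC and COCO agree per image
  r3 <- read_labelimg_xml(file.path(d1, "annotations", "img_0003.xml"))
  c3 <- read_coco_json(file.path(d1, "coco.json"))[[3]]
  expect_equal(r3$boxes, c3$boxes, tolerance = 1e-9)
})

test_that("dataset split is seeded, disjoint and exhaustive", {
  recs <- as.list(1:10)
  sp <- split_dataset(recs, ratio = 0.8, seed = 4)
  expect_equal(length(sp$train), 8L)
  expect_equal(length(sp$validation), 2L)
  expect_identical(split_dataset(recs, ratio = 0.8, seed = 4), sp)
  all_items <- c(unlist(sp$train), unlist(sp$validation))
  expect_setequal(all_items, 1:10)
  expect_equal(anyDuplicated(all_items), 0L)
  # stratified split applies the ratio within each stratum
  strata <- rep(c("a", "b"), each = 5)
  sps <- split_dataset(recs, ratio = 0.8, seed = 1, strata = strata)
  expect_equal(length(sps$train), 8L)
  expect_equal(sum(unlist(sps$train) <= 5), 4L)
  expect_error(split_dataset(list(), 0.8, 1), "empty")
})

test_that("seeding is local: the global RNG stream is untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_scene(small_cfg(), seed = 99))
  expect_identical(.Random.seed, before)
})
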