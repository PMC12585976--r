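test_that("IoU matches corner arithmetic on canonical cases", {
  a <- box_labels(0, 0.5, 0.5, 0.4, 0.4)
  expect_equal(iou(a, a), 1.0)
  disjoint <- box_labels(0, 0.8, 0.5, 0.1, 0.1)
  near <- box_labels(0, 0.2, 0.5, 0.1, 0.1)
  expect_equal(iou(near, disjoint), 0.0)
  # vertical halves of the unit square overlapping in a quarter-wide band:
  # A = [0, .5] x [0, 1], B = [.25, .75] x [0, 1]
  # intersection 0.25, union 0.75 -> IoU = 1/3 by hand
  A <- box_labels(0, 0.25, 0.5, 0.5, 1)
  B <- box_labels(0, 0.50, 0.5, 0.5, 1)
  expect_equal(iou(A, B), 1 / 3)
})

test_that("IoU is symmetric, bounded, 1 iff identical, 0 for degenerate", {
  set.seed(42)
  for (i in 1:50) {
    a <- random_boxes(1)
    b <- random_boxes(1)
    v1 <- iou(a, b); v2 <- iou(b, a)
    expect_equal(v1, v2)
    expect_gte(v1, 0); expect_lte(v1, 1)
    if (v1 == 1) expect_equal(unlist(a[, 2:5]), unlist(b[, 2:5]))
  }
  degen <- box_labels(0, 0.5, 0.5, 0, 0.2)
  expect_equal(iou(degen, box_labels(0, 0.5, 0.5, 0.3, 0.3)), 0)
})

test_that("YOLO label round trip is lossless to 1e-6", {
  path <- withr::local_tempfile(fileext = ".txt")
  set.seed(1)
  labs <- random_boxes(100, n_classes = 24)[, c("class_id", "cx", "cy", "w", "h")]
  write_yolo_labels(labs, path)
  back <- read_yolo_labels(path)
  expect_equal(nrow(back), 100)
  for (col in c("cx", "cy", "w", "h")) {
    expect_lt(max(abs(back[[col]] - labs[[col]])), 1e-6)
  }
  expect_identical(back$class_id, labs$class_id)
})

test_that("YOLO reader handles edge cases and bad input", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), path)
  expect_equal(nrow(read_yolo_labels(path)), 0)
  writeLines("3 0.5 0.5 0.2 0.1", path)
  one <- read_yolo_labels(path)
  expect_equal(one$class_id, 3L)
  expect_equal(one$w, 0.2)
  writeLines(c("0 0.5 0.5 0.1 0.1", "1 0.2 bad 0.1"), path)
  expect_error(read_yolo_labels(path), "line 2")
  writeLines("30 0.5 0.5 0.2 0.1", path)
  expect_error(read_yolo_labels(path, catalog = fine24_catalog()), "catalog")
  # writing an empty table produces an empty file
  write_yolo_labels(box_labels(), path)
  expect_equal(length(readLines(path)), 0)
})

test_that("COCO export denormalizes correctly and round-trips", {
  labs <- box_labels(0, cx = 0.5, cy = 0.5, w = 0.5, h = 0.5)
  man <- dataset_manifest(tibble::tibble(
    path = "img.png", width = 640, height = 640, split = "train",
    labels = list(labs)))
  doc <- to_coco_json(man)
  expect_length(doc$images, 1)
  expect_length(doc$categories, 24)
  expect_equal(unlist(doc$annotations[[1]]$bbox), c(160, 160, 320, 320))
  # empty-label image
  man0 <- dataset_manifest(tibble::tibble(
    path = "img.png", width = 100, height = 100, split = "train",
    labels = list(box_labels())))
  expect_length(to_coco_json(man0)$annotations, 0)
  # export -> reimport reproduces the box set exactly after renormalization
  set.seed(3)
  labs2 <- random_boxes(7, n_classes = 24)[, c("class_id", "cx", "cy", "w", "h")]
  man2 <- dataset_manifest(tibble::tibble(
    path = c("a.png", "b.png"), width = c(640, 320), height = c(480, 320),
    split = "test", labels = list(labs2[1:4, ], labs2[5:7, ])))
  path <- withr::local_tempfile(fileext = ".json")
  to_coco_json(man2, path)
  back <- from_coco_json(path)
  for (i in 1:2) {
    expect_equal(as.data.frame(back$labels[[i]]),
                 as.data.frame(man2$labels[[i]]), tolerance = 1e-12)
  }
  # a manifest without pixel sizes cannot be denormalized
  man_bad <- man2
  man_bad$width[1] <- NA
  expect_error(to_coco_json(man_bad), "pixel size")
})

test_that("letterboxing preserves aspect and inverts within a pixel", {
  sq <- array(runif(3 * 100 * 100), c(100, 100, 3))
  lb <- letterbox(sq, 640)
  expect_equal(lb$pad_x, 0); expect_equal(lb$pad_y, 0)
  expect_equal(dim(lb$image), c(640, 640, 3))
  wide <- array(runif(3 * 320 * 640), c(320, 640, 3))
  lb2 <- letterbox(wide, 640)
  expect_equal(lb2$pad_y, 160)
  expect_equal(lb2$pad_x, 0)
  set.seed(9)
  labs <- random_boxes(20)[, c("class_id", "cx", "cy", "w", "h")]
  mapped <- letterbox_boxes(labs, lb2, 640)
  back <- letterbox_boxes(mapped, lb2, 640, inverse = TRUE)
  # a pixel of the original 640-wide image is 1/640 in normalized units
  expect_lt(max(abs(as.matrix(back[, 2:5]) - as.matrix(labs[, 2:5]))), 1 / 640)
  expect_error(letterbox(sq, 0), "positive")
  expect_error(letterbox(sq, 100), "32")
})

test_that("split assignment follows the 7:1:2 ratio", {
  s <- split_assignment(100)
  expect_equal(unname(table(s)[c("train", "val", "test")]), c(70, 10, 20),
               ignore_attr = TRUE)
  s2 <- split_assignment(10)
  expect_equal(sum(s2 == "train"), 7)
})
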