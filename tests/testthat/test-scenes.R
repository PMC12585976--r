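small_spec <- function(...) {
  scene_spec(n_classes = 6, image_size = 96, instances_range = c(1, 4),
             size_range = c(0.15, 0.4), occlusion = 0.2, tail_ratio = 1 / 10,
             ...)
}

test_that("scene generation is deterministic in (spec, seed)", {
  sp <- small_spec()
  a <- generate_scene(sp, seed = 42)
  b <- generate_scene(sp, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(as.data.frame(a$labels), as.data.frame(b$labels))
  c <- generate_scene(sp, seed = 43)
  expect_false(identical(a$image, c$image))
})

test_that("zero instances yields pure background", {
  sp <- scene_spec(n_classes = 4, image_size = 96, instances_range = c(0, 0))
  s <- generate_scene(sp, seed = 1)
  expect_equal(nrow(s$labels), 0)
  expect_equal(dim(s$image), c(96, 96, 3))
})

test_that("label boxes tightly bound the rendered instance masks", {
  sp <- small_spec()
  for (seed in 1:5) {
    s <- generate_scene(sp, seed = seed, keep_masks = TRUE)
    S <- sp$image_size
    for (i in seq_along(s$masks)) {
      m <- s$masks[[i]]
      rr <- range(m$rows[rowSums(m$mask) > 0])
      cc <- range(m$cols[colSums(m$mask) > 0])
      lab <- s$labels[i, ]
      # mask-derived box against the emitted label, in pixels
      expect_lte(abs((lab$cx - mean(cc) / S)) * S, 2)
      expect_lte(abs((lab$cy - mean(rr) / S)) * S, 2)
      expect_lte(abs(lab$w * S - (diff(cc) + 1)), 2)
      expect_lte(abs(lab$h * S - (diff(rr) + 1)), 2)
    }
  }
})

test_that("class frequencies follow the configured long tail", {
  sp <- scene_spec(n_classes = 5, image_size = 96, instances_range = c(4, 4),
                   size_range = c(0.1, 0.2), occlusion = 1, tail_ratio = 1 / 16)
  counts <- integer(5)
  for (seed in 1:150) {
    s <- generate_scene(sp, seed = seed)
    counts <- counts + tabulate(s$labels$class_id + 1L, 5)
  }
  # chi-square against the configured profile at a generous level
  expect_gt(stats::chisq.test(counts, p = sp$class_probs)$p.value, 1e-4)
  # the head class clearly dominates the tail class
  expect_gt(counts[1], 5 * counts[5])
})

test_that("dataset generation writes the standard layout and is reproducible", {
  sp <- small_spec()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- generate_dataset(sp, 20, seed = 7, dir = dir1, write_images = FALSE)
  m2 <- generate_dataset(sp, 20, seed = 7, dir = dir2, write_images = FALSE)
  expect_equal(unname(table(m1$split)[c("train", "val", "test")]),
               c(14, 2, 4), ignore_attr = TRUE)
  f1 <- sort(list.files(file.path(dir1, "labels"), recursive = TRUE))
  expect_equal(f1, sort(list.files(file.path(dir2, "labels"), recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(dir1, "labels", f)),
                     readLines(file.path(dir2, "labels", f)))
  }
  y <- yaml::read_yaml(file.path(dir1, "data.yaml"))
  expect_equal(y$nc, 6)
  expect_length(y$names, 6)
})

test_that("oracle detector reproduces ground truth at zero noise", {
  sp <- small_spec()
  dir <- withr::local_tempdir()
  man <- generate_dataset(sp, 10, seed = 3, dir = dir, write_images = FALSE)
  dets <- oracle_detector(man, oracle_noise(), n_classes = 6, seed = 1)
  gts <- hdmsyolo:::gather_gts(man)
  expect_equal(nrow(dets), nrow(gts))
  res <- map_50_95(dets, gts)
  expect_equal(attr(res, "map50"), 1)
})

test_that("oracle drop rate reduces recall in line with expectation", {
  sp <- scene_spec(n_classes = 3, image_size = 96, instances_range = c(5, 5),
                   size_range = c(0.1, 0.2), occlusion = 1)
  dir <- withr::local_tempdir()
  man <- generate_dataset(sp, 20, seed = 5, dir = dir, write_images = FALSE)
  gts <- hdmsyolo:::gather_gts(man)   # 100 objects
  dets <- oracle_detector(man, oracle_noise(drop_rate = 0.5), n_classes = 3,
                          seed = 11)
  m <- match_detections(dets, gts, 0.5)
  rec <- recall(m$counts)
  # binomial(100, 0.5): +/- 4 sd
  expect_gt(rec, 0.5 - 4 * sqrt(0.25 / nrow(gts)))
  expect_lt(rec, 0.5 + 4 * sqrt(0.25 / nrow(gts)))
})

test_that("pure-spurious oracle output has precision zero", {
  sp <- small_spec()
  s <- generate_scene(sp, seed = 2)
  dets <- oracle_detector(s, oracle_noise(drop_rate = 1, spurious_rate = 3),
                          n_classes = 6, seed = 4)
  expect_gt(nrow(dets), 0)
  gts <- s$labels; gts$image_id <- 1L
  m <- match_detections(dets, gts, 0.5)
  # spurious boxes are random; none should align at IoU 0.5 with only
  # a handful of ground truths
  expect_lt(precision(m$counts), 0.2)
})

test_that("hard-pair mode renders two classes nearly identically", {
  sp <- small_spec(hard_pair = TRUE)
  s1 <- hdmsyolo:::class_style(1L, sp)
  s2 <- hdmsyolo:::class_style(2L, sp)
  expect_equal(s1$archetype, s2$archetype)
  expect_lt(max(abs(s1$color - s2$color)), 0.1)
  sp0 <- small_spec()
  d1 <- hdmsyolo:::class_style(1L, sp0)
  d2 <- hdmsyolo:::class_style(2L, sp0)
  expect_false(d1$archetype == d2$archetype)
})
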