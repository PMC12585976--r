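test_that("matching is greedy, one-to-one and class-aware", {
  gts <- box_labels(c(0, 1), cx = c(0.3, 0.7), cy = c(0.3, 0.7),
                    w = c(0.2, 0.2), h = c(0.2, 0.2))
  perfect <- gts
  perfect$conf <- c(0.9, 0.8)
  m <- match_detections(perfect, gts)
  expect_true(all(m$detections$tp))
  expect_equal(sum(m$counts$fp), 0)
  expect_equal(sum(m$counts$fn), 0)
  # a duplicate of one object: one TP, one FP
  dup <- dplyr::bind_rows(perfect[1, ], perfect[1, ])
  dup$conf <- c(0.9, 0.85)
  m2 <- match_detections(dup, gts[1, ])
  expect_equal(m2$detections$tp, c(TRUE, FALSE))
  # crafted 3 dets vs 2 gts agrees with the independent greedy oracle
  gt3 <- box_labels(c(0, 0), cx = c(0.35, 0.55), cy = c(0.5, 0.5),
                    w = c(0.2, 0.2), h = c(0.3, 0.3))
  d3 <- box_labels(c(0, 0, 0), cx = c(0.36, 0.45, 0.56), cy = c(0.5, 0.5, 0.5),
                   w = c(0.2, 0.2, 0.2), h = c(0.3, 0.3, 0.3),
                   conf = c(0.7, 0.95, 0.6))
  m3 <- match_detections(d3, gt3)
  expect_equal(m3$detections$tp, ref_match(d3, gt3, 0.5))
})

test_that("precision/recall zero-denominator conventions are frozen", {
  expect_equal(precision(tibble::tibble(tp = 9, fp = 1, fn = 0)), 0.9)
  expect_equal(recall(tibble::tibble(tp = 5, fp = 2, fn = 0)), 1.0)
  expect_equal(precision(tibble::tibble(tp = 0, fp = 0, fn = 3)), 0)
  expect_equal(precision(tibble::tibble(tp = 0, fp = 0, fn = 0)), 1)
  expect_equal(recall(tibble::tibble(tp = 0, fp = 0, fn = 0)), 1)
})

test_that("AP handles the canonical limit cases", {
  gt <- box_labels(0, 0.5, 0.5, 0.3, 0.3)
  hit <- gt; hit$conf <- 0.9
  expect_equal(average_precision(pr_curve(hit, gt)), 1.0)
  none <- box_labels(conf = numeric())
  expect_equal(average_precision(pr_curve(none, gt)), 0.0)
  # five-detection hand case, frozen against the threshold-enumeration oracle
  set.seed(11)
  gts <- random_boxes(3, n_classes = 1)
  dets <- noisy_dets(gts, jitter = 0.03, extra = 2)
  dets$class_id <- 0L
  expect_equal(average_precision(pr_curve(dets, gts)), ref_ap(dets, gts, 0.5),
               tolerance = 1e-12)
})

test_that("AP equals brute-force enumeration on random instances", {
  set.seed(202)
  for (i in 1:60) {
    n_gt <- sample(1:6, 1)
    gts <- random_boxes(n_gt, n_classes = 1)
    dets <- noisy_dets(gts, jitter = runif(1, 0, 0.15), extra = sample(0:6, 1))
    dets$class_id <- 0L
    thr <- sample(seq(0.5, 0.9, 0.1), 1)
    expect_equal(average_precision(pr_curve(dets, gts, thr)),
                 ref_ap(dets, gts, thr), tolerance = 1e-9)
  }
})

test_that("AP is invariant under monotone confidence transforms", {
  set.seed(5)
  gts <- random_boxes(5, n_classes = 1)
  dets <- noisy_dets(gts, 0.05, 3)
  dets$class_id <- 0L
  ap1 <- average_precision(pr_curve(dets, gts))
  dets2 <- dets
  dets2$conf <- plogis(3 * qlogis(pmin(pmax(dets$conf, 1e-6), 1 - 1e-6)))
  expect_equal(average_precision(pr_curve(dets2, gts)), ap1, tolerance = 1e-12)
})

test_that("mAP averages only classes present in the ground truth", {
  expect_equal(mean_ap(tibble::tibble(class_id = 0:1, ap = c(1, 0), n_gt = c(3, 2))), 0.5)
  expect_equal(mean_ap(tibble::tibble(class_id = 0:2, ap = c(0.8, 0.8, 0.1),
                                      n_gt = c(1, 4, 0))), 0.8)
  expect_error(mean_ap(tibble::tibble(class_id = 0, ap = 0.5, n_gt = 0)),
               "ground-truth")
})

test_that("the 50:5:95 sweep enumerates exactly ten thresholds", {
  expect_equal(hdmsyolo:::map_iou_thresholds(),
               c(0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 0.80, 0.85, 0.90, 0.95))
  gt <- box_labels(c(0, 1), cx = c(0.3, 0.7), cy = c(0.3, 0.7),
                   w = c(0.2, 0.2), h = c(0.2, 0.2))
  perfect <- gt; perfect$conf <- 0.9
  res <- map_50_95(perfect, gt)
  expect_equal(nrow(res), 2 * 10)
  expect_equal(attr(res, "map50"), 1)
  expect_equal(attr(res, "map50_95"), 1)
})

test_that("a box at IoU exactly 0.6 scores at three of ten thresholds", {
  # dyadic coordinates keep the arithmetic exact: same-size 0.5-boxes offset
  # by 0.125 have intersection 0.375*0.5 and union 0.3125, hence IoU 0.6
  gt <- box_labels(0, 0.5, 0.5, 0.5, 0.5)
  det <- box_labels(0, 0.625, 0.5, 0.5, 0.5, conf = 0.9)
  expect_equal(iou(det, gt), 0.6)
  res <- map_50_95(det, gt)
  expect_equal(attr(res, "map50"), 1)
  expect_equal(attr(res, "map50_95"), 3 / 10)
})

test_that("TP + FN equals the ground-truth count at every threshold", {
  set.seed(77)
  gts <- random_boxes(12, n_classes = 3)
  dets <- noisy_dets(gts, 0.08, 5)
  for (thr in c(0.5, 0.7, 0.9)) {
    m <- match_detections(dets, gts, thr)
    per_class_gt <- table(factor(gts$class_id, levels = m$counts$class_id))
    expect_equal(m$counts$tp + m$counts$fn, as.integer(per_class_gt),
                 ignore_attr = TRUE)
  }
})

test_that("confusion matrix separates hits, confusions and background", {
  gts <- box_labels(c(0, 1), cx = c(0.3, 0.7), cy = c(0.3, 0.7),
                    w = c(0.2, 0.2), h = c(0.2, 0.2))
  perfect <- gts; perfect$conf <- 0.9
  cm <- confusion_matrix(perfect, gts, n_classes = 3)
  expect_equal(diag(cm)[1:2], c(1, 1), ignore_attr = TRUE)
  expect_equal(sum(cm), 2)
  # everything below the confidence threshold lands in background
  low <- perfect; low$conf <- 0.1
  cm2 <- confusion_matrix(low, gts, n_classes = 3, conf_threshold = 0.25)
  expect_equal(sum(cm2[4, 1:3]), 2)   # missed ground truths
  expect_equal(sum(cm2[1:3, ]), 0)
  # mixed four-object fixture, enumerated by hand: one hit, one class
  # confusion, one missed gt, one spurious detection
  gts4 <- box_labels(c(0, 1, 2), cx = c(0.2, 0.5, 0.8), cy = c(0.2, 0.5, 0.8),
                     w = 0.15, h = 0.15)
  dets4 <- box_labels(c(0, 2, 1), cx = c(0.2, 0.5, 0.62), cy = c(0.2, 0.5, 0.25),
                      w = 0.15, h = 0.15, conf = c(0.9, 0.8, 0.7))
  cm4 <- confusion_matrix(dets4, gts4, n_classes = 3)
  expect_equal(cm4[1, 1], 1L)   # class 0 hit
  expect_equal(cm4[3, 2], 1L)   # gt class 1 predicted as class 2
  expect_equal(cm4[4, 3], 1L)   # gt class 2 missed
  expect_equal(cm4[2, 4], 1L)   # spurious class-1 prediction
})

test_that("the per-class report mirrors the standard table and its summary", {
  set.seed(123)
  gts <- random_boxes(20, n_classes = 3)
  dets <- noisy_dets(gts, 0.05, 4)
  res <- per_class_results(dets, gts, catalog = c("a", "b", "c"))
  expect_equal(res$category[1], "all")
  per <- res[-1, ]
  expect_equal(res$map50[1], mean(per$map50))
  expect_equal(res$precision[1], mean(per$precision))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res, path)
  hdr <- readLines(path, n = 1)
  expect_equal(hdr, paste0('"Category","Instances","Precision (%)",',
                           '"Recall (%)","mAP@50 (%)","mAP@50-95 (%)"'))
})
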