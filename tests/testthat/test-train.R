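test_that("defaults follow the standard single-stage training recipe", {
  tc <- train_config()
  expect_equal(tc$momentum, 0.937)
  expect_equal(tc$lr, 0.01)
  expect_equal(tc$batch_size, 16L)
  expect_equal(tc$epochs, 300L)
  expect_equal(tc$image_size, 640L)
  expect_equal(tc$seed, 0L)
  expect_equal(tc$optimizer, "sgd")
})

test_that("known distributional logits decode to the encoded box", {
  size <- 64L
  nc <- 3L
  outs <- lapply(c(8, 4, 2), function(n) {
    list(reg = array(-20, c(64, n, n)), cls = array(-20, c(nc, n, n)))
  })
  # place one confident detection at P3 cell (h=3, w=4) (0-based):
  # distances l,t,r,b = 2,1,2,1 grid units at stride 8
  enc <- function(d) { v <- rep(-20, 16); v[d + 1] <- 20; v }
  cell <- c(enc(2), enc(1), enc(2), enc(1))
  outs[[1]]$reg[, 4, 5] <- cell
  outs[[1]]$cls[2, 4, 5] <- 8
  dets <- hdmsyolo:::decode_predictions(outs, size, nc, conf_threshold = 0.5)
  expect_equal(nrow(dets), 1)
  expect_equal(dets$class_id, 1L)
  # anchor centre = (4.5, 3.5) * 8 = (36, 28); box spans x 20..52, y 20..36
  expect_equal(dets$cx * size, 36, tolerance = 1e-6)
  expect_equal(dets$cy * size, 28, tolerance = 1e-6)
  expect_equal(dets$w * size, 32, tolerance = 1e-6)
  expect_equal(dets$h * size, 16, tolerance = 1e-6)
})

test_that("NMS keeps the top detection per overlapping same-class cluster", {
  d <- box_labels(c(0, 0, 1), cx = c(0.5, 0.52, 0.5), cy = c(0.5, 0.5, 0.5),
                  w = 0.3, h = 0.3, conf = c(0.9, 0.8, 0.7))
  kept <- nms(d, iou_threshold = 0.45)
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$conf, c(0.9, 0.7))
})

test_that("evaluating ground truth as predictions yields perfect scores", {
  sp <- scene_spec(n_classes = 4, image_size = 96, instances_range = c(2, 4),
                   size_range = c(0.15, 0.35))
  dir <- withr::local_tempdir()
  man <- generate_dataset(sp, 10, seed = 2, dir = dir, write_images = FALSE,
                          split_ratio = c(0, 0, 1))
  dets <- oracle_detector(man, oracle_noise(), n_classes = 4, seed = 1)
  ev <- evaluate(dets, man, "test")
  expect_equal(ev$results$map50[1], 100)
  expect_equal(ev$results$map50_95[1], 100)
  ap <- ev$ap
  expect_true(all(ap$ap[ap$n_gt > 0] == 1))
  # the summary row is the unweighted mean of the class rows
  expect_equal(ev$results$precision[1], mean(ev$results$precision[-1]))
})

test_that("an empty prediction set scores zero everywhere", {
  sp <- scene_spec(n_classes = 3, image_size = 96, instances_range = c(1, 2))
  dir <- withr::local_tempdir()
  man <- generate_dataset(sp, 6, seed = 4, dir = dir, write_images = FALSE,
                          split_ratio = c(0, 0, 1))
  empty <- tibble::tibble(image_id = integer(), class_id = integer(),
                          cx = numeric(), cy = numeric(), w = numeric(),
                          h = numeric(), conf = numeric())
  ev <- evaluate(empty, man, "test")
  expect_equal(ev$results$map50[1], 0)
  expect_equal(ev$results$recall[1], 0)
})

test_that("one epoch of training runs with finite losses and a usable trace", {
  sp <- scene_spec(n_classes = 3, image_size = 64, instances_range = c(1, 2),
                   size_range = c(0.3, 0.5), occlusion = 0)
  dir <- withr::local_tempdir()
  man <- generate_dataset(sp, 8, seed = 1, dir = dir, split_ratio = c(1, 0, 0))
  m <- build_model(ablation_config(n_classes = 3, image_size = 64), seed = 1)
  fit <- train(m, man, train_config(epochs = 1, batch_size = 4, image_size = 64,
                                    seed = 1))
  expect_equal(nrow(fit$trace), 1)
  expect_true(all(is.finite(fit$trace$loss)))
  expect_true(all(c("box", "cls", "dfl") %in% names(fit$trace)))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$epochs, 1)
})

test_that("a few epochs on an overfit fixture reduce the loss", {
  sp <- scene_spec(n_classes = 2, image_size = 64, instances_range = c(1, 2),
                   size_range = c(0.3, 0.5), occlusion = 0)
  dir <- withr::local_tempdir()
  man <- generate_dataset(sp, 4, seed = 9, dir = dir, split_ratio = c(1, 0, 0))
  m <- build_model(ablation_config(n_classes = 2, image_size = 64), seed = 2)
  fit <- train(m, man, train_config(epochs = 16, batch_size = 4,
                                    image_size = 64, seed = 2,
                                    warmup_epochs = 1))
  # windowed check: the smoothed tail sits below the early-phase loss
  expect_lt(mean(tail(fit$trace$loss, 3)), min(fit$trace$loss[1:3]))
})

test_that("autograd gradients match finite differences through the loss", {
  cfg <- ablation_config(TRUE, TRUE, TRUE, n_classes = 3, image_size = 64)
  m <- build_model(cfg, seed = 2)
  set.seed(7)
  img <- array(runif(3 * 64 * 64), c(3, 64, 64))
  gt <- box_labels(class_id = c(0, 2), cx = c(0.3, 0.7), cy = c(0.4, 0.6),
                   w = c(0.3, 0.25), h = c(0.35, 0.3))
  outs0 <- m$forward(img)
  anchors <- hdmsyolo:::anchor_table(64)
  dist_val <- do.call(cbind, lapply(outs0, function(o) {
    hdmsyolo:::decode_distances(o$reg)
  }))
  cls_prob <- do.call(cbind, lapply(outs0, function(o) {
    1 / (1 + exp(-matrix(o$cls, dim(o$cls)[1])))
  }))
  asg <- hdmsyolo:::tal_assign(gt, anchors, dist_val, cls_prob, 64)
  lossfn <- function() {
    hdmsyolo:::detection_loss(m$forward(img), gt, 64, 3,
                              fixed_assignment = asg)
  }
  hdmsyolo:::zero_grads(m)
  hdmsyolo:::ag_start_tape()
  dl <- lossfn()
  hdmsyolo:::ag_backward(dl$loss)
  hdmsyolo:::ag_clear_tape()
  expect_gt(dl$n_assigned, 0)
  set.seed(8)
  checked <- 0
  for (pi in sample(seq_along(m$ctx$params))) {
    p <- m$ctx$params[[pi]]
    if (is.null(p$grad) || !isTRUE(p$trainable)) next
    idx <- which.max(abs(p$grad))
    if (abs(p$grad[idx]) < 1e-6) next
    eps <- 1e-5
    v0 <- p$value[idx]
    p$value[idx] <- v0 + eps
    lp <- hdmsyolo:::ag_val(lossfn()$loss)
    p$value[idx] <- v0 - eps
    lm <- hdmsyolo:::ag_val(lossfn()$loss)
    p$value[idx] <- v0
    gn <- (lp - lm) / (2 * eps)
    expect_equal(p$grad[idx], gn, tolerance = 5e-3)
    checked <- checked + 1
    if (checked >= 6) break
  }
  expect_gte(checked, 4)
})

test_that("trained checkpoints evaluate identically after a round trip", {
  sp <- scene_spec(n_classes = 2, image_size = 64, instances_range = c(1, 2),
                   size_range = c(0.3, 0.5), occlusion = 0)
  dir <- withr::local_tempdir()
  man <- generate_dataset(sp, 4, seed = 3, dir = dir, split_ratio = c(1, 0, 0))
  m <- build_model(ablation_config(n_classes = 2, image_size = 64), seed = 1)
  fit <- train(m, man, train_config(epochs = 1, batch_size = 4,
                                    image_size = 64, seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  m2 <- load_checkpoint(path)
  man$split <- "test"
  e1 <- evaluate(fit$model, man, "test")
  e2 <- evaluate(m2, man, "test")
  expect_identical(e1$results, e2$results)
})
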