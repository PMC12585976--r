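test_that("task attention is sigmoid-bounded and 0.5 at zero input", {
  z <- array(0, c(32, 6, 6))
  params0 <- list(w1 = matrix(0.3, 32, 26), b1 = numeric(26),
                  w2 = matrix(-0.2, 26, 32), b2 = numeric(32))
  res <- task_attention(z, params = params0)
  expect_equal(res$weights, rep(0.5, 32))
  expect_equal(res$output, z * 0.5)
  set.seed(61)
  x <- array(rnorm(32 * 6 * 6, sd = 5), c(32, 6, 6))
  r2 <- task_attention(x, seed = 2)
  expect_true(all(r2$weights > 0 & r2$weights < 1))
})

test_that("task attention commutes with channel permutation", {
  set.seed(62)
  C <- 16
  x <- array(rnorm(C * 5 * 5), c(C, 5, 5))
  params <- list(w1 = matrix(rnorm(C * 8), C, 8), b1 = rnorm(8),
                 w2 = matrix(rnorm(8 * C), 8, C), b2 = rnorm(C))
  base <- task_attention(x, params = params)
  perm <- sample(C)
  params_p <- list(w1 = params$w1[perm, , drop = FALSE], b1 = params$b1,
                   w2 = params$w2[, perm, drop = FALSE], b2 = params$b2[perm])
  permuted <- task_attention(x[perm, , , drop = FALSE], params = params_p)
  expect_equal(permuted$weights, base$weights[perm], tolerance = 1e-12)
})

test_that("spatial attention squashes to (0,1) and saturates as designed", {
  set.seed(63)
  x <- array(rnorm(8 * 7 * 7), c(8, 7, 7))
  r <- spatial_attention(x, seed = 1)
  expect_true(all(r$map > 0 & r$map < 1))
  r0 <- spatial_attention(x, weights = numeric(8), bias = 0)
  expect_equal(r0$output, x * 0.5)
  # a hugely negative bias drives the attended output toward zero
  rneg <- spatial_attention(x, weights = numeric(8), bias = -30)
  expect_lt(max(abs(rneg$output)), 1e-10)
})

test_that("deformable convolution with zero offsets equals dense convolution", {
  set.seed(64)
  for (i in 1:8) {
    C <- sample(c(2, 4), 1); Cout <- sample(c(2, 4), 1)
    H <- sample(5:9, 1); W <- sample(5:9, 1)
    x <- array(rnorm(C * H * W), c(C, H, W))
    w <- array(rnorm(9 * C * Cout), c(3, 3, C, Cout))
    b <- rnorm(Cout)
    field <- list(offsets = array(0, c(18, H, W)), mask = array(1, c(9, H, W)))
    expect_lt(max(abs(deformable_regression(x, field, w, b) -
                        conv2d(x, w, b))), 1e-5)
  }
})

test_that("zero modulation suppresses everything except the bias", {
  set.seed(65)
  x <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
  w <- array(rnorm(9 * 4 * 2), c(3, 3, 4, 2))
  field <- list(offsets = array(rnorm(18 * 36), c(18, 6, 6)),
                mask = array(0, c(9, 6, 6)))
  y <- deformable_regression(x, field, w, bias = c(1, -2))
  expect_true(all(abs(y[1, , ] - 1) < 1e-12))
  expect_true(all(abs(y[2, , ] + 2) < 1e-12))
})

test_that("integer offsets reproduce shifted-input convolution in the interior", {
  set.seed(66)
  x <- array(rnorm(3 * 10 * 10), c(3, 10, 10))
  w <- array(rnorm(9 * 3 * 2), c(3, 3, 3, 2))
  # shift every tap by (+1, 0): samples come from one row below
  off <- array(0, c(18, 10, 10))
  off[seq(1, 17, 2), , ] <- 1
  field <- list(offsets = off, mask = array(1, c(9, 10, 10)))
  y <- deformable_regression(x, field, w)
  xs <- x
  xs[, 1:9, ] <- x[, 2:10, ]     # input shifted up by one row
  ys <- conv2d(xs, w)
  expect_lt(max(abs(y[, 2:8, 2:9] - ys[, 2:8, 2:9])), 1e-10)
})

test_that("deformable convolution validates field shapes", {
  x <- array(0, c(4, 6, 6))
  w <- array(0, c(3, 3, 4, 4))
  expect_error(deformable_regression(
    x, list(offsets = array(0, c(18, 5, 6)), mask = array(1, c(9, 6, 6))), w),
    "offset")
  expect_error(deformable_regression(
    x, list(offsets = array(0, c(18, 6, 6)), mask = array(1, c(8, 6, 6))), w),
    "mask")
})

test_that("scale fusion reweights levels linearly", {
  set.seed(67)
  outs <- lapply(c(8, 4, 2), function(n) {
    list(reg = array(rnorm(64 * n * n), c(64, n, n)),
         cls = array(rnorm(4 * n * n), c(4, n, n)))
  })
  id <- fuse_scales(outs, c(1, 1, 1))
  expect_equal(id, outs)
  zero <- fuse_scales(outs, c(0, 0, 0))
  expect_true(all(vapply(zero, function(o) max(abs(o$cls)) == 0, TRUE)))
  dbl <- fuse_scales(outs, c(2, 1, 1))
  expect_equal(dbl[[1]]$reg, 2 * outs[[1]]$reg)
  expect_equal(dbl[[2]], outs[[2]])
  expect_error(fuse_scales(outs, c(1, 1)), "per pyramid level")
})

test_that("the head emits stride-8/16/32 grids with the contracted channels", {
  cfg <- ablation_config(use_integradet = TRUE, n_classes = 24, image_size = 96)
  m <- build_model(cfg, seed = 1)
  outs <- m$forward(array(runif(3 * 96 * 96), c(3, 96, 96)))
  expect_length(outs, 3)
  sizes <- vapply(outs, function(o) dim(o$reg)[2], 0)
  expect_equal(sizes, c(12, 6, 3))
  for (o in outs) {
    expect_equal(dim(o$reg)[1] + dim(o$cls)[1], 24 + 4 * 16)
  }
})

test_that("head weight sharing keeps the variant lighter than the baseline", {
  base <- build_model(ablation_config(), seed = 0)
  head <- build_model(ablation_config(use_integradet = TRUE), seed = 0)
  expect_lt(count_parameters(head), count_parameters(base))
  expect_equal(count_parameters(base) - count_parameters(head), 385133)
})
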