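test_that("space-to-depth conserves every input element and inverts exactly", {
  x <- array(as.numeric(seq_len(3 * 4 * 4)), c(3, 4, 4))
  y <- space_to_depth(x)
  expect_equal(dim(y), c(12, 2, 2))
  expect_equal(sort(as.vector(y)), sort(as.vector(x)))
  expect_identical(depth_to_space(y), x)
  # constant input stays constant
  k <- space_to_depth(array(2.5, c(2, 6, 6)))
  expect_true(all(k == 2.5))
  # random shapes, bit-exact inversion
  set.seed(10)
  for (i in 1:10) {
    d <- c(sample(1:8, 1), 2 * sample(1:6, 1), 2 * sample(1:6, 1))
    x <- array(rnorm(prod(d)), d)
    expect_identical(depth_to_space(space_to_depth(x)), x)
  }
  expect_error(space_to_depth(array(0, c(3, 5, 4))), "even")
})

test_that("conv2d agrees with the naive reference convolution", {
  set.seed(21)
  for (i in 1:6) {
    cin <- sample(c(2, 4, 6), 1)
    cout <- sample(c(2, 4), 1)
    k <- sample(c(1, 3, 5), 1)
    stride <- sample(1:2, 1)
    g <- if (cin %% 2 == 0 && cout %% 2 == 0 && sample(2, 1) == 1) 2 else 1
    x <- array(rnorm(cin * 8 * 10), c(cin, 8, 10))
    w <- array(rnorm(k * k * (cin / g) * cout), c(k, k, cin / g, cout))
    b <- rnorm(cout)
    expect_equal(conv2d(x, w, b, stride = stride, groups = g),
                 ref_conv2d(x, w, b, stride = stride, groups = g),
                 tolerance = 1e-12)
  }
})

test_that("stride-2 grouped convolution halves space; depthwise channels stay independent", {
  x <- array(rnorm(16 * 8 * 8), c(16, 8, 8))
  w <- array(rnorm(3 * 3 * 4 * 8), c(3, 3, 4, 8))
  y <- conv2d(x, w, stride = 2, groups = 4)
  expect_equal(dim(y), c(8, 4, 4))
  # depthwise limit: perturbing channel j changes only output channel j
  wd <- array(rnorm(3 * 3 * 1 * 16), c(3, 3, 1, 16))
  y0 <- conv2d(x, wd, stride = 2, groups = 16)
  x2 <- x
  x2[5, , ] <- x2[5, , ] + rnorm(64)
  y1 <- conv2d(x2, wd, stride = 2, groups = 16)
  changed <- which(apply(abs(y1 - y0), 1, max) > 1e-12)
  expect_equal(changed, 5L)
})

test_that("max pooling matches a window-max oracle and is monotone", {
  set.seed(30)
  x <- array(rnorm(2 * 9 * 9), c(2, 9, 9))
  y <- max_pool2d(x, k = 3, stride = 2, pad = 1)
  # independent window-max computation
  for (c in 1:2) for (ho in 1:5) for (wo in 1:5) {
    hs <- max(1, 2 * ho - 2):min(9, 2 * ho)
    ws <- max(1, 2 * wo - 2):min(9, 2 * wo)
    expect_equal(y[c, ho, wo], max(x[c, hs, ws]))
  }
  expect_true(all(max_pool2d(array(3, c(1, 8, 8))) == 3))
  # monotone: raising any input never lowers the pooled map
  for (i in 1:20) {
    idx <- c(sample(2, 1), sample(9, 1), sample(9, 1))
    x2 <- x
    x2[idx[1], idx[2], idx[3]] <- x2[idx[1], idx[2], idx[3]] + runif(1, 0, 2)
    expect_true(all(max_pool2d(x2) - y >= -1e-12))
  }
  # hot pixel: affected pooled cells are exactly the windows covering it
  xz <- array(0, c(1, 8, 8))
  xz[1, 4, 4] <- 5
  yz <- max_pool2d(xz)
  hit <- which(yz > 0, arr.ind = TRUE)
  expect_true(all(yz[hit] == 5))
  expect_equal(nrow(hit), 4)  # 3x3/stride-2 windows overlap on even pixels
})

test_that("SRFD produces the half and quarter resolution maps", {
  blk <- srfd_block(seed = 1)
  x <- array(runif(3 * 64 * 64), c(3, 64, 64))
  out <- srfd_forward(blk, x)
  expect_equal(dim(out$half), c(16, 32, 32))
  expect_equal(dim(out$quarter), c(32, 16, 16))
  expect_error(srfd_forward(blk, array(0, c(3, 66, 64))), "divisible by 4")
  # zeros propagate to zeros (normalization of a constant-zero map is zero)
  z <- srfd_forward(blk, array(0, c(3, 32, 32)))
  expect_equal(max(abs(z$quarter)), 0)
})

test_that("DRFD halves space and follows the channel-doubling convention", {
  blk <- drfd_block(16)
  expect_equal(blk$cout, 32)
  x <- array(rnorm(16 * 20 * 20), c(16, 20, 20))
  y <- drfd_forward(blk, x)
  expect_equal(dim(y), c(32, 10, 10))
  expect_error(drfd_forward(blk, array(0, c(16, 9, 10))), "even")
  expect_error(drfd_forward(blk, array(0, c(8, 10, 10))), "channels")
  # shape contract over random valid sizes
  set.seed(4)
  for (i in 1:5) {
    h <- 2 * sample(3:12, 1); w <- 2 * sample(3:12, 1)
    y <- drfd_forward(blk, array(rnorm(16 * h * w), c(16, h, w)))
    expect_equal(dim(y), c(32, h / 2, w / 2))
  }
})

test_that("DRFD parameter count follows the grouped closed forms", {
  blk <- drfd_block(64, 64)
  # cut: 4*64*64 + 64; conv: 9*64*64/2 + 64; pooled projection: 64*64/2 + 64
  expect_equal(count_parameters(blk),
               (4 * 64 * 64 + 64) + (9 * 64 * 64 / 2 + 64) + (64 * 64 / 2 + 64))
})
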