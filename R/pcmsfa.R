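# Partial-convolution multi-scale feature aggregation. Each unit runs a 3x3
# convolution for basic feature extraction, routes one leading channel slice
# through a 5x5 convolution (medium scale) and the next slice through a 7x7
# convolution (large-scale context) while the remaining channels pass
# through untouched, fuses everything with a 1x1 convolution and adds the
# unit input back as a residual.

# slice fractions, in 64ths of the unit width (calibrated against the
# published parameter budget of the block)
PC_MSFA_F5 <- 38L
PC_MSFA_F7 <- 19L

#' Partial convolution over a leading channel slice
#'
#' Convolves only the first `floor(fraction * C)` channels with a dense
#' `k x k` kernel; all remaining channels pass through bit-identically.
#'
#' @param x Numeric array `(C, H, W)`.
#' @param kernel Kernel size, 5 or 7.
#' @param fraction Fraction of channels to convolve; must select at least
#'   one channel.
#' @param weights Optional `(k, k, c_sel, c_sel)` weights; drawn from the
#'   Kaiming-uniform initializer under `seed` when omitted.
#' @param bias Optional length-`c_sel` bias (zeros when omitted).
#' @param seed Seed used when `weights` is `NULL`.
#' @return Numeric array of the same shape as `x`.
#' @export
partial_branch <- function(x, kernel = c(5, 7), fraction = 0.25,
                           weights = NULL, bias = NULL, seed = 0L) {
  kernel <- match.arg(as.character(kernel[1]), c("5", "7"))
  k <- as.integer(kernel)
  C <- dim(x)[1]
  c_sel <- floor(fraction * C)
  if (c_sel < 1) {
    stop("fraction ", fraction, " selects no channels of ", C, call. = FALSE)
  }
  if (is.null(weights)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    bound <- 1 / sqrt(k^2 * c_sel)
    weights <- array(runif(k * k * c_sel * c_sel, -bound, bound),
                     dim = c(k, k, c_sel, c_sel))
  }
  stopifnot(all(dim(weights) == c(k, k, c_sel, c_sel)))
  if (is.null(bias)) bias <- numeric(c_sel)
  out <- x
  out[seq_len(c_sel), , ] <- conv2d_fw(
    x[seq_len(c_sel), , , drop = FALSE], weights, bias, 1L, k %/% 2, 1L)
  out
}

# one residual unit at width c
mk_pcmsfa_unit <- function(ctx, c) {
  c5 <- max(1L, (c * PC_MSFA_F5) %/% 64L)
  c7 <- max(1L, (c * PC_MSFA_F7) %/% 64L)
  p5 <- mk_conv(ctx, 5, c5, c5, norm = "none", bias = TRUE, act = "none")
  p7 <- mk_conv(ctx, 7, c7, c7, norm = "none", bias = TRUE, act = "none")
  fuse <- mk_conv(ctx, 1, c, c, groups = 2, act = "silu")
  list(cout = c, c5 = c5, c7 = c7, fwd = function(u) {
    if (is_shape(u)) {
      p5$fwd(agshape(c5, u$h, u$w))
      p7$fwd(agshape(c7, u$h, u$w))
      return(fuse$fwd(u))
    }
    s5 <- ag_slice(u, seq_len(c5))
    s7 <- ag_slice(u, c5 + seq_len(c7))
    parts <- list(p5$fwd(s5), p7$fwd(s7))
    if (c5 + c7 < c) {
      parts <- c(parts, list(ag_slice(u, c5 + c7 + seq_len(c - c5 - c7))))
    }
    mixed <- ag_concat(parts)
    ag_add(u, fuse$fwd(mixed))
  })
}

mk_pcmsfa <- function(ctx, cin, cout, n = 1) {
  c <- max(8L, cout %/% 2L)
  entry <- mk_conv(ctx, 3, cin, c, groups = 4, act = "silu")
  units <- lapply(seq_len(n), function(i) mk_pcmsfa_unit(ctx, c))
  exit <- mk_conv(ctx, 1, c, cout, act = "silu")
  list(cout = cout, width = c, fwd = function(x) {
    u <- entry$fwd(x)
    for (un in units) u <- un$fwd(u)
    exit$fwd(u)
  })
}

#' Build a partial-convolution multi-scale aggregation block
#'
#' Drop-in replacement for the C3k2 sites of the baseline: a 3x3 entry
#' convolution maps to the unit width (half the output channels),
#' `repeat_count` residual units apply the 5x5/7x7 partial convolutions and
#' the 1x1 fusion, and a 1x1 exit convolution restores the requested output
#' width. With `repeat_count = 0` the block degenerates to the entry/exit
#' projections.
#'
#' @param in_channels,out_channels Channel counts.
#' @param repeat_count Number of stacked inner units.
#' @param seed Seed for weight initialization.
#' @return A `pc_msfa_block`.
#' @export
build_pc_msfa <- function(in_channels, out_channels, repeat_count = 1L,
                          seed = 0L) {
  stopifnot(in_channels >= 1, out_channels >= 1, repeat_count >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ctx <- new_ctx()
  blk <- mk_pcmsfa(ctx, in_channels, out_channels, repeat_count)
  structure(list(ctx = ctx, block = blk, cin = in_channels,
                 cout = out_channels), class = "pc_msfa_block")
}

#' Run a PC-MSFA block
#'
#' @param block A [build_pc_msfa()] result.
#' @param x Numeric array `(in_channels, H, W)`.
#' @return Numeric array `(out_channels, H, W)`: spatial size is preserved.
#' @export
pc_msfa_forward <- function(block, x) {
  if (dim(x)[1] != block$cin) {
    stop("input has ", dim(x)[1], " channels; block expects ", block$cin,
         call. = FALSE)
  }
  block$block$fwd(x)
}
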