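# Hierarchical robust feature downsampling: an SRFD stem (two stages) for
# the shallow layers and DRFD blocks for every deeper stride-2 site. Each
# stage fuses complementary parallel branches by addition:
#   CutD  — space-to-depth slicing (lossless) + learned pointwise projection
#   ConvD — stride-2 grouped convolution for local context
#   MaxD  — stride-2 max pooling + pointwise projection for salient features

#' Space-to-depth rearrangement (the CutD slicing)
#'
#' Moves each 2x2 spatial neighbourhood into the channel dimension:
#' `(C, H, W) -> (4C, H/2, W/2)`. The rearrangement is a bijection of the
#' input elements — no pixel is discarded — which is what distinguishes this
#' downsampling route from strided convolution or pooling. Inside SRFD/DRFD
#' it is followed by a learned pointwise projection.
#'
#' @param x Numeric array `(C, H, W)` with even `H` and `W`.
#' @return Numeric array `(4C, H/2, W/2)`.
#' @export
space_to_depth <- function(x) {
  d <- dim(x)
  if (length(d) != 3) stop("expected a (C, H, W) array", call. = FALSE)
  if (d[2] %% 2 || d[3] %% 2) {
    stop("space-to-depth needs even spatial size, got ", d[2], "x", d[3],
         call. = FALSE)
  }
  s2d_fw_(x)
}

#' @rdname space_to_depth
#' @param y Numeric array `(4C, H, W)` produced by [space_to_depth()].
#' @export
depth_to_space <- function(y) {
  d <- dim(y)
  if (d[1] %% 4) stop("channel count must be a multiple of 4", call. = FALSE)
  s2d_inverse(y)
}

#' Stride-2 max pooling
#'
#' The pooling stage of the MaxD branch: 3x3 max pooling with stride 2 and
#' padding 1. Monotone non-decreasing in every input element.
#'
#' @param x Numeric array `(C, H, W)`.
#' @param k Pooling kernel.
#' @param stride,pad Stride and zero padding.
#' @return Pooled array.
#' @export
max_pool2d <- function(x, k = 3, stride = 2, pad = 1) {
  if (dim(x)[2] < k || dim(x)[3] < k) {
    stop("spatial size must be at least the pooling kernel", call. = FALSE)
  }
  maxpool2d_fw(x, k, stride, pad)$y
}

#' Plain 2-D convolution on a feature array
#'
#' Direct (non-deformable) convolution, exposed for use as an independent
#' reference in equivalence checks and for building one-off branches.
#'
#' @param x Numeric array `(C, H, W)`.
#' @param w Weights `(k, k, C/groups, Cout)`.
#' @param bias Optional length-`Cout` bias.
#' @param stride,pad,groups Convolution geometry.
#' @return Numeric array `(Cout, Ho, Wo)`.
#' @export
conv2d <- function(x, w, bias = NULL, stride = 1, pad = NULL, groups = 1) {
  k <- dim(w)[1]
  if (is.null(pad)) pad <- k %/% 2
  conv2d_fw(x, w, if (is.null(bias)) numeric() else bias, stride, pad, groups)
}

new_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- list()
  ctx$atoms <- list()
  ctx
}

# one fused multi-branch downsampling stage
mk_rfd_stage <- function(ctx, cin, cout, branches, act = "silu",
                         cut_groups = 1, conv_groups = 1, max_groups = 1) {
  cut <- if ("cut" %in% branches) {
    mk_conv(ctx, 1, 4 * cin, cout, groups = cut_groups, act = "none")
  }
  cnv <- if ("conv" %in% branches) {
    mk_conv(ctx, 3, cin, cout, stride = 2, groups = conv_groups, act = "none")
  }
  mx <- if ("max" %in% branches) {
    mk_conv(ctx, 1, cin, cout, groups = max_groups, act = "none")
  }
  list(cout = cout, fwd = function(x) {
    parts <- list()
    if (!is.null(cut)) parts <- c(parts, list(cut$fwd(ag_s2d(x))))
    if (!is.null(cnv)) parts <- c(parts, list(cnv$fwd(x)))
    if (!is.null(mx)) parts <- c(parts, list(mx$fwd(ag_maxpool(x, 3, 2, 1))))
    y <- parts[[1]]
    if (!is_shape(y)) for (p in parts[-1]) y <- ag_add(y, p)
    ag_act(y, act)
  })
}

# SRFD stem: 7x7 preliminary features at full resolution, then the two
# fused downsampling stages (1/2 with CutD+ConvD, 1/4 with CutD+ConvD+MaxD)
mk_srfd <- function(ctx, c_stem = 32L, c_mid = 16L, c_out = 32L) {
  stem <- mk_conv(ctx, 7, 3, c_stem)
  st1 <- mk_rfd_stage(ctx, c_stem, c_mid, c("cut", "conv"),
                      cut_groups = 8, conv_groups = 4)
  st2 <- mk_rfd_stage(ctx, c_mid, c_out, c("cut", "conv", "max"),
                      cut_groups = 8, conv_groups = 1, max_groups = 1)
  list(cout = c_out, fwd = function(x) {
    half <- st1$fwd(stem$fwd(x))
    list(half = half, quarter = st2$fwd(half))
  })
}

# DRFD deep downsampler; GELU after the three-branch fusion
mk_drfd <- function(ctx, cin, cout) {
  st <- mk_rfd_stage(ctx, cin, cout, c("cut", "conv", "max"), act = "gelu",
                     cut_groups = 1, conv_groups = 2, max_groups = 2)
  list(cout = cout, fwd = st$fwd)
}

check_even_spatial <- function(x, what) {
  d <- dim(x)
  if (d[2] %% 2 || d[3] %% 2) {
    stop(what, " requires even spatial size, got ", d[2], "x", d[3],
         call. = FALSE)
  }
  invisible()
}

#' Build a standalone SRFD stem
#'
#' The shallow robust feature downsampler: a 7x7 convolution extracts
#' preliminary features at full resolution, stage one halves the image with
#' parallel CutD and ConvD pathways, stage two reaches quarter resolution
#' with CutD, ConvD and MaxD branches. Branch outputs are normalized and
#' fused by addition.
#'
#' @param out_channels Output channels of the quarter-resolution map.
#' @param mid_channels Channels of the intermediate half-resolution map.
#' @param stem_channels Width of the 7x7 stem.
#' @param seed Seed for weight initialization.
#' @return An `srfd_block`.
#' @export
srfd_block <- function(out_channels = 32L, mid_channels = 16L,
                       stem_channels = 32L, seed = 0L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ctx <- new_ctx()
  blk <- mk_srfd(ctx, stem_channels, mid_channels, out_channels)
  structure(list(ctx = ctx, block = blk), class = "srfd_block")
}

#' Run an SRFD stem over an image tensor
#'
#' @param block An [srfd_block()].
#' @param x Numeric array `(3, H, W)`; `H` and `W` must be divisible by 4.
#' @return List with `half` (1/2 resolution) and `quarter` (1/4 resolution)
#'   feature arrays.
#' @export
srfd_forward <- function(block, x) {
  d <- dim(x)
  if (d[2] %% 4 || d[3] %% 4) {
    stop("SRFD requires spatial size divisible by 4", call. = FALSE)
  }
  block$block$fwd(x)
}

#' Build a standalone DRFD downsampler
#'
#' The deep robust feature downsampler: CutD, ConvD and MaxD branches fused
#' by addition with a GELU nonlinearity, halving the spatial size. In its
#' canonical configuration the channel count doubles
#' (`out_channels = 2 * in_channels`).
#'
#' @param in_channels,out_channels Channel counts.
#' @param seed Seed for weight initialization.
#' @return A `drfd_block`.
#' @export
drfd_block <- function(in_channels, out_channels = 2L * in_channels, seed = 0L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ctx <- new_ctx()
  blk <- mk_drfd(ctx, in_channels, out_channels)
  structure(list(ctx = ctx, block = blk, cin = in_channels,
                 cout = out_channels), class = "drfd_block")
}

#' Run a DRFD block
#'
#' @param block A [drfd_block()].
#' @param x Numeric array `(in_channels, H, W)` with even `H`, `W`.
#' @return Numeric array `(out_channels, H/2, W/2)`.
#' @export
drfd_forward <- function(block, x) {
  check_even_spatial(x, "DRFD")
  if (dim(x)[1] != block$cin) {
    stop("input has ", dim(x)[1], " channels; block expects ", block$cin,
         call. = FALSE)
  }
  block$block$fwd(x)
}
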