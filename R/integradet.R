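# Task-aligned dynamic detection head. A shared trunk (weights shared by
# all pyramid levels, GroupNorm-normalized) feeds two task-specific
# pathways: channel attention from globally pooled features decomposes the
# trunk output into regression- and classification-oriented views; the
# regression branch adapts its receptive field with modulated deformable
# convolution (DCNv2); the classification branch suppresses background with
# a sigmoid spatial-attention map; per-level learnable scalars reweight the
# contributions of the three scales.

#' Channel task attention from pooled features
#'
#' Squeeze-excitation realization of `A = sigma(W1 . delta(GAP(F)))`: the
#' feature map is globally average pooled, projected through a hidden layer
#' with an inner ReLU (the delta activation) and squashed by a sigmoid,
#' yielding one weight in (0, 1) per channel which multiplies the map.
#'
#' @param x Numeric array `(C, H, W)`.
#' @param hidden Hidden width of the squeeze projection.
#' @param params Optional list `(w1, b1, w2, b2)` with `w1: C x hidden`,
#'   `w2: hidden x C`; random Kaiming-uniform draws under `seed` if omitted.
#' @param seed Seed used when `params` is `NULL`.
#' @return List with `weights` (length `C`, all in (0, 1)) and `output`
#'   (the attended map `x * weights`).
#' @export
task_attention <- function(x, hidden = 26L, params = NULL, seed = 0L) {
  C <- dim(x)[1]
  if (is.null(params)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    params <- list(
      w1 = matrix(runif(C * hidden, -1, 1) / sqrt(C), C, hidden),
      b1 = numeric(hidden),
      w2 = matrix(runif(hidden * C, -1, 1) / sqrt(hidden), hidden, C),
      b2 = numeric(C)
    )
  }
  z <- rowMeans(matrix(x, C))
  h <- pmax(as.vector(crossprod(params$w1, z)) + params$b1, 0)
  a <- 1 / (1 + exp(-(as.vector(crossprod(params$w2, h)) + params$b2)))
  list(weights = a, output = x * a)
}

#' Sigmoid spatial attention
#'
#' `A_cls = sigma(Conv1x1(F))`: a single-channel map from a 1x1 convolution
#' squashed to (0, 1), broadcast-multiplied over all channels to suppress
#' background responses.
#'
#' @param x Numeric array `(C, H, W)`.
#' @param weights Optional length-`C` 1x1 kernel; random under `seed` when
#'   omitted.
#' @param bias Scalar bias.
#' @param seed Seed used when `weights` is `NULL`.
#' @return List with `map` (`1 x H x W`, values in (0, 1)) and `output`.
#' @export
spatial_attention <- function(x, weights = NULL, bias = 0, seed = 0L) {
  C <- dim(x)[1]
  if (is.null(weights)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    weights <- runif(C, -1, 1) / sqrt(C)
  }
  lin <- apply(x * weights, c(2, 3), sum) + bias
  m <- 1 / (1 + exp(-lin))
  out <- x * rep(1, C)  # copy
  for (c in seq_len(C)) out[c, , ] <- x[c, , ] * m
  list(map = array(m, dim = c(1, dim(x)[2], dim(x)[3])), output = out)
}

#' Modulated deformable convolution (DCNv2)
#'
#' Samples each kernel tap at its location plus a predicted offset using
#' bilinear interpolation, scales the sample by a per-tap modulation mask in
#' `[0, 1]`, and convolves. Out-of-bounds samples read as zero. With zero
#' offsets and unit masks this reduces exactly to the dense convolution
#' with the same weights.
#'
#' @param x Numeric array `(C, H, W)`.
#' @param field List with `offsets` (`2*k^2, H, W`; channel `2t` is the
#'   vertical and `2t+1` the horizontal displacement of tap `t`) and `mask`
#'   (`k^2, H, W`, values in `[0, 1]`).
#' @param weights `(k, k, C/groups, Cout)` kernel.
#' @param bias Optional length-`Cout` bias.
#' @param groups Channel groups.
#' @return Numeric array `(Cout, H, W)`.
#' @export
deformable_regression <- function(x, field, weights, bias = NULL, groups = 1) {
  k <- dim(weights)[1]
  d <- dim(x)
  if (!all(dim(field$offsets) == c(2 * k^2, d[2], d[3]))) {
    stop("offset field shape must be (2k^2, H, W)", call. = FALSE)
  }
  if (!all(dim(field$mask) == c(k^2, d[2], d[3]))) {
    stop("mask shape must be (k^2, H, W)", call. = FALSE)
  }
  dcn_fw(x, weights, if (is.null(bias)) numeric() else bias,
         field$offsets, field$mask, k %/% 2, groups)
}

#' Reweight per-level head outputs by learnable scale factors
#'
#' Per-level realization of the cross-scale integration
#' `Y = sum_i alpha_i Head_i`: each pyramid level's classification and
#' regression maps are multiplied by that level's scalar before decoding.
#'
#' @param outputs List of per-level outputs, each `list(reg = ..., cls = ...)`.
#' @param alphas Numeric vector, one scalar per level.
#' @return Outputs with each level scaled by its alpha.
#' @export
fuse_scales <- function(outputs, alphas) {
  if (length(alphas) != length(outputs)) {
    stop("need one scale weight per pyramid level", call. = FALSE)
  }
  purrr::map2(outputs, as.numeric(alphas), function(o, a) {
    list(reg = o$reg * a, cls = o$cls * a)
  })
}

# the trainable head module
mk_integradet <- function(ctx, nc, ch = c(64L, 128L, 256L), bins = 16L) {
  cw <- 32L   # trunk width
  bw <- 16L   # branch width
  hidden <- 26L
  projs <- lapply(ch, function(x) {
    mk_conv(ctx, 1, x, cw, norm = "none", bias = TRUE, act = "none")
  })
  trunk <- lapply(1:2, function(i) mk_conv(ctx, 3, cw, cw, norm = "gn"))
  se <- lapply(c("reg", "cls"), function(t) {
    list(l1 = mk_linear(ctx, cw, hidden), l2 = mk_linear(ctx, hidden, cw))
  })
  names(se) <- c("reg", "cls")
  tproj <- lapply(c("reg", "cls"), function(t) {
    mk_conv(ctx, 1, cw, bw, norm = "gn")
  })
  names(tproj) <- c("reg", "cls")
  tower <- lapply(c("reg", "cls"), function(t) mk_conv(ctx, 3, bw, bw, norm = "gn"))
  names(tower) <- c("reg", "cls")
  offc <- mk_conv(ctx, 3, bw, 27, norm = "none", bias = TRUE, act = "none",
                  zero_init = TRUE)
  register_atom(ctx, "dcn", 3, bw, bw, 2, "none", TRUE)
  dcn_w <- new_param(ctx, c(3, 3, bw / 2, bw), init = "kaiming", fan_in = 9 * bw / 2)
  dcn_b <- new_param(ctx, bw, init = "zeros")
  reg_out <- mk_conv(ctx, 1, bw, 4 * bins, norm = "none", bias = TRUE, act = "none")
  sattn <- mk_conv(ctx, 1, bw, 1, norm = "none", bias = TRUE, act = "none")
  cls_out <- mk_conv(ctx, 1, bw, nc, norm = "none", bias = TRUE, act = "none")
  # rare-object prior on the classification logits
  cls_out$params$b$value[] <- -log((1 - 0.01) / 0.01)
  alphas <- mk_scalars(ctx, 3, value = 1)
  dfl <- mk_dfl(ctx, bins)
  se_apply <- function(which, t) {
    z <- ag_gap(t)
    a <- ag_sigmoid(se[[which]]$l2$fwd(ag_relu(se[[which]]$l1$fwd(z))))
    ag_cmul(t, a)
  }
  list(
    nc = nc, bins = bins, dfl = dfl, alphas = alphas,
    fwd = function(pyr) {
      if (length(pyr) != 3) stop("head expects three pyramid levels", call. = FALSE)
      lapply(seq_along(pyr), function(l) {
        t <- projs[[l]]$fwd(pyr[[l]])
        for (tc in trunk) t <- tc$fwd(t)
        if (is_shape(t)) {
          # shape mode: execute every parametric op once per level
          se[["reg"]]$l1$fwd(agvshape(cw)); se[["reg"]]$l2$fwd(agvshape(hidden))
          se[["cls"]]$l1$fwd(agvshape(cw)); se[["cls"]]$l2$fwd(agvshape(hidden))
          r <- tower[["reg"]]$fwd(tproj[["reg"]]$fwd(t))
          offc$fwd(r)
          ag_dcn(r, dcn_w$value, NULL, NULL, NULL, 1, 2)
          reg <- reg_out$fwd(r)
          cl <- tower[["cls"]]$fwd(tproj[["cls"]]$fwd(t))
          sattn$fwd(cl)
          cls <- cls_out$fwd(cl)
          return(list(reg = reg, cls = cls))
        }
        tr <- se_apply("reg", t)
        tc <- se_apply("cls", t)
        r <- tower[["reg"]]$fwd(tproj[["reg"]]$fwd(tr))
        om <- offc$fwd(r)
        off <- ag_slice(om, 1:18)
        msk <- ag_sigmoid(ag_slice(om, 19:27))
        r2 <- ag_relu(ag_dcn(r, ag_param(dcn_w), ag_param(dcn_b), off, msk, 1, 2))
        reg <- ag_scale(reg_out$fwd(r2), slice_scalar(alphas, l))
        cl <- tower[["cls"]]$fwd(tproj[["cls"]]$fwd(tc))
        amap <- ag_sigmoid(sattn$fwd(cl))
        cls <- ag_scale(cls_out$fwd(ag_smul(cl, amap)), slice_scalar(alphas, l))
        list(reg = reg, cls = cls)
      })
    }
  )
}

# node view of one element of a scalar parameter vector; the gradient is
# scattered back into position i of the parameter
slice_scalar <- function(p, i) {
  if (!ag_recording()) return(p$value[i])
  n <- new_node(p$value[i], param = p)
  n$param_index <- i
  n
}
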