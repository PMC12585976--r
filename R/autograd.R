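# Minimal reverse-mode autodiff on dense arrays.
#
# Three execution modes share one forward code path:
#  * recording  — ops build tape nodes; ag_backward() runs the reverse sweep
#  * plain      — ops see raw arrays and just compute values (inference)
#  * shape      — ops see `agshape` descriptors; parametric ops accumulate
#                 their multiply-accumulate counts into the active collector,
#                 which is how FLOPs are derived without touching pixels
#
# Activations are (C, H, W) arrays; vectors are plain numeric vectors.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$macs <- NULL

ag_recording <- function() !is.null(.ag$tape)

ag_with_tape <- function(expr) {
  old <- .ag$tape
  .ag$tape <- list()
  on.exit(.ag$tape <- old, add = TRUE)
  value <- force(expr)
  list(value = value, tape = .ag$tape)
}

ag_start_tape <- function() .ag$tape <- list()
ag_clear_tape <- function() .ag$tape <- NULL

is_node <- function(x) inherits(x, "agnode")
is_shape <- function(x) inherits(x, "agshape")

agshape <- function(c, h, w) structure(list(c = c, h = h, w = w), class = "agshape")
agvshape <- function(len) structure(list(len = len), class = c("agshape", "agvshape"))

ag_val <- function(x) if (is_node(x)) x$value else x

new_node <- function(value, parents = list(), vjp = NULL, param = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$vjp <- vjp
  n$param <- param
  n$grad <- NULL
  class(n) <- "agnode"
  .ag$tape[[length(.ag$tape) + 1L]] <- n
  n
}

# wrap a parameter (env with $value, $grad) for the current mode
ag_param <- function(p) {
  if (!ag_recording()) return(p$value)
  new_node(p$value, param = p)
}

ag_leaf <- function(value) {
  if (!ag_recording()) return(value)
  new_node(value)
}

add_grad <- function(node, g) {
  if (!is_node(node)) return(invisible())
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible()
}

#' @noRd
ag_backward <- function(loss_node) {
  stopifnot(is_node(loss_node))
  loss_node$grad <- 1
  tape <- .ag$tape
  for (i in rev(seq_along(tape))) {
    n <- tape[[i]]
    if (is.null(n$grad)) next
    if (!is.null(n$param)) {
      p <- n$param
      if (is.null(n$param_index)) {
        p$grad <- if (is.null(p$grad)) n$grad else p$grad + n$grad
      } else {
        if (is.null(p$grad)) p$grad <- array(0, dim = dim(p$value) %||% length(p$value))
        p$grad[n$param_index] <- p$grad[n$param_index] + sum(n$grad)
      }
    }
    if (is.null(n$vjp) || !length(n$parents)) next
    gs <- n$vjp(n$grad)
    for (j in seq_along(n$parents)) {
      if (!is.null(gs[[j]])) add_grad(n$parents[[j]], gs[[j]])
    }
  }
  invisible()
}

ag_count_macs <- function(n) {
  if (!is.null(.ag$macs)) .ag$macs$total <- .ag$macs$total + n
  invisible()
}

ag_collect_macs <- function(expr) {
  old <- .ag$macs
  .ag$macs <- new.env(parent = emptyenv())
  .ag$macs$total <- 0
  on.exit(.ag$macs <- old, add = TRUE)
  force(expr)
  .ag$macs$total
}

# generic unary elementwise op helper
ag_unary <- function(x, f, df) {
  if (is_shape(x)) return(x)
  if (!is_node(x)) return(f(x))
  v <- f(x$value)
  new_node(v, list(x), function(g) list(g * df(x$value, v)))
}

ag_relu <- function(x) ag_unary(x, function(z) pmax(z, 0),
                                function(z, v) (z > 0) * 1)
ag_sigmoid <- function(x) ag_unary(x, function(z) 1 / (1 + exp(-z)),
                                   function(z, v) v * (1 - v))
ag_silu <- function(x) ag_unary(x, function(z) z / (1 + exp(-z)),
                                function(z, v) {
                                  s <- 1 / (1 + exp(-z)); s * (1 + z * (1 - s))
                                })
ag_gelu <- function(x) {
  # tanh approximation, as deployed detection stacks use
  k <- sqrt(2 / pi)
  ag_unary(x,
    function(z) 0.5 * z * (1 + tanh(k * (z + 0.044715 * z^3))),
    function(z, v) {
      t <- tanh(k * (z + 0.044715 * z^3))
      0.5 * (1 + t) + 0.5 * z * (1 - t^2) * k * (1 + 3 * 0.044715 * z^2)
    })
}

ag_act <- function(x, act) {
  switch(act,
         silu = ag_silu(x), gelu = ag_gelu(x), relu = ag_relu(x),
         sigmoid = ag_sigmoid(x), none = x,
         stop("unknown activation: ", act))
}

ag_add <- function(a, b) {
  if (is_shape(a)) return(a)
  if (!is_node(a) && !is_node(b)) return(a + b)
  new_node(ag_val(a) + ag_val(b), list(a, b), function(g) list(g, g))
}

# multiply an activation map by a per-channel vector (broadcast over H, W)
ag_cmul <- function(x, v) {
  if (is_shape(x)) return(x)
  xv <- ag_val(x); vv <- ag_val(v)
  out <- xv * as.vector(vv)  # recycling down the C-first dimension
  if (!is_node(x) && !is_node(v)) return(out)
  new_node(out, list(x, v), function(g) {
    gx <- g * as.vector(vv)
    gv <- rowSums(matrix(g * xv, dim(xv)[1]))
    list(gx, gv)
  })
}

# multiply an activation map by a single-channel spatial map (1, H, W)
ag_smul <- function(x, m) {
  if (is_shape(x)) return(x)
  xv <- ag_val(x); mv <- ag_val(m)
  C <- dim(xv)[1]
  mm <- array(rep(mv, each = C), dim = dim(xv))
  out <- xv * mm
  if (!is_node(x) && !is_node(m)) return(out)
  new_node(out, list(x, m), function(g) {
    gx <- g * mm
    gm <- array(colSums(matrix(g * xv, C)), dim = dim(mv))
    list(gx, gm)
  })
}

# multiply by a scalar parameter (the cross-scale alpha weights)
ag_scale <- function(x, s) {
  if (is_shape(x)) return(x)
  xv <- ag_val(x); sv <- ag_val(s)
  out <- xv * as.numeric(sv)
  if (!is_node(x) && !is_node(s)) return(out)
  new_node(out, list(x, s), function(g) list(g * as.numeric(sv), sum(g * xv)))
}

ag_concat <- function(xs) {
  if (is_shape(xs[[1]])) {
    return(agshape(sum(vapply(xs, function(s) s$c, 0)), xs[[1]]$h, xs[[1]]$w))
  }
  vals <- lapply(xs, ag_val)
  cs <- vapply(vals, function(v) dim(v)[1], 0)
  H <- dim(vals[[1]])[2]; W <- dim(vals[[1]])[3]
  out <- array(0, dim = c(sum(cs), H, W))
  at <- 0
  for (v in vals) { out[at + seq_len(dim(v)[1]), , ] <- v; at <- at + dim(v)[1] }
  if (!any(vapply(xs, is_node, TRUE))) return(out)
  new_node(out, xs, function(g) {
    at <- 0
    lapply(cs, function(ci) {
      sl <- g[at + seq_len(ci), , , drop = FALSE]
      at <<- at + ci
      sl
    })
  })
}

ag_slice <- function(x, idx) {
  if (is_shape(x)) return(agshape(length(idx), x$h, x$w))
  xv <- ag_val(x)
  out <- xv[idx, , , drop = FALSE]
  if (!is_node(x)) return(out)
  new_node(out, list(x), function(g) {
    gx <- array(0, dim = dim(xv))
    gx[idx, , ] <- g
    list(gx)
  })
}

# space-to-depth: (C,H,W) -> (4C, H/2, W/2); the rearrangement is a bijection
ag_s2d <- function(x) {
  if (is_shape(x)) {
    if (x$h %% 2 || x$w %% 2) stop("space-to-depth needs even spatial size")
    return(agshape(4 * x$c, x$h / 2, x$w / 2))
  }
  xv <- ag_val(x)
  d <- dim(xv)
  if (d[2] %% 2 || d[3] %% 2) {
    stop("space-to-depth needs even spatial size, got ",
         d[2], "x", d[3], call. = FALSE)
  }
  out <- s2d_fw_(xv)
  if (!is_node(x)) return(out)
  new_node(out, list(x), function(g) list(s2d_bw_(g, d)))
}

s2d_fw_ <- function(xv) {
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]
  # blocks ordered (top-left, bottom-left, top-right, bottom-right)
  out <- array(0, dim = c(4 * C, H / 2, W / 2))
  out[seq_len(C), , ] <- xv[, seq(1, H, 2), seq(1, W, 2), drop = FALSE]
  out[C + seq_len(C), , ] <- xv[, seq(2, H, 2), seq(1, W, 2), drop = FALSE]
  out[2 * C + seq_len(C), , ] <- xv[, seq(1, H, 2), seq(2, W, 2), drop = FALSE]
  out[3 * C + seq_len(C), , ] <- xv[, seq(2, H, 2), seq(2, W, 2), drop = FALSE]
  out
}

s2d_bw_ <- function(g, d) {
  C <- d[1]; H <- d[2]; W <- d[3]
  gx <- array(0, dim = d)
  gx[, seq(1, H, 2), seq(1, W, 2)] <- g[seq_len(C), , , drop = FALSE]
  gx[, seq(2, H, 2), seq(1, W, 2)] <- g[C + seq_len(C), , , drop = FALSE]
  gx[, seq(1, H, 2), seq(2, W, 2)] <- g[2 * C + seq_len(C), , , drop = FALSE]
  gx[, seq(2, H, 2), seq(2, W, 2)] <- g[3 * C + seq_len(C), , , drop = FALSE]
  gx
}

s2d_inverse <- function(y) s2d_bw_(y, c(dim(y)[1] / 4, dim(y)[2] * 2, dim(y)[3] * 2))

ag_conv <- function(x, w, b, stride, pad, groups) {
  if (is_shape(x)) {
    wd <- dim(ag_val(w))
    ho <- (x$h + 2 * pad - wd[1]) %/% stride + 1
    wo <- (x$w + 2 * pad - wd[1]) %/% stride + 1
    ag_count_macs(as.numeric(wd[1])^2 * wd[3] * wd[4] * ho * wo)
    return(agshape(wd[4], ho, wo))
  }
  xv <- ag_val(x); wv <- ag_val(w)
  bv <- if (is.null(b)) numeric() else ag_val(b)
  recording <- any(vapply(list(x, w, b), is_node, TRUE))
  if (!recording) return(conv2d_fw(xv, wv, bv, stride, pad, groups))
  # keep the im2col buffers so the backward pass skips re-gathering
  fw <- conv2d_fw_train(xv, wv, bv, stride, pad, groups)
  new_node(fw$y, list(x, w, b), function(g) {
    bw <- conv2d_bw_cached(fw$cols, wv, g, dim(xv), stride, pad, groups,
                           need_dx = is_node(x), has_bias = !is.null(b))
    list(if (is_node(x)) bw$dx else NULL, bw$dw,
         if (!is.null(b)) bw$db else NULL)
  })
}

ag_dcn <- function(x, w, b, off, mask, pad, groups) {
  if (is_shape(x)) {
    wd <- dim(ag_val(w))
    ag_count_macs(as.numeric(wd[1])^2 * wd[3] * wd[4] * x$h * x$w)
    return(agshape(wd[4], x$h, x$w))
  }
  xv <- ag_val(x); wv <- ag_val(w)
  bv <- if (is.null(b)) numeric() else ag_val(b)
  ov <- ag_val(off); mv <- ag_val(mask)
  out <- dcn_fw(xv, wv, bv, ov, mv, pad, groups)
  nodes <- Filter(is_node, list(x, w, b, off, mask))
  if (!length(nodes)) return(out)
  new_node(out, list(x, w, b, off, mask), function(g) {
    bw <- dcn_bw(xv, wv, ov, mv, g, pad, groups, has_bias = !is.null(b))
    list(bw$dx, bw$dw, if (!is.null(b)) bw$db else NULL, bw$doff, bw$dmask)
  })
}

ag_maxpool <- function(x, k, stride, pad) {
  if (is_shape(x)) {
    return(agshape(x$c, (x$h + 2 * pad - k) %/% stride + 1,
                   (x$w + 2 * pad - k) %/% stride + 1))
  }
  xv <- ag_val(x)
  fw <- maxpool2d_fw(xv, k, stride, pad)
  if (!is_node(x)) return(fw$y)
  new_node(fw$y, list(x), function(g) list(maxpool2d_bw(fw$idx, g, dim(xv))))
}

ag_upsample <- function(x) {
  if (is_shape(x)) return(agshape(x$c, 2 * x$h, 2 * x$w))
  xv <- ag_val(x)
  out <- upsample2x_fw(xv)
  if (!is_node(x)) return(out)
  new_node(out, list(x), function(g) list(upsample2x_bw(g, dim(xv))))
}

# per-sample group normalization over channel groups (+ spatial), with
# per-channel affine. groups = C gives the per-channel (instance) statistics
# the package uses in place of running batch statistics.
ag_norm <- function(x, gamma, beta, groups, eps = 1e-5) {
  if (is_shape(x)) return(x)
  xv <- ag_val(x); gv <- as.vector(ag_val(gamma)); bv <- as.vector(ag_val(beta))
  d <- dim(xv); C <- d[1]
  cg <- C / groups
  xm <- matrix(xv, C)                       # C x (H*W)
  n_per <- cg * ncol(xm)
  if (groups == C) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    inv <- 1 / sqrt(rowSums(xc^2) / n_per + eps)
    gi <- seq_len(C)
  } else {
    gi <- rep(seq_len(groups), each = cg)
    mu <- rowsum(rowSums(xm), gi) / n_per
    xc <- xm - mu[gi]
    inv <- 1 / sqrt(rowsum(rowSums(xc^2), gi) / n_per + eps)
  }
  xhat <- xc * inv[gi]
  out <- array(xhat * gv + bv, dim = d)
  if (!is_node(x) && !is_node(gamma) && !is_node(beta)) return(out)
  new_node(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, C)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    dxhat <- gm * gv
    if (groups == C) {
      s1 <- rowSums(dxhat)
      s2 <- rowSums(dxhat * xhat)
    } else {
      s1 <- rowsum(rowSums(dxhat), gi)
      s2 <- rowsum(rowSums(dxhat * xhat), gi)
    }
    dx <- (dxhat - (s1[gi] + xhat * s2[gi]) / n_per) * inv[gi]
    list(array(dx, dim = d), dgamma, dbeta)
  })
}

ag_gap <- function(x) {
  if (is_shape(x)) return(agvshape(x$c))
  xv <- ag_val(x)
  d <- dim(xv)
  out <- rowMeans(matrix(xv, d[1]))
  if (!is_node(x)) return(out)
  new_node(out, list(x), function(g) {
    list(array(rep(g / (d[2] * d[3]), d[2] * d[3]), dim = d))
  })
}

ag_linear <- function(v, w, b) {
  if (is_shape(v)) {
    wd <- dim(ag_val(w))
    ag_count_macs(as.numeric(wd[1]) * wd[2])
    return(agvshape(wd[2]))
  }
  vv <- ag_val(v); wv <- ag_val(w)
  bv <- if (is.null(b)) 0 else ag_val(b)
  out <- as.vector(crossprod(wv, vv)) + bv
  if (!is_node(v) && !is_node(w) && !is_node(b)) return(out)
  new_node(out, list(v, w, b), function(g) {
    list(as.vector(wv %*% g), outer(vv, g), if (!is.null(b)) g else NULL)
  })
}

# matrix product for the attention block: A (m x k) %*% B (k x n)
ag_matmul <- function(a, b) {
  if (is_shape(a)) return(a)
  av <- ag_val(a); bv <- ag_val(b)
  out <- av %*% bv
  if (!is_node(a) && !is_node(b)) return(out)
  new_node(out, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

ag_reshape <- function(x, dims) {
  if (is_shape(x)) return(x)
  xv <- ag_val(x)
  out <- array(xv, dim = dims)
  if (!is_node(x)) return(out)
  new_node(out, list(x), function(g) list(array(g, dim = dim(xv))))
}

ag_transpose <- function(x) {
  if (is_shape(x)) return(x)
  xv <- ag_val(x)
  out <- t(xv)
  if (!is_node(x)) return(out)
  new_node(out, list(x), function(g) list(t(g)))
}

# column-wise softmax of a matrix
ag_softmax_cols <- function(x, scale = 1) {
  if (is_shape(x)) return(x)
  xv <- ag_val(x) * scale
  mx <- xv[cbind(max.col(t(xv), ties.method = "first"), seq_len(ncol(xv)))]
  e <- exp(sweep(xv, 2, mx))
  out <- sweep(e, 2, colSums(e), "/")
  if (!is_node(x)) return(out)
  new_node(out, list(x), function(g) {
    list(scale * out * sweep(g, 2, colSums(g * out)))
  })
}

# gather per-cell feature columns from a (C, H, W) map: returns C x n matrix
ag_gather_cells <- function(x, cell_idx) {
  if (is_shape(x)) return(x)
  xv <- ag_val(x)
  d <- dim(xv)
  xm <- matrix(xv, d[1])
  out <- xm[, cell_idx, drop = FALSE]
  if (!is_node(x)) return(out)
  new_node(out, list(x), function(g) {
    gm <- matrix(0, d[1], d[2] * d[3])
    for (j in seq_along(cell_idx)) {
      gm[, cell_idx[j]] <- gm[, cell_idx[j]] + g[, j]
    }
    list(array(gm, dim = d))
  })
}

ag_sum <- function(x) {
  if (is_shape(x)) return(agvshape(1))
  xv <- ag_val(x)
  out <- sum(xv)
  if (!is_node(x)) return(out)
  new_node(out, list(x), function(g) list(array(g, dim = dim(xv) %||% length(xv))))
}

ag_add_any <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  if (!is_node(a) && !is_node(b)) return(av + bv)
  new_node(av + bv, list(a, b), function(g) list(g, g))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# binary cross-entropy with logits, per-element weights; mean over elements
# divided by `norm`. A fused primitive keeps the backward numerically exact.
ag_bce_logits <- function(logits, targets, weights = 1, norm = 1) {
  lv <- ag_val(logits)
  p <- 1 / (1 + exp(-lv))
  eps <- 1e-12
  loss <- -sum(weights * (targets * log(p + eps) +
                            (1 - targets) * log(1 - p + eps))) / norm
  if (!is_node(logits)) return(loss)
  new_node(loss, list(logits), function(g) {
    list(g * weights * (p - targets) / norm)
  })
}
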