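# Layer constructors. Every parametric layer registers an "atom" descriptor
# (kind, kernel, channels, groups, normalization, bias) with the owning model
# context; parameter counting and the FLOPs audit read those descriptors, so
# the audited numbers always describe the graph that actually runs.

new_param <- function(ctx, dim, init = c("kaiming", "zeros", "ones", "scalar"),
                      fan_in = NULL, value = NULL, trainable = TRUE) {
  init <- match.arg(init)
  p <- new.env(parent = emptyenv())
  if (!is.null(value)) {
    p$value <- value
  } else {
    p$value <- switch(init,
      kaiming = {
        bound <- 1 / sqrt(fan_in)
        array(runif(prod(dim), -bound, bound), dim = dim)
      },
      zeros = array(0, dim = dim),
      ones = array(1, dim = dim),
      scalar = array(1, dim = dim)
    )
  }
  p$grad <- NULL
  p$trainable <- trainable
  ctx$params[[length(ctx$params) + 1L]] <- p
  p
}

register_atom <- function(ctx, kind, k = 0, cin = 0, cout = 0, groups = 1,
                          norm = "none", bias = FALSE, n = 0) {
  ctx$atoms[[length(ctx$atoms) + 1L]] <-
    list(kind = kind, k = k, cin = cin, cout = cout, groups = groups,
         norm = norm, bias = bias, n = n)
  invisible()
}

atom_count <- function(a, fused = TRUE) {
  switch(a$kind,
    conv = ,
    dcn = {
      w <- a$k^2 * a$cin * a$cout / a$groups
      extra <- if (a$norm == "bn") {
        if (fused) a$cout else 2 * a$cout
      } else if (a$norm == "gn") {
        2 * a$cout
      } else if (a$bias) a$cout else 0
      w + extra
    },
    linear = a$cin * a$cout + if (a$bias) a$cout else 0,
    scalars = a$n,
    dfl = a$n
  )
}

#' @noRd
mk_conv <- function(ctx, k, cin, cout, stride = 1, groups = 1,
                    norm = c("bn", "gn", "none"), act = "silu",
                    bias = FALSE, gn_groups = 16, pad = NULL,
                    zero_init = FALSE) {
  norm <- match.arg(norm)
  if (cin %% groups || cout %% groups) {
    stop("groups must divide both channel counts (", cin, "->", cout,
         " g=", groups, ")", call. = FALSE)
  }
  if (is.null(pad)) pad <- k %/% 2
  register_atom(ctx, "conv", k, cin, cout, groups, norm, bias)
  w <- new_param(ctx, c(k, k, cin / groups, cout),
                 init = if (zero_init) "zeros" else "kaiming",
                 fan_in = k^2 * cin / groups)
  b <- if (bias) new_param(ctx, cout, init = "zeros") else NULL
  gamma <- beta <- NULL
  if (norm != "none") {
    gamma <- new_param(ctx, cout, init = "ones")
    beta <- new_param(ctx, cout, init = "zeros")
  }
  ng <- if (norm == "gn") {
    g <- gn_groups
    while (cout %% g) g <- g %/% 2   # largest power-of-two divisor <= gn_groups
    g
  } else cout
  list(
    cout = cout,
    fwd = function(x) {
      y <- ag_conv(x, ag_param(w), if (is.null(b)) NULL else ag_param(b),
                   stride, pad, groups)
      if (norm != "none" && !is_shape(y)) {
        y <- ag_norm(y, ag_param(gamma), ag_param(beta), ng)
      }
      ag_act(y, act)
    },
    params = list(w = w, b = b, gamma = gamma, beta = beta)
  )
}

mk_linear <- function(ctx, cin, cout, bias = TRUE) {
  register_atom(ctx, "linear", cin = cin, cout = cout, bias = bias)
  w <- new_param(ctx, c(cin, cout), init = "kaiming", fan_in = cin)
  b <- if (bias) new_param(ctx, cout, init = "zeros") else NULL
  list(fwd = function(v) ag_linear(v, ag_param(w),
                                   if (is.null(b)) NULL else ag_param(b)),
       params = list(w = w, b = b))
}

mk_scalars <- function(ctx, n, value = 1) {
  register_atom(ctx, "scalars", n = n)
  new_param(ctx, n, value = array(value, n))
}

mk_dfl <- function(ctx, bins = 16) {
  register_atom(ctx, "dfl", n = bins)
  new_param(ctx, bins, value = array(seq_len(bins) - 1, bins), trainable = FALSE)
}

# ---- YOLO11 family blocks -------------------------------------------------

mk_bottleneck <- function(ctx, cin, cout, shortcut = TRUE, k = c(3, 3), e = 0.5) {
  c_ <- as.integer(cout * e)
  cv1 <- mk_conv(ctx, k[1], cin, c_)
  cv2 <- mk_conv(ctx, k[2], c_, cout)
  add <- shortcut && cin == cout
  list(cout = cout, fwd = function(x) {
    y <- cv2$fwd(cv1$fwd(x))
    if (add) ag_add(x, y) else y
  })
}

mk_c3k <- function(ctx, cin, cout, n = 2, e = 0.5) {
  c_ <- as.integer(cout * e)
  cv1 <- mk_conv(ctx, 1, cin, c_)
  cv2 <- mk_conv(ctx, 1, cin, c_)
  cv3 <- mk_conv(ctx, 1, 2 * c_, cout)
  ms <- lapply(seq_len(n), function(i) mk_bottleneck(ctx, c_, c_, TRUE, c(3, 3), 1.0))
  list(cout = cout, fwd = function(x) {
    a <- cv1$fwd(x)
    for (m in ms) a <- m$fwd(a)
    cv3$fwd(ag_concat(list(a, cv2$fwd(x))))
  })
}

mk_c3k2 <- function(ctx, cin, cout, n = 1, c3k = FALSE, e = 0.5) {
  c_ <- as.integer(cout * e)
  cv1 <- mk_conv(ctx, 1, cin, 2 * c_)
  cv2 <- mk_conv(ctx, 1, (2 + n) * c_, cout)
  ms <- lapply(seq_len(n), function(i) {
    if (c3k) mk_c3k(ctx, c_, c_, 2) else mk_bottleneck(ctx, c_, c_, TRUE, c(3, 3), 0.5)
  })
  list(cout = cout, fwd = function(x) {
    y <- cv1$fwd(x)
    if (is_shape(y)) {
      parts <- list(agshape(c_, y$h, y$w), agshape(c_, y$h, y$w))
    } else {
      parts <- list(ag_slice(y, seq_len(c_)), ag_slice(y, c_ + seq_len(c_)))
    }
    for (m in ms) parts[[length(parts) + 1L]] <- m$fwd(parts[[length(parts)]])
    cv2$fwd(ag_concat(parts))
  })
}

mk_sppf <- function(ctx, cin, cout, k = 5) {
  c_ <- cin %/% 2
  cv1 <- mk_conv(ctx, 1, cin, c_)
  cv2 <- mk_conv(ctx, 1, c_ * 4, cout)
  list(cout = cout, fwd = function(x) {
    a <- cv1$fwd(x)
    p1 <- ag_maxpool(a, k, 1, k %/% 2)
    p2 <- ag_maxpool(p1, k, 1, k %/% 2)
    p3 <- ag_maxpool(p2, k, 1, k %/% 2)
    cv2$fwd(ag_concat(list(a, p1, p2, p3)))
  })
}

mk_attention <- function(ctx, dim, num_heads) {
  head_dim <- dim %/% num_heads
  key_dim <- head_dim %/% 2
  h <- dim + 2 * key_dim * num_heads
  qkv <- mk_conv(ctx, 1, dim, h, act = "none")
  proj <- mk_conv(ctx, 1, dim, dim, act = "none")
  pe <- mk_conv(ctx, 3, dim, dim, groups = dim, act = "none")
  scale <- 1 / sqrt(key_dim)
  list(cout = dim, fwd = function(x) {
    y <- qkv$fwd(x)
    if (is_shape(y)) {
      pe$fwd(agshape(dim, x$h, x$w))
      return(proj$fwd(agshape(dim, x$h, x$w)))
    }
    d <- dim(ag_val(y))
    hw <- d[2] * d[3]
    per <- 2 * key_dim + head_dim
    outs <- vector("list", num_heads)
    vs <- vector("list", num_heads)
    for (hd in seq_len(num_heads)) {
      base <- (hd - 1) * per
      q <- ag_reshape(ag_slice(y, base + seq_len(key_dim)), c(key_dim, hw))
      kk <- ag_reshape(ag_slice(y, base + key_dim + seq_len(key_dim)), c(key_dim, hw))
      vsl <- ag_slice(y, base + 2 * key_dim + seq_len(head_dim))
      vs[[hd]] <- vsl
      v <- ag_reshape(vsl, c(head_dim, hw))
      # columns index queries, rows keys; column softmax normalizes over keys
      att <- ag_softmax_cols(ag_matmul(ag_transpose(kk), q), scale = scale)
      outs[[hd]] <- ag_reshape(ag_matmul(v, att), c(head_dim, d[2], d[3]))
    }
    vout <- ag_concat(outs)
    proj$fwd(ag_add(vout, pe$fwd(ag_concat(vs))))
  })
}

mk_psablock <- function(ctx, c) {
  attn <- mk_attention(ctx, c, max(1L, c %/% 64L))
  ffn1 <- mk_conv(ctx, 1, c, 2 * c)
  ffn2 <- mk_conv(ctx, 1, 2 * c, c, act = "none")
  list(cout = c, fwd = function(x) {
    x <- if (is_shape(x)) attn$fwd(x) else ag_add(x, attn$fwd(x))
    y <- ffn2$fwd(ffn1$fwd(x))
    if (is_shape(x)) y else ag_add(x, y)
  })
}

mk_c2psa <- function(ctx, cin, cout, n = 1) {
  c_ <- cin %/% 2
  cv1 <- mk_conv(ctx, 1, cin, 2 * c_)
  cv2 <- mk_conv(ctx, 1, 2 * c_, cin)
  blocks <- lapply(seq_len(n), function(i) mk_psablock(ctx, c_))
  list(cout = cout, fwd = function(x) {
    y <- cv1$fwd(x)
    if (is_shape(y)) {
      a <- agshape(c_, y$h, y$w)
      for (bl in blocks) a <- bl$fwd(a)
      return(cv2$fwd(agshape(2 * c_, y$h, y$w)))
    }
    a <- ag_slice(y, seq_len(c_))
    b <- ag_slice(y, c_ + seq_len(c_))
    for (bl in blocks) b <- bl$fwd(b)
    cv2$fwd(ag_concat(list(a, b)))
  })
}
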