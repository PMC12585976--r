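# Training and evaluation harness: box decoding, non-maximum suppression,
# task-aligned target assignment, the composite detection loss
# (IoU + distributional focal + binary cross-entropy), and a plain
# SGD-with-momentum loop.

#' Training configuration
#'
#' Defaults follow the single-stage detector family's standard recipe:
#' SGD with momentum 0.937, initial learning rate 0.01, batch size 16,
#' 640 px inputs.
#'
#' @param epochs Training epochs.
#' @param batch_size Images per optimizer step.
#' @param lr Initial learning rate.
#' @param momentum SGD momentum.
#' @param image_size Square input size (divisible by 32).
#' @param seed Seed controlling shuffling and initialization.
#' @param warmup_epochs Epochs of linear learning-rate warmup.
#' @param workers Data-loading workers (kept for interface parity; loading
#'   is synchronous here).
#' @param lr_schedule `"hold-decay"` (constant rate, cosine decay to 10%
#'   over the final quarter) or `"constant"`.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 16L, lr = 0.01,
                         momentum = 0.937, image_size = 640L, seed = 0L,
                         warmup_epochs = 3L, workers = 8L,
                         lr_schedule = c("hold-decay", "constant")) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, image_size %% 32 == 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, image_size = as.integer(image_size),
                 seed = as.integer(seed), warmup_epochs = warmup_epochs,
                 workers = as.integer(workers), optimizer = "sgd",
                 ema_decay = 0.995, lr_schedule = lr_schedule),
            class = "train_config")
}

.anchor_cache <- new.env(parent = emptyenv())

# anchor cell centres (pixels) for the three pyramid levels; memoized
anchor_table <- function(image_size, strides = c(8L, 16L, 32L)) {
  key <- paste(image_size, paste(strides, collapse = "-"))
  if (!is.null(.anchor_cache[[key]])) return(.anchor_cache[[key]])
  out <- anchor_table_build(image_size, strides)
  .anchor_cache[[key]] <- out
  out
}

anchor_table_build <- function(image_size, strides) {
  purrr::map_dfr(seq_along(strides), function(l) {
    s <- strides[l]
    n <- image_size %/% s
    # column order matches matrix(x, C): h fastest, then w
    grid <- expand.grid(h = seq_len(n) - 1, w = seq_len(n) - 1)
    grid <- grid[order(grid$w, grid$h), ]
    tibble::tibble(level = l, stride = s,
                   cell = seq_len(n * n),
                   ax = (grid$w + 0.5) * s, ay = (grid$h + 0.5) * s)
  })
}

# distributional decode: reg logits (4*bins, H, W) -> distances matrix 4 x P
decode_distances <- function(reg, bins = 16L) {
  d <- dim(reg)
  m <- matrix(reg, d[1])                 # (4*bins) x P
  z <- array(m, dim = c(bins, 4 * ncol(m)))
  mx <- z[cbind(max.col(t(z), ties.method = "first"), seq_len(ncol(z)))]
  e <- exp(sweep(z, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  matrix(colSums(p * (seq_len(bins) - 1)), 4)   # 4 x P (l, t, r, b)
}

# decode raw per-level outputs into a detection tibble (normalized boxes)
decode_predictions <- function(outputs, image_size, nc, bins = 16L,
                               conf_threshold = 0.001, nms_iou = 0.7,
                               max_det = 300L, strides = c(8L, 16L, 32L)) {
  rows <- purrr::map_dfr(seq_along(outputs), function(l) {
    reg <- ag_val(outputs[[l]]$reg)
    cls <- ag_val(outputs[[l]]$cls)
    s <- strides[l]
    n <- dim(reg)[2]
    dist <- decode_distances(reg, bins)   # 4 x P, grid units
    cm <- matrix(cls, dim(cls)[1])        # nc x P
    probs <- 1 / (1 + exp(-cm))
    grid <- expand.grid(h = seq_len(n) - 1, w = seq_len(dim(reg)[3]) - 1)
    ax <- (grid$w + 0.5) * s
    ay <- (grid$h + 0.5) * s
    best <- apply(probs, 2, which.max)
    conf <- probs[cbind(best, seq_len(ncol(probs)))]
    keep <- which(conf >= conf_threshold)
    if (!length(keep)) return(NULL)
    x1 <- ax[keep] - dist[1, keep] * s
    y1 <- ay[keep] - dist[2, keep] * s
    x2 <- ax[keep] + dist[3, keep] * s
    y2 <- ay[keep] + dist[4, keep] * s
    tibble::tibble(
      class_id = best[keep] - 1L,
      cx = (x1 + x2) / 2 / image_size, cy = (y1 + y2) / 2 / image_size,
      w = pmax(x2 - x1, 1) / image_size, h = pmax(y2 - y1, 1) / image_size,
      conf = conf[keep]
    )
  })
  if (is.null(rows) || !nrow(rows)) {
    return(box_labels(conf = numeric()))
  }
  rows$cx <- pmin(1, pmax(0, rows$cx)); rows$cy <- pmin(1, pmax(0, rows$cy))
  rows$w <- pmin(1, rows$w); rows$h <- pmin(1, rows$h)
  out <- nms(rows, nms_iou)
  head(out[order(-out$conf), , drop = FALSE], max_det)
}

#' Per-class non-maximum suppression
#'
#' Greedy removal of lower-confidence detections overlapping a kept
#' detection of the same class above the IoU threshold.
#'
#' @param dets Detection tibble.
#' @param iou_threshold Overlap threshold.
#' @return Filtered detection tibble.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  if (!nrow(dets)) return(dets)
  keep <- logical(nrow(dets))
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    idx <- idx[order(-dets$conf[idx])]
    while (length(idx)) {
      i <- idx[1]
      keep[i] <- TRUE
      idx <- idx[-1]
      if (length(idx)) {
        ious <- iou_matrix(dets[i, , drop = FALSE], dets[idx, , drop = FALSE])
        idx <- idx[ious[1, ] < iou_threshold]
      }
    }
  }
  dets[keep, , drop = FALSE]
}

# ---- task-aligned assignment ----------------------------------------------

# gts: normalized labels for one image; preds: decoded value-level info
tal_assign <- function(gt, anchors, dist_val, cls_prob, image_size,
                       topk = 10L, alpha = 0.5, beta = 6.0) {
  n_gt <- nrow(gt)
  n_cells <- nrow(anchors)
  if (!n_gt) {
    return(list(cells = integer(), gt_idx = integer(), weight = numeric()))
  }
  gx1 <- (gt$cx - gt$w / 2) * image_size
  gy1 <- (gt$cy - gt$h / 2) * image_size
  gx2 <- (gt$cx + gt$w / 2) * image_size
  gy2 <- (gt$cy + gt$h / 2) * image_size
  px1 <- anchors$ax - dist_val[1, ] * anchors$stride
  py1 <- anchors$ay - dist_val[2, ] * anchors$stride
  px2 <- anchors$ax + dist_val[3, ] * anchors$stride
  py2 <- anchors$ay + dist_val[4, ] * anchors$stride
  assign_gt <- integer(n_cells)
  assign_metric <- numeric(n_cells)
  assign_iou <- numeric(n_cells)
  for (g in seq_len(n_gt)) {
    inside <- which(anchors$ax >= gx1[g] & anchors$ax <= gx2[g] &
                      anchors$ay >= gy1[g] & anchors$ay <= gy2[g])
    if (!length(inside)) next
    ix <- pmax(0, pmin(px2[inside], gx2[g]) - pmax(px1[inside], gx1[g]))
    iy <- pmax(0, pmin(py2[inside], gy2[g]) - pmax(py1[inside], gy1[g]))
    inter <- ix * iy
    area_p <- pmax(0, px2[inside] - px1[inside]) * pmax(0, py2[inside] - py1[inside])
    area_g <- (gx2[g] - gx1[g]) * (gy2[g] - gy1[g])
    iou_g <- ifelse(area_p + area_g - inter > 0,
                    inter / (area_p + area_g - inter), 0)
    s <- cls_prob[cbind(gt$class_id[g] + 1L, inside)]
    metric <- s^alpha * iou_g^beta
    sel <- inside[order(-metric)[seq_len(min(topk, length(inside)))]]
    msel <- metric[match(sel, inside)]
    isel <- iou_g[match(sel, inside)]
    for (j in seq_along(sel)) {
      cell <- sel[j]
      # a cell contested by several objects goes to the higher-IoU one
      if (assign_gt[cell] == 0L || isel[j] > assign_iou[cell]) {
        assign_gt[cell] <- g
        assign_metric[cell] <- msel[j]
        assign_iou[cell] <- isel[j]
      }
    }
  }
  cells <- which(assign_gt > 0L)
  if (!length(cells)) {
    return(list(cells = integer(), gt_idx = integer(), weight = numeric()))
  }
  gt_idx <- assign_gt[cells]
  # normalize the alignment metric per object and rescale by its best IoU
  w <- assign_metric[cells]
  for (g in unique(gt_idx)) {
    sel <- gt_idx == g
    mmax <- max(w[sel])
    imax <- max(assign_iou[cells][sel])
    w[sel] <- if (mmax > 0) w[sel] / mmax * imax else 0
  }
  list(cells = cells, gt_idx = gt_idx, weight = w)
}

# IoU loss with analytic gradient wrt the four side distances (grid units)
ag_iou_loss <- function(dist_node, anchors_sub, gt_box_px, weights, norm) {
  dv <- ag_val(dist_node)               # 4 x n
  s <- anchors_sub$stride
  ax <- anchors_sub$ax; ay <- anchors_sub$ay
  x1 <- ax - dv[1, ] * s; y1 <- ay - dv[2, ] * s
  x2 <- ax + dv[3, ] * s; y2 <- ay + dv[4, ] * s
  g <- gt_box_px                         # matrix n x 4 (x1,y1,x2,y2)
  ix1 <- pmax(x1, g[, 1]); iy1 <- pmax(y1, g[, 2])
  ix2 <- pmin(x2, g[, 3]); iy2 <- pmin(y2, g[, 4])
  iw <- pmax(0, ix2 - ix1); ih <- pmax(0, iy2 - iy1)
  inter <- iw * ih
  area_p <- pmax(0, x2 - x1) * pmax(0, y2 - y1)
  area_g <- (g[, 3] - g[, 1]) * (g[, 4] - g[, 2])
  union <- area_p + area_g - inter
  iou_v <- ifelse(union > 0, inter / union, 0)
  loss <- sum(weights * (1 - iou_v)) / norm
  if (!is_node(dist_node)) return(loss)
  new_node(loss, list(dist_node), function(gout) {
    # d iou / d corners
    dI_dx1 <- ifelse(iw > 0 & ih > 0 & x1 > g[, 1], -ih, 0)
    dI_dy1 <- ifelse(iw > 0 & ih > 0 & y1 > g[, 2], -iw, 0)
    dI_dx2 <- ifelse(iw > 0 & ih > 0 & x2 < g[, 3], ih, 0)
    dI_dy2 <- ifelse(iw > 0 & ih > 0 & y2 < g[, 4], iw, 0)
    dA_dx1 <- -(y2 - y1); dA_dy1 <- -(x2 - x1)
    dA_dx2 <- (y2 - y1); dA_dy2 <- (x2 - x1)
    safe_u <- pmax(union, 1e-9)
    diou <- function(dI, dA) (dI * safe_u - inter * (dA - dI)) / safe_u^2
    gx1 <- diou(dI_dx1, dA_dx1); gy1 <- diou(dI_dy1, dA_dy1)
    gx2 <- diou(dI_dx2, dA_dx2); gy2 <- diou(dI_dy2, dA_dy2)
    coef <- -gout * weights / norm       # d loss / d iou = -w/norm
    gd <- rbind(-gx1 * s, -gy1 * s, gx2 * s, gy2 * s) *
      rep(coef, each = 4)
    list(gd)
  })
}

# distributional focal loss on gathered regression logits
ag_dfl_loss <- function(reg_node, target_dist, weights, norm, bins = 16L) {
  zv <- ag_val(reg_node)                 # (4*bins) x n
  n <- ncol(zv)
  z <- array(zv, dim = c(bins, 4 * n))
  t <- pmin(pmax(as.vector(target_dist), 0), bins - 1 - 1e-3)  # length 4n
  tl <- floor(t); tr <- tl + 1
  wl <- tr - t; wr <- t - tl
  mx <- apply(z, 2, max)
  e <- exp(sweep(z, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  idx_l <- cbind(tl + 1, seq_len(4 * n))
  idx_r <- cbind(pmin(tr + 1, bins), seq_len(4 * n))
  wcell <- rep(weights, each = 4)
  loss <- -sum(wcell * (wl * log(p[idx_l] + 1e-12) +
                          wr * log(p[idx_r] + 1e-12))) / norm
  if (!is_node(reg_node)) return(loss)
  new_node(loss, list(reg_node), function(g) {
    tgt <- matrix(0, bins, 4 * n)
    tgt[idx_l] <- tgt[idx_l] + wl
    tgt[idx_r] <- tgt[idx_r] + wr
    gz <- sweep(p, 2, colSums(tgt), "*") - tgt
    gz <- sweep(gz, 2, wcell, "*") * g / norm
    list(array(gz, dim = dim(zv)))
  })
}

# loss for one image; outputs are tape nodes
detection_loss <- function(outputs, gt, image_size, nc, bins = 16L,
                           strides = c(8L, 16L, 32L),
                           w_box = 7.5, w_cls = 0.5, w_dfl = 1.5,
                           fixed_assignment = NULL) {
  anchors <- anchor_table(image_size, strides)
  asg <- if (!is.null(fixed_assignment)) fixed_assignment else {
    dist_val <- do.call(cbind, lapply(outputs, function(o) {
      decode_distances(ag_val(o$reg), bins)
    }))
    cls_prob <- do.call(cbind, lapply(outputs, function(o) {
      v <- ag_val(o$cls); 1 / (1 + exp(-matrix(v, dim(v)[1])))
    }))
    tal_assign(gt, anchors, dist_val, cls_prob, image_size)
  }
  norm <- max(sum(asg$weight), 1)
  # classification targets, dense per level
  level_sizes <- vapply(outputs, function(o) prod(dim(ag_val(o$cls))[2:3]), 0)
  offsets <- c(0, cumsum(level_sizes))
  loss <- NULL
  for (l in seq_along(outputs)) {
    clsn <- outputs[[l]]$cls
    dcls <- dim(ag_val(clsn))
    tgt <- array(0, dim = dcls)
    in_l <- which(asg$cells > offsets[l] & asg$cells <= offsets[l + 1])
    if (length(in_l)) {
      local_cells <- asg$cells[in_l] - offsets[l]
      tm <- matrix(0, dcls[1], dcls[2] * dcls[3])
      tm[cbind(gt$class_id[asg$gt_idx[in_l]] + 1L, local_cells)] <- asg$weight[in_l]
      tgt <- array(tm, dim = dcls)
    }
    lc <- ag_bce_logits(clsn, tgt, weights = 1, norm = norm)
    lc <- if (is_node(lc)) lc else ag_leaf(lc)
    loss <- if (is.null(loss)) lc else ag_add_any(loss, lc)
  }
  cls_loss_val <- ag_val(loss)
  box_loss_val <- 0; dfl_loss_val <- 0
  if (length(asg$cells)) {
    gx1 <- (gt$cx - gt$w / 2) * image_size
    gy1 <- (gt$cy - gt$h / 2) * image_size
    gx2 <- (gt$cx + gt$w / 2) * image_size
    gy2 <- (gt$cy + gt$h / 2) * image_size
    total_box <- NULL; total_dfl <- NULL
    for (l in seq_along(outputs)) {
      in_l <- which(asg$cells > offsets[l] & asg$cells <= offsets[l + 1])
      if (!length(in_l)) next
      local_cells <- asg$cells[in_l] - offsets[l]
      gidx <- asg$gt_idx[in_l]
      wts <- asg$weight[in_l]
      anch <- anchors[anchors$level == l, ][local_cells, ]
      reg_g <- ag_gather_cells(outputs[[l]]$reg, local_cells)  # (4*bins) x n
      z <- ag_reshape(reg_g, c(bins, 4 * length(in_l)))
      sm <- ag_softmax_cols(z)
      expect <- ag_matmul(matrix(seq_len(bins) - 1, 1), sm)    # 1 x 4n
      dist_n <- ag_reshape(expect, c(4, length(in_l)))
      gbox <- cbind(gx1[gidx], gy1[gidx], gx2[gidx], gy2[gidx])
      lb <- ag_iou_loss(dist_n, anch, gbox, wts, norm)
      # integer-bin regression targets (distances in grid units)
      tdist <- rbind((anch$ax - gbox[, 1]) / anch$stride,
                     (anch$ay - gbox[, 2]) / anch$stride,
                     (gbox[, 3] - anch$ax) / anch$stride,
                     (gbox[, 4] - anch$ay) / anch$stride)
      ld <- ag_dfl_loss(reg_g, tdist, wts, norm, bins)
      total_box <- if (is.null(total_box)) lb else ag_add_any(total_box, lb)
      total_dfl <- if (is.null(total_dfl)) ld else ag_add_any(total_dfl, ld)
    }
    if (!is.null(total_box)) {
      box_loss_val <- ag_val(total_box)
      dfl_loss_val <- ag_val(total_dfl)
      loss <- ag_add_any(ag_scale_const(loss, w_cls),
                         ag_add_any(ag_scale_const(total_box, w_box),
                                    ag_scale_const(total_dfl, w_dfl)))
    } else {
      loss <- ag_scale_const(loss, w_cls)
    }
  } else {
    loss <- ag_scale_const(loss, w_cls)
  }
  list(loss = loss,
       parts = c(box = box_loss_val, cls = cls_loss_val, dfl = dfl_loss_val),
       n_assigned = length(asg$cells))
}

ag_scale_const <- function(x, k) {
  if (!is_node(x)) return(x * k)
  new_node(ag_val(x) * k, list(x), function(g) list(g * k))
}

# ---- optimizer ------------------------------------------------------------

sgd_step <- function(model, lr, momentum) {
  for (p in model$ctx$params) {
    if (!isTRUE(p$trainable) || is.null(p$grad)) next
    if (is.null(p$mom)) p$mom <- p$grad * 0
    p$mom <- momentum * p$mom + p$grad
    p$value <- p$value - lr * p$mom
  }
  invisible()
}

zero_grads <- function(model) {
  for (p in model$ctx$params) p$grad <- NULL
  invisible()
}

# exponential moving average of the weights, the standard evaluation
# stabilizer for single-stage detectors
ema_update <- function(model, decay) {
  for (p in model$ctx$params) {
    if (!isTRUE(p$trainable)) next
    if (is.null(p$ema)) p$ema <- p$value
    p$ema <- decay * p$ema + (1 - decay) * p$value
  }
  invisible()
}

# swap EMA weights in (returns a restore closure)
ema_swap <- function(model) {
  saved <- lapply(model$ctx$params, function(p) p$value)
  for (p in model$ctx$params) if (!is.null(p$ema)) p$value <- p$ema
  function() {
    for (i in seq_along(saved)) model$ctx$params[[i]]$value <- saved[[i]]
  }
}

load_image_chw <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  aperm(img[, , 1:3, drop = FALSE], c(3, 1, 2))
}

#' Train a detector on a manifest
#'
#' Minibatch SGD with momentum over the manifest's train split. Losses are
#' the one-stage standard: IoU box loss and distributional focal loss on
#' task-aligned assigned cells, binary cross-entropy classification with
#' alignment-weighted soft targets.
#'
#' @param model A [build_model()] result.
#' @param manifest A [dataset_manifest()] whose images exist on disk.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` and `trace` (per-epoch loss tibble).
#' @export
train <- function(model, manifest, config = train_config(), verbose = FALSE) {
  rows <- manifest[manifest$split == "train", ]
  if (!nrow(rows)) stop("manifest has no train images", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  nc <- model$config$n_classes
  size <- config$image_size
  images <- lapply(rows$path, load_image_chw)
  trace <- tibble::tibble(epoch = integer(), loss = numeric(),
                          box = numeric(), cls = numeric(), dfl = numeric())
  n <- length(images)
  step <- 0L
  total_steps_warmup <- max(1, config$warmup_epochs) * ceiling(n / config$batch_size)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- c(loss = 0, box = 0, cls = 0, dfl = 0)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in batches) {
      zero_grads(model)
      step <- step + 1L
      lr <- if (step <= total_steps_warmup && config$warmup_epochs > 0) {
        config$lr * step / total_steps_warmup
      } else if (config$lr_schedule == "constant") {
        config$lr
      } else {
        # hold the base rate, then cosine-decay to 10% over the final quarter
        prog <- epoch / config$epochs
        if (prog <= 0.75) config$lr else {
          f <- (prog - 0.75) / 0.25
          config$lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * f)))
        }
      }
      for (i in b) {
        ag_start_tape()
        outs <- model$forward(images[[i]])
        dl <- detection_loss(outs, rows$labels[[i]], size, nc)
        if (!is.finite(ag_val(dl$loss))) {
          ag_clear_tape()
          stop("non-finite loss at epoch ", epoch, call. = FALSE)
        }
        ag_backward(dl$loss)
        ag_clear_tape()
        ep_loss <- ep_loss + c(ag_val(dl$loss), dl$parts) / n
      }
      # average gradients over the batch
      for (p in model$ctx$params) if (!is.null(p$grad)) p$grad <- p$grad / length(b)
      sgd_ema_step(model$ctx$params, lr, config$momentum,
                   min(config$ema_decay, step / (step + 20)), TRUE)
    }
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      epoch = epoch, loss = ep_loss[["loss"]], box = ep_loss[["box"]],
      cls = ep_loss[["cls"]], dfl = ep_loss[["dfl"]]))
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f (box %.3f cls %.3f dfl %.3f)",
                      epoch, ep_loss[["loss"]], ep_loss[["box"]],
                      ep_loss[["cls"]], ep_loss[["dfl"]]))
    }
  }
  structure(list(model = model, trace = trace, config = config),
            class = "train_result")
}

#' @export
tidy.train_result <- function(x, ...) x$trace

#' @export
glance.train_result <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$trace),
                 final_loss = x$trace$loss[nrow(x$trace)],
                 min_loss = min(x$trace$loss))
}

#' Run inference over a manifest split
#'
#' @param model A trained [build_model()] result.
#' @param manifest A [dataset_manifest()].
#' @param split Which split to run.
#' @param conf_threshold Confidence floor (dense sweep default 0.001 for
#'   evaluation).
#' @param nms_iou NMS IoU threshold (0.7 evaluation convention).
#' @return Detection tibble with `image_id` keyed to manifest row numbers.
#' @export
predict_manifest <- function(model, manifest, split = "test",
                             conf_threshold = 0.001, nms_iou = 0.7) {
  idx <- which(manifest$split == split)
  if (!length(idx)) stop("split '", split, "' is empty", call. = FALSE)
  purrr::map_dfr(idx, function(i) {
    img <- load_image_chw(manifest$path[i])
    outs <- model$forward(img)
    d <- decode_predictions(outs, dim(img)[2], model$config$n_classes,
                            conf_threshold = conf_threshold, nms_iou = nms_iou)
    if (nrow(d)) d$image_id <- i
    d
  })
}

#' Evaluate a model (or oracle detections) on a split
#'
#' Runs inference, feeds the detection metrics, and returns the per-class
#' results table (percent precision/recall at the F1-optimal confidence,
#' mAP@50, mAP@50-95) with the `all` summary row first.
#'
#' @param object A `detector_model`, or a detection tibble (e.g. from
#'   [oracle_detector()]).
#' @param manifest A [dataset_manifest()].
#' @param split Split to evaluate.
#' @param ... Passed to [predict_manifest()] when `object` is a model.
#' @return List with `results` (per-class table) and `ap` (the
#'   [map_50_95()] object).
#' @export
evaluate <- function(object, manifest, split = "test", ...) {
  idx <- which(manifest$split == split)
  if (!length(idx)) stop("split '", split, "' is empty", call. = FALSE)
  gts <- purrr::map_dfr(idx, function(i) {
    l <- manifest$labels[[i]]
    if (nrow(l)) { l$image_id <- i; l } else NULL
  })
  dets <- if (inherits(object, "detector_model")) {
    predict_manifest(object, manifest, split, ...)
  } else {
    object[object$image_id %in% idx, , drop = FALSE]
  }
  if (!nrow(dets)) {
    dets <- tibble::tibble(image_id = integer(), class_id = integer(),
                           cx = numeric(), cy = numeric(), w = numeric(),
                           h = numeric(), conf = numeric())
  }
  results <- per_class_results(dets, gts, catalog = manifest_catalog(manifest))
  ap <- map_50_95(dets, gts)
  list(results = results, ap = ap, detections = dets)
}

#' Overfit smoke test
#'
#' Trains the configured variant on a small synthetic scene set and
#' evaluates on the same images: a desk-scale check that the complete
#' architecture (backbone, neck, head, assignment, losses, decoding)
#' optimizes end-to-end. Scene and training sizes default to a CPU-feasible
#' problem: `n_images` images at `image_size` px with `n_classes` classes
#' and up to three large instances each.
#'
#' @param config An [ablation_config()].
#' @param n_images Number of images (trained on and evaluated against).
#' @param epochs Optimization epochs.
#' @param image_size Scene/input size (divisible by 32).
#' @param n_classes Classes in the fixture.
#' @param seed Master seed.
#' @param verbose Print epoch losses.
#' @return List with `map50`, `trace`, `results`.
#' @export
overfit_smoke_test <- function(config = ablation_config(TRUE, TRUE, TRUE),
                               n_images = 16L, epochs = 120L,
                               image_size = 64L, n_classes = 4L,
                               seed = 0L, verbose = FALSE) {
  spec <- scene_spec(n_classes = n_classes, image_size = image_size,
                     instances_range = c(1L, 3L), size_range = c(0.25, 0.5),
                     occlusion = 0, illumination = 0.1, tail_ratio = 1 / 4)
  ds <- generate_dataset(spec, n_images, seed = seed, split_ratio = c(1, 0, 0))
  cfg <- config
  cfg$n_classes <- as.integer(n_classes)
  cfg$image_size <- as.integer(image_size)
  model <- build_model(cfg, seed = seed)
  ds_eval <- ds
  ds_eval$split <- "test"
  # train in segments and track the best moving-average checkpoint: the
  # question is whether the model reaches the target within the budget
  segments <- unique(pmax(1, round(epochs * c(0.6, 0.8, 1.0))))
  done <- 0L
  trace <- NULL
  best <- -Inf; best_results <- NULL
  for (si in seq_along(segments)) {
    seg_epochs <- segments[si] - done
    if (seg_epochs <= 0) next
    tc <- train_config(
      epochs = seg_epochs, batch_size = 8L, image_size = image_size,
      seed = seed + si - 1L,
      warmup_epochs = if (done == 0L) 3L else 0L,
      lr_schedule = if (si == length(segments)) "hold-decay" else "constant")
    fit <- train(model, ds, tc, verbose = verbose)
    model <- fit$model
    trace <- if (is.null(trace)) fit$trace else
      dplyr::bind_rows(trace, dplyr::mutate(fit$trace, epoch = epoch + done))
    done <- segments[si]
    restore <- ema_swap(model)
    ev <- evaluate(model, ds_eval, "test", conf_threshold = 0.01)
    restore()
    m50 <- attr(ev$ap, "map50")
    if (verbose) message(sprintf("epoch %d: mAP@50 %.3f", done, m50))
    if (m50 > best) { best <- m50; best_results <- ev$results }
  }
  list(map50 = best, trace = trace, results = best_results, model = model)
}
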