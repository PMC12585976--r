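# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: the convolution is a naive septuple loop,
# AP is an enumeration over all confidence cuts, and matching is written
# from the protocol definition rather than shared with the package.

# naive dense/grouped convolution by explicit loops
ref_conv2d <- function(x, w, bias = NULL, stride = 1, pad = NULL, groups = 1) {
  k <- dim(w)[1]
  if (is.null(pad)) pad <- k %/% 2
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  cg <- dim(w)[3]; Cout <- dim(w)[4]
  cout_g <- Cout / groups
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, dim = c(Cout, Ho, Wo))
  for (co in seq_len(Cout)) {
    g <- (co - 1) %/% cout_g
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- if (is.null(bias)) 0 else bias[co]
      for (ci in seq_len(cg)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        hi <- (ho - 1) * stride - pad + ki
        wi <- (wo - 1) * stride - pad + kj
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          acc <- acc + x[g * cg + ci, hi, wi] * w[ki, kj, ci, co]
        }
      }
      y[co, ho, wo] <- acc
    }
  }
  y
}

# greedy confidence-ordered matching, written independently from the
# protocol description (single image, single class assumed pre-filtered)
ref_match <- function(dets, gts, thr) {
  ord <- order(-dets$conf)
  used <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(dets))
  for (i in ord) {
    best <- 0; bestj <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j]) next
      if (dets$class_id[i] != gts$class_id[j]) next
      v <- iou(dets[i, ], gts[j, ])
      if (v >= thr && v > best) { best <- v; bestj <- j }
    }
    if (bestj > 0) { used[bestj] <- TRUE; tp[i] <- TRUE }
  }
  tp[ord]  # in descending-confidence order
}

# brute-force AP: enumerate every distinct confidence cut, build the PR
# point set, integrate the monotone envelope exactly
ref_ap <- function(dets, gts, thr) {
  n_gt <- nrow(gts)
  if (n_gt == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  tp <- ref_match(dets, gts, thr)
  confs <- sort(dets$conf, decreasing = TRUE)
  cuts <- unique(confs)
  rec <- prec <- numeric(0)
  for (ct in cuts) {
    keep <- seq_len(sum(confs >= ct))
    ntp <- sum(tp[keep])
    rec <- c(rec, ntp / n_gt)
    prec <- c(prec, ntp / length(keep))
  }
  r <- c(0, rec); p <- c(1, prec)
  p <- rev(cummax(rev(p)))
  sum(diff(r) * p[-1])
}

random_boxes <- function(n, n_classes = 3, with_conf = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- runif(n, 0.05, 0.4); h <- runif(n, 0.05, 0.4)
  out <- box_labels(
    class_id = sample.int(n_classes, n, replace = TRUE) - 1L,
    cx = runif(n, w / 2, 1 - w / 2), cy = runif(n, h / 2, 1 - h / 2),
    w = w, h = h,
    conf = if (with_conf) runif(n) else NULL
  )
  out$image_id <- 1L
  out
}

# jittered copies of ground truths plus clutter: a detection set with a
# mixture of hits and misses for metric stress tests
noisy_dets <- function(gts, jitter = 0.05, extra = 2) {
  d <- gts
  n <- nrow(d)
  d$cx <- pmin(1, pmax(0, d$cx + rnorm(n, 0, jitter)))
  d$cy <- pmin(1, pmax(0, d$cy + rnorm(n, 0, jitter)))
  d$conf <- runif(n)
  if (extra > 0) {
    d <- dplyr::bind_rows(d, random_boxes(extra, with_conf = TRUE))
  }
  d
}
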