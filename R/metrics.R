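#' Match detections to ground truths
#'
#' Greedy confidence-ordered one-to-one matching, the standard detection
#' evaluation protocol: detections are visited in order of descending
#' confidence and each is matched to the not-yet-matched ground truth of the
#' same class (and same image) with the highest IoU, provided that IoU
#' reaches the threshold. Every further detection of an already matched
#' object is a false positive.
#'
#' @param dets Detection tibble: columns `image_id, class_id, cx, cy, w, h,
#'   conf`.
#' @param gts Ground-truth tibble: columns `image_id, class_id, cx, cy, w, h`.
#' @param iou_threshold Minimum IoU for a true positive.
#' @return List with `detections` (input rows plus a logical `tp` column, in
#'   descending-confidence order) and `counts` (per-class `tp`, `fp`, `fn`).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  dets <- normalize_det_table(dets)
  gts <- normalize_gt_table(gts)
  ord <- order(-dets$conf)
  dets <- dets[ord, , drop = FALSE]
  tp <- logical(nrow(dets))
  gt_used <- logical(nrow(gts))
  if (nrow(dets) && nrow(gts)) {
    iom <- iou_matrix(dets, gts)
    same <- outer(dets$image_id, gts$image_id, `==`) &
      outer(dets$class_id, gts$class_id, `==`)
    iom[!same] <- -1
    for (i in seq_len(nrow(dets))) {
      cand <- which(!gt_used & iom[i, ] >= iou_threshold)
      if (length(cand)) {
        j <- cand[which.max(iom[i, cand])]
        gt_used[j] <- TRUE
        tp[i] <- TRUE
      }
    }
  }
  dets$tp <- tp
  classes <- sort(unique(c(dets$class_id, gts$class_id)))
  counts <- purrr::map_dfr(classes, function(cl) {
    d <- dets$class_id == cl
    g <- gts$class_id == cl
    tibble::tibble(class_id = cl,
                   tp = sum(dets$tp[d]),
                   fp = sum(!dets$tp[d]),
                   fn = sum(g) - sum(dets$tp[d]))
  })
  list(detections = dets, counts = counts)
}

normalize_det_table <- function(dets) {
  stopifnot(all(c("class_id", "cx", "cy", "w", "h", "conf") %in% names(dets)))
  if (!"image_id" %in% names(dets)) dets$image_id <- 1L
  tibble::as_tibble(dets)
}

normalize_gt_table <- function(gts) {
  stopifnot(all(c("class_id", "cx", "cy", "w", "h") %in% names(gts)))
  if (!"image_id" %in% names(gts)) gts$image_id <- 1L
  tibble::as_tibble(gts)
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. Zero
#' denominators follow the documented convention: with no predictions,
#' precision is 0 when targets were missed (`FN > 0`) and 1 when there was
#' nothing to find; recall is 1 when there are no targets.
#'
#' @param counts Tibble with columns `tp`, `fp`, `fn` (one row, or summed).
#' @return A single numeric value.
#' @export
precision <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  if (tp + fp == 0) return(if (fn > 0) 0 else 1)
  tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(counts) {
  tp <- sum(counts$tp); fn <- sum(counts$fn)
  if (tp + fn == 0) return(1)
  tp / (tp + fn)
}

#' Precision-recall curve for one class
#'
#' Sweeps the confidence threshold over every detection of the class,
#' yielding one `(recall, precision)` point per detection in
#' descending-confidence order (the standard cumulative construction).
#'
#' @param dets,gts Detection / ground-truth tables (single class or
#'   pre-filtered; `class_id` is ignored here beyond matching).
#' @param iou_threshold IoU threshold for the underlying matching.
#' @return Tibble with columns `conf`, `recall`, `precision`; attribute
#'   `n_gt` carries the ground-truth count.
#' @export
pr_curve <- function(dets, gts, iou_threshold = 0.5) {
  m <- match_detections(dets, gts, iou_threshold)
  d <- m$detections
  n_gt <- nrow(normalize_gt_table(gts))
  cum_tp <- cumsum(d$tp)
  cum_fp <- cumsum(!d$tp)
  out <- tibble::tibble(
    conf = d$conf,
    recall = if (n_gt > 0) cum_tp / n_gt else rep(0, nrow(d)),
    precision = ifelse(cum_tp + cum_fp > 0, cum_tp / (cum_tp + cum_fp), 0)
  )
  attr(out, "n_gt") <- n_gt
  class(out) <- c("pr_curve", class(out))
  out
}

#' Average precision by monotone-envelope integration
#'
#' Area under the precision-recall curve with precision replaced by its
#' running maximum from the right (the interpolated envelope), integrated
#' continuously over recall — the convention of the model family's native
#' evaluator rather than 11- or 101-point sampling.
#'
#' @param curve A [pr_curve()] result.
#' @return AP in `[0, 1]`; 0 when there are ground truths but no detections.
#' @export
average_precision <- function(curve) {
  n_gt <- attr(curve, "n_gt")
  if (is.null(n_gt)) stop("curve lacks its n_gt attribute", call. = FALSE)
  if (n_gt == 0) return(NA_real_)
  if (!nrow(curve)) return(0)
  r <- c(0, curve$recall)
  p <- c(1, curve$precision)
  # monotone non-increasing envelope from the right
  p <- rev(cummax(rev(p)))
  sum(diff(r) * p[-1])
}

#' Mean average precision over classes
#'
#' Unweighted mean over classes that are present in the ground truth;
#' classes that never occur contribute nothing.
#'
#' @param per_class Tibble with columns `class_id`, `ap`, `n_gt`.
#' @return Mean AP.
#' @export
mean_ap <- function(per_class) {
  present <- per_class[per_class$n_gt > 0, ]
  if (!nrow(present)) stop("no class with ground-truth instances", call. = FALSE)
  mean(present$ap)
}

map_iou_thresholds <- function() seq(0.5, 0.95, by = 0.05)

#' Per-class AP across the 0.50:0.05:0.95 IoU sweep
#'
#' Evaluates average precision per class at the ten IoU thresholds
#' 0.50, 0.55, ..., 0.95 and aggregates to mAP@50 and mAP@50-95.
#'
#' @param dets,gts Detection / ground-truth tables.
#' @return An `ap_result`: tibble with one row per class and threshold
#'   (`class_id`, `iou_threshold`, `ap`, `n_gt`) plus `map50`/`map50_95`
#'   attributes (also via [glance.ap_result()]).
#' @export
map_50_95 <- function(dets, gts) {
  dets <- normalize_det_table(dets)
  gts <- normalize_gt_table(gts)
  classes <- sort(unique(gts$class_id))
  thresholds <- map_iou_thresholds()
  rows <- purrr::map_dfr(thresholds, function(th) {
    purrr::map_dfr(classes, function(cl) {
      curve <- pr_curve(dets[dets$class_id == cl, , drop = FALSE],
                        gts[gts$class_id == cl, , drop = FALSE], th)
      tibble::tibble(class_id = cl, iou_threshold = th,
                     ap = average_precision(curve),
                     n_gt = attr(curve, "n_gt"))
    })
  })
  structure(rows, class = c("ap_result", class(rows)),
            map50 = mean(rows$ap[rows$iou_threshold == 0.5]),
            map50_95 = mean(rows$ap))
}

#' @export
glance.ap_result <- function(x, ...) {
  tibble::tibble(map50 = attr(x, "map50"), map50_95 = attr(x, "map50_95"),
                 n_classes = length(unique(x$class_id)))
}

#' Detection confusion matrix
#'
#' Class-agnostic greedy IoU matching at a fixed confidence and IoU
#' threshold, followed by label comparison. Rows index the predicted class,
#' columns the true class; the extra `background` row collects missed ground
#' truths and the `background` column false detections.
#'
#' @param dets,gts Detection / ground-truth tables.
#' @param n_classes Size of the class catalog.
#' @param conf_threshold Minimum confidence for a detection to count.
#' @param iou_threshold IoU threshold for the class-agnostic matching.
#' @return Integer matrix of size `(n_classes + 1)^2` with dimnames.
#' @export
confusion_matrix <- function(dets, gts, n_classes,
                             conf_threshold = 0.25, iou_threshold = 0.45) {
  dets <- normalize_det_table(dets)
  gts <- normalize_gt_table(gts)
  dets <- dets[dets$conf >= conf_threshold, , drop = FALSE]
  dets <- dets[order(-dets$conf), , drop = FALSE]
  m <- matrix(0L, n_classes + 1, n_classes + 1,
              dimnames = list(pred = c(seq_len(n_classes) - 1, "background"),
                              truth = c(seq_len(n_classes) - 1, "background")))
  gt_used <- logical(nrow(gts))
  if (nrow(dets)) {
    iom <- iou_matrix(dets, gts)
    same_img <- outer(dets$image_id, gts$image_id, `==`)
    if (length(iom)) iom[!same_img] <- -1
    for (i in seq_len(nrow(dets))) {
      cand <- if (nrow(gts)) which(!gt_used & iom[i, ] >= iou_threshold) else integer()
      if (length(cand)) {
        j <- cand[which.max(iom[i, cand])]
        gt_used[j] <- TRUE
        m[dets$class_id[i] + 1, gts$class_id[j] + 1] <-
          m[dets$class_id[i] + 1, gts$class_id[j] + 1] + 1L
      } else {
        m[dets$class_id[i] + 1, n_classes + 1] <-
          m[dets$class_id[i] + 1, n_classes + 1] + 1L
      }
    }
  }
  for (j in which(!gt_used)) {
    m[n_classes + 1, gts$class_id[j] + 1] <- m[n_classes + 1, gts$class_id[j] + 1] + 1L
  }
  m
}

#' Per-class results table
#'
#' The standard per-class report: instances, precision and recall at the
#' per-class F1-optimal confidence, mAP@50 and mAP@50-95, plus an `all`
#' summary row holding unweighted class means. Values are percentages.
#'
#' @param dets,gts Detection / ground-truth tables.
#' @param catalog Class catalog naming the rows.
#' @return Tibble with columns `category`, `instances`, `precision`,
#'   `recall`, `map50`, `map50_95`.
#' @export
per_class_results <- function(dets, gts, catalog = fine24_catalog()) {
  dets <- normalize_det_table(dets)
  gts <- normalize_gt_table(gts)
  apres <- map_50_95(dets, gts)
  classes <- sort(unique(gts$class_id))
  rows <- purrr::map_dfr(classes, function(cl) {
    curve <- pr_curve(dets[dets$class_id == cl, , drop = FALSE],
                      gts[gts$class_id == cl, , drop = FALSE], 0.5)
    n_gt <- attr(curve, "n_gt")
    if (nrow(curve)) {
      f1 <- 2 * curve$precision * curve$recall /
        pmax(curve$precision + curve$recall, 1e-12)
      k <- which.max(f1)
      p <- curve$precision[k]; r <- curve$recall[k]
    } else {
      p <- 0; r <- 0
    }
    a <- apres[apres$class_id == cl, ]
    tibble::tibble(
      category = catalog[cl + 1], instances = n_gt,
      precision = 100 * p, recall = 100 * r,
      map50 = 100 * a$ap[a$iou_threshold == 0.5],
      map50_95 = 100 * mean(a$ap)
    )
  })
  summary <- tibble::tibble(
    category = "all", instances = sum(rows$instances),
    precision = mean(rows$precision), recall = mean(rows$recall),
    map50 = mean(rows$map50), map50_95 = mean(rows$map50_95)
  )
  dplyr::bind_rows(summary, rows)
}

#' Write a per-class results table as CSV
#'
#' @param results A [per_class_results()] table.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_results_csv <- function(results, path) {
  out <- results
  names(out) <- c("Category", "Instances", "Precision (%)", "Recall (%)",
                  "mAP@50 (%)", "mAP@50-95 (%)")
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 1))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plot a precision-recall curve
#'
#' @param object A [pr_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Plot a detection confusion matrix
#'
#' @param m A [confusion_matrix()] result.
#' @param normalize Normalize columns to proportions of the true class.
#' @return A ggplot object.
#' @export
plot_confusion_matrix <- function(m, normalize = TRUE) {
  df <- as.data.frame.table(m, responseName = "count")
  if (normalize) {
    df <- dplyr::group_by(df, .data$truth)
    df <- dplyr::mutate(df, count = .data$count / pmax(sum(.data$count), 1))
    df <- dplyr::ungroup(df)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$pred,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "True class", y = "Predicted class",
                  fill = if (normalize) "Proportion" else "Count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
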