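#' Build a dataset manifest
#'
#' A manifest is the package's tabular view of a detection dataset: one row
#' per image with its path, pixel size, split assignment and a list-column of
#' box labels. It mirrors the common YOLO dataset layout (`images/`,
#' `labels/`, a YAML file naming classes and splits).
#'
#' @param images Tibble with columns `path`, `width`, `height`, `split` and a
#'   list-column `labels` of box label tibbles.
#' @param catalog Character vector of class names.
#' @return A `dataset_manifest` tibble.
#' @export
dataset_manifest <- function(images, catalog = fine24_catalog()) {
  stopifnot(all(c("path", "width", "height", "split", "labels") %in% names(images)))
  bad <- purrr::map_lgl(images$labels, function(l) {
    nrow(l) > 0 && any(l$class_id >= length(catalog))
  })
  if (any(bad)) stop("label class ids exceed catalog size", call. = FALSE)
  out <- tibble::as_tibble(images)
  attr(out, "catalog") <- catalog
  class(out) <- c("dataset_manifest", class(out))
  out
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %d images, %d classes\n",
              nrow(x), length(attr(x, "catalog"))))
  print(dplyr::count(tibble::as_tibble(x), .data$split))
  invisible(x)
}

manifest_catalog <- function(manifest) {
  cat_ <- attr(manifest, "catalog")
  if (is.null(cat_)) fine24_catalog() else cat_
}

#' Assign train/val/test splits by ratio
#'
#' Deterministic contiguous assignment in image order, following the
#' configured ratio (default 7:1:2). With `n` images the train split gets
#' `round(n * 7/10)` images and the validation split `round(n * 1/10)`,
#' the remainder going to test.
#'
#' @param n Number of images.
#' @param ratio Three non-negative weights for train/val/test.
#' @return Character vector of length `n` with values `train`, `val`, `test`.
#' @export
split_assignment <- function(n, ratio = c(7, 1, 2)) {
  stopifnot(length(ratio) == 3, all(ratio >= 0), sum(ratio) > 0)
  p <- ratio / sum(ratio)
  n_train <- round(n * p[1])
  n_val <- round(n * p[2])
  n_train <- min(n_train, n)
  n_val <- min(n_val, n - n_train)
  rep(c("train", "val", "test"), c(n_train, n_val, n - n_train - n_val))
}

#' Export a manifest as a COCO annotation document
#'
#' Converts normalized centre-format boxes to absolute pixel top-left
#' `[x, y, width, height]` boxes and emits the standard
#' `categories`/`images`/`annotations` structure. Annotation and image ids
#' are 1-based and unique.
#'
#' @param manifest A [dataset_manifest()].
#' @param path Optional path; when given the JSON document is written there.
#' @return The COCO document as a list (invisibly when `path` is given).
#' @export
to_coco_json <- function(manifest, path = NULL) {
  catalog <- manifest_catalog(manifest)
  if (any(!is.finite(manifest$width)) || any(!is.finite(manifest$height)) ||
      any(manifest$width <= 0) || any(manifest$height <= 0)) {
    stop("every image needs a positive pixel size to denormalize boxes",
         call. = FALSE)
  }
  categories <- purrr::imap(catalog, function(nm, i) {
    list(id = i, name = nm, supercategory = "plant")
  })
  images <- purrr::pmap(
    list(seq_len(nrow(manifest)), manifest$path, manifest$width, manifest$height),
    function(id, p, w, h) list(id = id, file_name = basename(p), width = w, height = h)
  )
  ann_id <- 0L
  annotations <- list()
  for (i in seq_len(nrow(manifest))) {
    lab <- manifest$labels[[i]]
    if (!nrow(lab)) next
    W <- manifest$width[i]; H <- manifest$height[i]
    for (j in seq_len(nrow(lab))) {
      ann_id <- ann_id + 1L
      bw <- lab$w[j] * W; bh <- lab$h[j] * H
      annotations[[ann_id]] <- list(
        id = ann_id, image_id = i,
        category_id = lab$class_id[j] + 1L,
        bbox = c(lab$cx[j] * W - bw / 2, lab$cy[j] * H - bh / 2, bw, bh),
        area = bw * bh, iscrowd = 0L
      )
    }
  }
  doc <- list(images = images, annotations = annotations, categories = categories)
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    return(invisible(doc))
  }
  doc
}

#' Re-import a COCO annotation document as a manifest
#'
#' Inverse of [to_coco_json()] (up to file paths): boxes are renormalized to
#' centre format. Used to verify that the COCO export is lossless.
#'
#' @param doc A COCO document list or a path to a JSON file.
#' @param split Split assigned to every image (COCO files carry no splits).
#' @return A [dataset_manifest()].
#' @export
from_coco_json <- function(doc, split = "test") {
  if (is.character(doc)) doc <- jsonlite::read_json(doc)
  catalog <- purrr::map_chr(doc$categories, "name")
  imgs <- purrr::map(doc$images, function(im) {
    tibble::tibble(id = im$id, path = im$file_name,
                   width = im$width, height = im$height)
  })
  imgs <- dplyr::bind_rows(imgs)
  anns <- purrr::map(doc$annotations, function(a) {
    bb <- unlist(a$bbox)
    tibble::tibble(image_id = a$image_id, class_id = a$category_id - 1L,
                   x = bb[1], y = bb[2], w = bb[3], h = bb[4])
  })
  anns <- if (length(anns)) dplyr::bind_rows(anns) else
    tibble::tibble(image_id = integer(), class_id = integer(),
                   x = numeric(), y = numeric(), w = numeric(), h = numeric())
  labels <- purrr::map(imgs$id, function(id) {
    a <- anns[anns$image_id == id, ]
    im <- imgs[imgs$id == id, ]
    box_labels(class_id = a$class_id,
               cx = (a$x + a$w / 2) / im$width,
               cy = (a$y + a$h / 2) / im$height,
               w = a$w / im$width, h = a$h / im$height)
  })
  dataset_manifest(
    tibble::tibble(path = imgs$path, width = imgs$width, height = imgs$height,
                   split = split, labels = labels),
    catalog = catalog
  )
}

#' Letterbox an image to a square target size
#'
#' Aspect-preserving nearest-neighbour resize padded to `target x target`
#' with a neutral gray. Returns the resized image together with the affine
#' record (`scale`, `pad_x`, `pad_y`) needed to map boxes in and out.
#'
#' @param image Numeric array `H x W x 3` with values in `[0, 1]`.
#' @param target Side length of the square output; must be divisible by 32
#'   (the stride of the deepest pyramid level).
#' @param fill Pad value.
#' @return List with `image`, `scale`, `pad_x`, `pad_y`, `orig_width`,
#'   `orig_height`.
#' @export
letterbox <- function(image, target = 640L, fill = 114 / 255) {
  if (target <= 0) stop("target size must be positive", call. = FALSE)
  if (target %% 32 != 0) stop("target size must be divisible by 32", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  scale <- min(target / w, target / h)
  new_w <- round(w * scale); new_h <- round(h * scale)
  xi <- pmin(w, pmax(1, ceiling(seq_len(new_w) / scale - 1e-9)))
  yi <- pmin(h, pmax(1, ceiling(seq_len(new_h) / scale - 1e-9)))
  resized <- image[yi, xi, , drop = FALSE]
  out <- array(fill, dim = c(target, target, dim(image)[3]))
  pad_x <- (target - new_w) %/% 2
  pad_y <- (target - new_h) %/% 2
  out[pad_y + seq_len(new_h), pad_x + seq_len(new_w), ] <- resized
  list(image = out, scale = scale, pad_x = pad_x, pad_y = pad_y,
       orig_width = w, orig_height = h)
}

#' Map normalized boxes through a letterbox transform
#'
#' @param labels Box labels normalized to the original image.
#' @param lb A letterbox record from [letterbox()].
#' @param target Side length used in the letterbox call.
#' @param inverse Map letterboxed boxes back to the original image instead.
#' @return Box labels normalized to the letterboxed (or original) image.
#' @export
letterbox_boxes <- function(labels, lb, target = 640L, inverse = FALSE) {
  if (!nrow(labels)) return(labels)
  out <- labels
  if (!inverse) {
    out$cx <- (labels$cx * lb$orig_width * lb$scale + lb$pad_x) / target
    out$cy <- (labels$cy * lb$orig_height * lb$scale + lb$pad_y) / target
    out$w <- labels$w * lb$orig_width * lb$scale / target
    out$h <- labels$h * lb$orig_height * lb$scale / target
  } else {
    out$cx <- (labels$cx * target - lb$pad_x) / lb$scale / lb$orig_width
    out$cy <- (labels$cy * target - lb$pad_y) / lb$scale / lb$orig_height
    out$w <- labels$w * target / lb$scale / lb$orig_width
    out$h <- labels$h * target / lb$scale / lb$orig_height
  }
  validate_box_labels(out)
  out
}
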