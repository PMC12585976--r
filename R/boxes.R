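#' Fine-grained crop/weed class catalog
#'
#' Default 24-class catalog (8 crop species, 16 weed species) used throughout
#' the package: the class set of the fine-grained crop-and-weed detection
#' setting the synthetic scene generator emulates. Any function taking a
#' `catalog` argument accepts an arbitrary character vector of class names,
#' so the catalog is a default, not a constraint.
#'
#' @return Character vector of 24 class names.
#' @export
fine24_catalog <- function() {
  c("Maize", "Sugar beet", "Sunflower", "Bean", "Pea", "Soy", "Potato",
    "Pumpkin", "Grasses", "Thistle", "Geranium", "Knotweed", "Amaranth",
    "Goosefoot", "Potato weed", "Chamomile", "Crucifer", "Plantago",
    "Poppy", "Corn spurry", "Mercuries", "Solanales", "Chickweed",
    "Labiate")
}

#' Construct a tibble of normalized box labels
#'
#' Boxes use the YOLO convention: class id (0-based), box centre `(cx, cy)`
#' and size `(w, h)` as fractions of the image in `[0, 1]`.
#'
#' @param class_id Integer vector, 0-based class ids.
#' @param cx,cy Box centre, normalized to `[0, 1]`.
#' @param w,h Box width/height, normalized to `(0, 1]`.
#' @param conf Optional confidence in `[0, 1]`; when supplied the result is a
#'   detection table rather than a ground-truth label table.
#' @return A tibble with columns `class_id, cx, cy, w, h` (and `conf` if given).
#' @export
box_labels <- function(class_id = integer(), cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric(), conf = NULL) {
  out <- tibble::tibble(
    class_id = as.integer(class_id),
    cx = as.numeric(cx), cy = as.numeric(cy),
    w = as.numeric(w), h = as.numeric(h)
  )
  if (!is.null(conf)) out$conf <- as.numeric(conf)
  validate_box_labels(out)
  out
}

validate_box_labels <- function(x, allow_conf = TRUE) {
  stopifnot(is.data.frame(x))
  need <- c("class_id", "cx", "cy", "w", "h")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("box label table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$class_id < 0)) stop("class_id must be >= 0", call. = FALSE)
  if (any(x$cx < 0 | x$cx > 1 | x$cy < 0 | x$cy > 1)) {
    stop("box centres must lie in [0, 1]", call. = FALSE)
  }
  if (any(x$w < 0 | x$w > 1 | x$h < 0 | x$h > 1)) {
    stop("box sizes must lie in [0, 1]", call. = FALSE)
  }
  if (allow_conf && "conf" %in% names(x) && any(x$conf < 0 | x$conf > 1)) {
    stop("confidences must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# centre-format -> corner-format, clamped to the unit square
box_corners <- function(b) {
  tibble::tibble(
    x1 = pmax(0, b$cx - b$w / 2), y1 = pmax(0, b$cy - b$h / 2),
    x2 = pmin(1, b$cx + b$w / 2), y2 = pmin(1, b$cy + b$h / 2)
  )
}

#' Intersection-over-union of axis-aligned boxes
#'
#' Vectorized pairwise IoU between two box tables of equal length (or one of
#' length 1, recycled). Degenerate boxes (zero width or height) have IoU 0 by
#' convention so that detection matching never divides by zero.
#'
#' @param a,b Box label tables (see [box_labels()]).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ca <- box_corners(a); cb <- box_corners(b)
  ix <- pmax(0, pmin(ca$x2, cb$x2) - pmax(ca$x1, cb$x1))
  iy <- pmax(0, pmin(ca$y2, cb$y2) - pmax(ca$y1, cb$y1))
  inter <- ix * iy
  area_a <- pmax(0, ca$x2 - ca$x1) * pmax(0, ca$y2 - ca$y1)
  area_b <- pmax(0, cb$x2 - cb$x1) * pmax(0, cb$y2 - cb$y1)
  un <- area_a + area_b - inter
  ifelse(un > 0, inter / un, 0)
}

# IoU matrix between m detections and n ground truths (corner arithmetic,
# no recycling surprises); rows = a, cols = b
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(numeric(), nrow = nrow(a), ncol = nrow(b)))
  }
  ca <- box_corners(a); cb <- box_corners(b)
  ix <- pmax(0, outer(ca$x2, cb$x2, pmin) - outer(ca$x1, cb$x1, pmax))
  iy <- pmax(0, outer(ca$y2, cb$y2, pmin) - outer(ca$y1, cb$y1, pmax))
  inter <- ix * iy
  area_a <- pmax(0, ca$x2 - ca$x1) * pmax(0, ca$y2 - ca$y1)
  area_b <- pmax(0, cb$x2 - cb$x1) * pmax(0, cb$y2 - cb$y1)
  un <- outer(area_a, area_b, `+`) - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

#' Read YOLO-format label files
#'
#' Parses the standard one-object-per-line text format
#' `class cx cy w h` (whitespace separated, normalized coordinates).
#'
#' @param path Path to a label text file. A missing or empty file yields an
#'   empty label table.
#' @param catalog Optional class catalog; when given, class ids are checked
#'   against its length.
#' @return A box label tibble.
#' @export
read_yolo_labels <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("no such label file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(box_labels())
  parsed <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 5 || anyNA(vals)) {
      stop(sprintf("malformed YOLO label line %d in %s: '%s'",
                   i, path, lines[[i]]), call. = FALSE)
    }
    vals
  })
  m <- do.call(rbind, parsed)
  out <- box_labels(class_id = m[, 1], cx = m[, 2], cy = m[, 3],
                    w = m[, 4], h = m[, 5])
  if (!is.null(catalog) && nrow(out) && any(out$class_id >= length(catalog))) {
    stop("class id outside catalog range in ", path, call. = FALSE)
  }
  out
}

#' Write YOLO-format label files
#'
#' Inverse of [read_yolo_labels()]; values are serialized with six decimal
#' places so that a write/read round trip is lossless to 1e-6.
#'
#' @param labels Box label tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_yolo_labels <- function(labels, path) {
  validate_box_labels(labels)
  lines <- if (nrow(labels)) {
    sprintf("%d %.6f %.6f %.6f %.6f",
            labels$class_id, labels$cx, labels$cy, labels$w, labels$h)
  } else character()
  writeLines(lines, path)
  invisible(path)
}
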