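#' Specification of the synthetic farmland scene generator
#'
#' The generator emulates the statistical structure of a fine-grained
#' crop/weed detection dataset without any external assets: 24 plant classes
#' drawn as parametric silhouettes (leaf-blade, rosette, lobed, compact
#' archetypes cycled over the catalog), a long-tailed class frequency
#' profile, textured soil backgrounds, per-image illumination jitter and
#' optional instance overlap. It is deliberately not photorealistic; it
#' exists so that every pipeline stage (label I/O, training, evaluation,
#' confusion analysis) is exercisable deterministically on CPU.
#'
#' @param n_classes Number of plant classes (default 24: 8 crop-like and 16
#'   weed-like classes).
#' @param image_size Square image side in pixels (>= 64; default 640).
#' @param instances_range Inclusive range of instances per image.
#' @param size_range Instance diameter as a fraction of the image side.
#' @param tail_ratio Frequency ratio between the rarest and the most common
#'   class; the profile is geometric over class rank. The default 1/80
#'   mirrors the roughly 4000-vs-50 instance imbalance of real fine-grained
#'   weed datasets.
#' @param occlusion Fraction of instances allowed to overlap previously
#'   placed ones.
#' @param illumination Half-width of the per-image multiplicative brightness
#'   jitter (gain drawn from `1 +/- illumination`).
#' @param hard_pair Render classes 1 and 2 with nearly identical silhouettes
#'   and colors, to probe confusion between morphologically similar species.
#' @param catalog Class names (length `n_classes`).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_classes = 24L, image_size = 640L,
                       instances_range = c(1L, 8L), size_range = c(0.08, 0.35),
                       tail_ratio = 1 / 80, occlusion = 0.3,
                       illumination = 0.25, hard_pair = FALSE,
                       catalog = NULL) {
  stopifnot(n_classes >= 1, image_size >= 64,
            instances_range[1] >= 0, instances_range[2] >= instances_range[1],
            size_range[1] > 0, size_range[2] <= 1,
            tail_ratio > 0, tail_ratio <= 1,
            occlusion >= 0, occlusion <= 1, illumination >= 0)
  if (is.null(catalog)) {
    catalog <- if (n_classes == 24L) fine24_catalog() else
      sprintf("class_%02d", seq_len(n_classes) - 1)
  }
  stopifnot(length(catalog) == n_classes)
  probs <- tail_ratio^(seq(0, 1, length.out = n_classes))
  spec <- list(
    n_classes = as.integer(n_classes), image_size = as.integer(image_size),
    instances_range = as.integer(instances_range), size_range = size_range,
    tail_ratio = tail_ratio, class_probs = probs / sum(probs),
    occlusion = occlusion, illumination = illumination,
    hard_pair = hard_pair, catalog = catalog
  )
  class(spec) <- "scene_spec"
  spec
}

scene_spec_hash <- function(spec) {
  key <- paste(spec$n_classes, spec$image_size,
               paste(spec$instances_range, collapse = ","),
               paste(signif(spec$size_range, 8), collapse = ","),
               signif(spec$tail_ratio, 8), signif(spec$occlusion, 8),
               signif(spec$illumination, 8), spec$hard_pair, sep = "|")
  sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 1000003L
}

# counter-based seed fan-out: images are independent of generation order
child_seed <- function(seed, counter) {
  (as.integer(seed) %% 2147480L) * 977L + 131L * (counter %% 16381L) + counter %% 977L
}

# deterministic per-class appearance (archetype cycles over the catalog)
class_style <- function(class_id, spec) {
  archetypes <- c("leaf-blade", "rosette", "lobed", "compact")
  k <- class_id
  if (isTRUE(spec$hard_pair) && class_id == 2L) k <- 1L
  arch <- archetypes[(k %% 4L) + 1L]
  frac <- k / max(1, spec$n_classes - 1)
  hue <- 0.20 + 0.22 * frac
  sat <- 0.55 + 0.35 * (((k * 7L) %% spec$n_classes) / max(1, spec$n_classes))
  val <- 0.35 + 0.40 * (((k * 13L) %% spec$n_classes) / max(1, spec$n_classes))
  if (isTRUE(spec$hard_pair) && class_id == 2L) hue <- hue + 0.01
  rgb_ <- hsv2rgb_num(hue, sat, val)
  list(archetype = arch, color = rgb_)
}

# hsv -> rgb without grDevices string round trip
hsv2rgb_num <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6); f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(t, p, v), c(v, p, q))
}

# smooth value noise: coarse uniform grid, bilinear upsampled
smooth_noise <- function(size, cells = 8) {
  g <- matrix(runif((cells + 1)^2), cells + 1, cells + 1)
  pos <- seq(0, cells, length.out = size)
  i0 <- pmin(floor(pos), cells - 1); f <- pos - i0
  a <- g[i0 + 1, i0 + 1, drop = FALSE]
  gy0 <- g[i0 + 1, , drop = FALSE]; gy1 <- g[i0 + 2, , drop = FALSE]
  rowm <- gy0 * (1 - f) + gy1 * f           # size x (cells+1)
  colm0 <- rowm[, i0 + 1, drop = FALSE]; colm1 <- rowm[, i0 + 2, drop = FALSE]
  colm0 * matrix(1 - f, size, size, byrow = TRUE) +
    colm1 * matrix(f, size, size, byrow = TRUE)
}

# silhouette mask of one instance inside a local window; returns the mask
# (logical matrix) in window coordinates
instance_mask <- function(archetype, size_px, angle, wiggle) {
  half <- ceiling(size_px / 2) + 2L
  n <- 2L * half + 1L
  xs <- matrix(rep(seq(-half, half), each = n), n, n)
  ys <- matrix(rep(seq(-half, half), times = n), n, n)
  xr <- cos(angle) * xs + sin(angle) * ys
  yr <- -sin(angle) * xs + cos(angle) * ys
  a <- size_px / 2
  mask <- switch(
    archetype,
    "compact" = (xr / a)^2 + (yr / (0.8 * a))^2 <= 1,
    "leaf-blade" = {
      taper <- 1 - 0.55 * (xr / a + 1) / 2
      (xr / a)^2 + (yr / pmax(0.28 * a * taper, 1e-6))^2 <= 1
    },
    "lobed" = {
      r <- sqrt(xr^2 + yr^2); th <- atan2(yr, xr)
      r <= a * (0.62 + 0.38 * abs(cos(2.5 * th + wiggle))^0.8)
    },
    "rosette" = {
      m <- matrix(FALSE, n, n)
      leaves <- 6L
      for (l in seq_len(leaves)) {
        phi <- 2 * pi * (l - 1) / leaves + wiggle
        xl <- cos(phi) * xr + sin(phi) * yr
        yl <- -sin(phi) * xr + cos(phi) * yr
        m <- m | (((xl - 0.45 * a) / (0.55 * a))^2 + (yl / (0.18 * a))^2 <= 1)
      }
      m
    },
    stop("unknown archetype: ", archetype)
  )
  mask
}

#' Render one synthetic farmland scene
#'
#' Deterministic for a given `(spec, seed)`: renders a textured soil
#' background, places plant instances (classes drawn from the long-tailed
#' profile), applies per-image illumination jitter and returns exact
#' mask-derived bounding boxes.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; the scene is a pure function of `(spec, seed)`.
#' @param keep_masks Also return each instance's pixel mask (row/column
#'   window plus logical matrix), for auditing label tightness.
#' @return A `rendered_scene`: list with `image` (`H x W x 3` array in
#'   `[0, 1]`), `labels` (box label tibble), `seed`, `spec_hash` (and
#'   `masks` when requested).
#' @export
generate_scene <- function(spec, seed = 0L, keep_masks = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 0L))
  S <- spec$image_size
  soil_base <- c(0.36, 0.27, 0.18)
  noise <- smooth_noise(S, cells = 8)
  fine <- matrix(runif(S * S, -0.05, 0.05), S, S)
  img <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) img[, , ch] <- soil_base[ch] * (0.75 + 0.5 * noise) + fine * 0.5
  n_inst <- if (spec$instances_range[2] > spec$instances_range[1]) {
    sample(spec$instances_range[1]:spec$instances_range[2], 1)
  } else spec$instances_range[1]
  labels <- box_labels()
  masks <- list()
  occupied <- matrix(FALSE, S, S)
  max_retries <- 40L
  placed <- 0L
  while (placed < n_inst) {
    cls <- sample.int(spec$n_classes, 1, prob = spec$class_probs) - 1L
    style <- class_style(cls, spec)
    size_px <- runif(1, spec$size_range[1], spec$size_range[2]) * S
    allow_overlap <- runif(1) < spec$occlusion
    ok <- FALSE
    for (try_ in seq_len(max_retries)) {
      cx <- runif(1, size_px / 2 + 2, S - size_px / 2 - 2)
      cy <- runif(1, size_px / 2 + 2, S - size_px / 2 - 2)
      angle <- runif(1, 0, pi); wiggle <- runif(1, 0, 2 * pi)
      mask <- instance_mask(style$archetype, size_px, angle, wiggle)
      half <- (nrow(mask) - 1L) / 2L
      rows <- round(cy) + seq(-half, half)
      cols <- round(cx) + seq(-half, half)
      keep_r <- rows >= 1 & rows <= S; keep_c <- cols >= 1 & cols <= S
      mask_w <- mask[keep_r, keep_c, drop = FALSE]
      rows <- rows[keep_r]; cols <- cols[keep_c]
      if (!any(mask_w)) next
      if (!allow_overlap &&
          any(occupied[rows, cols][mask_w])) next
      ok <- TRUE
      break
    }
    if (!ok) {
      if (allow_overlap || placed == 0L) {
        stop("could not place instance after bounded retries; spec overcrowded",
             call. = FALSE)
      }
      break
    }
    texture <- 0.78 + 0.44 * matrix(runif(length(mask_w)), nrow(mask_w))
    for (ch in 1:3) {
      sub <- img[rows, cols, ch]
      sub[mask_w] <- pmin(1, pmax(0, style$color[ch] * texture[mask_w]))
      img[rows, cols, ch] <- sub
    }
    occupied[rows, cols] <- occupied[rows, cols] | mask_w
    rr <- range(rows[rowSums(mask_w) > 0])
    cc <- range(cols[colSums(mask_w) > 0])
    labels <- dplyr::bind_rows(labels, box_labels(
      class_id = cls,
      cx = mean(cc) / S, cy = mean(rr) / S,
      w = (diff(cc) + 1) / S, h = (diff(rr) + 1) / S
    ))
    if (keep_masks) {
      masks[[placed + 1L]] <- list(rows = rows, cols = cols, mask = mask_w)
    }
    placed <- placed + 1L
  }
  gain <- 1 + runif(1, -spec$illumination, spec$illumination)
  img[] <- pmin(1, pmax(0, img * gain))
  out <- list(image = img, labels = labels, seed = seed,
              spec_hash = scene_spec_hash(spec))
  if (keep_masks) out$masks <- masks
  structure(out, class = "rendered_scene")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic dataset on disk
#'
#' Writes the standard YOLO dataset layout (`images/<split>/`,
#' `labels/<split>/`, plus a `data.yaml` naming classes and split
#' directories), with images seeded independently from the master seed so
#' the result does not depend on generation order.
#'
#' @param spec A [scene_spec()].
#' @param n_images Number of images (>= 1).
#' @param seed Master seed.
#' @param dir Output directory.
#' @param split_ratio Train/val/test weights (default `c(7, 1, 2)`).
#' @param write_images Render and write PNGs (set `FALSE` to emit labels
#'   only, e.g. for metric fixtures where pixels are irrelevant).
#' @return A [dataset_manifest()] with scene labels attached.
#' @export
generate_dataset <- function(spec, n_images, seed = 0L, dir = tempfile("synds"),
                             split_ratio = c(7, 1, 2), write_images = TRUE) {
  stopifnot(n_images >= 1)
  splits <- split_assignment(n_images, split_ratio)
  for (s in unique(splits)) {
    dir.create(file.path(dir, "images", s), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "labels", s), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- purrr::map_dfr(seq_len(n_images), function(i) {
    scene <- generate_scene(spec, seed = child_seed(seed, i))
    s <- splits[i]
    stem <- sprintf("scene_%04d", i)
    img_path <- file.path(dir, "images", s, paste0(stem, ".png"))
    lab_path <- file.path(dir, "labels", s, paste0(stem, ".txt"))
    if (write_images) png::writePNG(scene$image, img_path)
    write_yolo_labels(scene$labels, lab_path)
    tibble::tibble(path = img_path, width = spec$image_size,
                   height = spec$image_size, split = s,
                   labels = list(scene$labels))
  })
  manifest <- dataset_manifest(rows, catalog = spec$catalog)
  yaml::write_yaml(list(
    path = normalizePath(dir),
    train = "images/train", val = "images/val", test = "images/test",
    nc = spec$n_classes, names = as.list(spec$catalog)
  ), file.path(dir, "data.yaml"))
  attr(manifest, "dir") <- dir
  manifest
}

#' Perturbation spec for the oracle detector
#'
#' @param jitter Standard deviation of centre/size noise, relative to box
#'   size (0 = exact boxes).
#' @param drop_rate Probability that a ground-truth object is missed.
#' @param spurious_rate Expected number of spurious detections per true
#'   object.
#' @param class_flip_rate Probability that a kept detection reports a
#'   uniformly random wrong class.
#' @param conf_range Confidence range for true detections.
#' @param spurious_conf Confidence range for spurious detections.
#' @return An `oracle_noise` list.
#' @export
oracle_noise <- function(jitter = 0, drop_rate = 0, spurious_rate = 0,
                         class_flip_rate = 0, conf_range = c(0.6, 1),
                         spurious_conf = c(0.05, 0.5)) {
  structure(list(jitter = jitter, drop_rate = drop_rate,
                 spurious_rate = spurious_rate,
                 class_flip_rate = class_flip_rate,
                 conf_range = conf_range, spurious_conf = spurious_conf),
            class = "oracle_noise")
}

#' Oracle detector: ground truth with controlled corruption
#'
#' Returns the ground-truth labels of a scene (or manifest) perturbed by a
#' configurable noise model, producing detection sets with known expected
#' TP/FP/FN composition — the fixture used to validate the metric stack.
#' With zero noise the downstream mAP@50 is exactly 1.
#'
#' @param x A `rendered_scene`, a [dataset_manifest()], or a ground-truth
#'   tibble with an `image_id` column.
#' @param noise An [oracle_noise()] spec.
#' @param n_classes Number of classes (needed for class flips and spurious
#'   labels).
#' @param seed Seed for the perturbation draw.
#' @return Detection tibble (`image_id, class_id, cx, cy, w, h, conf`).
#' @export
oracle_detector <- function(x, noise = oracle_noise(), n_classes = 24L,
                            seed = 0L) {
  gts <- gather_gts(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, 9999L))
  kept <- gts[runif(nrow(gts)) >= noise$drop_rate, , drop = FALSE]
  if (nrow(kept)) {
    n <- nrow(kept)
    kept$cx <- pmin(1, pmax(0, kept$cx + rnorm(n, 0, noise$jitter) * kept$w))
    kept$cy <- pmin(1, pmax(0, kept$cy + rnorm(n, 0, noise$jitter) * kept$h))
    kept$w <- pmin(1, pmax(1e-4, kept$w * exp(rnorm(n, 0, noise$jitter))))
    kept$h <- pmin(1, pmax(1e-4, kept$h * exp(rnorm(n, 0, noise$jitter))))
    flip <- runif(n) < noise$class_flip_rate
    if (any(flip)) {
      kept$class_id[flip] <- (kept$class_id[flip] +
        sample.int(n_classes - 1, sum(flip), replace = TRUE)) %% n_classes
    }
    kept$conf <- runif(n, noise$conf_range[1], noise$conf_range[2])
  } else {
    kept$conf <- numeric()
  }
  n_spur <- if (noise$spurious_rate > 0) {
    stats::rpois(1, noise$spurious_rate * max(1, nrow(gts)))
  } else 0L
  if (n_spur > 0) {
    spur <- tibble::tibble(
      image_id = sample(unique(gts$image_id), n_spur, replace = TRUE),
      class_id = sample.int(n_classes, n_spur, replace = TRUE) - 1L,
      cx = runif(n_spur, 0.1, 0.9), cy = runif(n_spur, 0.1, 0.9),
      w = runif(n_spur, 0.05, 0.3), h = runif(n_spur, 0.05, 0.3),
      conf = runif(n_spur, noise$spurious_conf[1], noise$spurious_conf[2])
    )
    kept <- dplyr::bind_rows(kept, spur)
  }
  kept
}

gather_gts <- function(x) {
  if (inherits(x, "rendered_scene")) {
    g <- x$labels; g$image_id <- 1L; return(g)
  }
  if (inherits(x, "dataset_manifest")) {
    return(purrr::imap_dfr(x$labels, function(l, i) {
      if (nrow(l)) { l$image_id <- i; l } else NULL
    }))
  }
  normalize_gt_table(x)
}

#' Plot a rendered scene with its boxes
#'
#' @param scene A `rendered_scene`.
#' @return A ggplot object.
#' @export
plot_scene <- function(scene) {
  S <- dim(scene$image)[1]
  lab <- scene$labels
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(scene$image, xmin = 0, xmax = 1, ymin = 0, ymax = 1) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::theme_void()
  if (nrow(lab)) {
    rect <- tibble::tibble(
      xmin = lab$cx - lab$w / 2, xmax = lab$cx + lab$w / 2,
      ymin = 1 - (lab$cy + lab$h / 2), ymax = 1 - (lab$cy - lab$h / 2),
      class_id = factor(lab$class_id)
    )
    p <- p + ggplot2::geom_rect(
      data = rect,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   colour = .data$class_id),
      fill = NA, linewidth = 0.4
    )
  }
  p
}
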