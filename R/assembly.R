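# Assembly of the YOLO11n-scale baseline and its ablation variants. The
# parameter audit and FLOPs estimate are derived from the same constructed
# graph that runs the forward pass, never from separate arithmetic.

#' Ablation configuration
#'
#' The three module flags enumerate the eight ablation variants: the
#' baseline detector (all flags off), each proposed module alone, every
#' pair, and the complete model (all flags on).
#'
#' @param use_hrfn Replace the backbone downsampling with SRFD/DRFD.
#' @param use_pcmsfa Replace every C3k2 site with the PC-MSFA block.
#' @param use_integradet Replace the decoupled head with the task-aligned
#'   dynamic head.
#' @param n_classes Number of object classes (default 24).
#' @param image_size Nominal square input size, divisible by 32.
#' @return An `ablation_config`.
#' @export
ablation_config <- function(use_hrfn = FALSE, use_pcmsfa = FALSE,
                            use_integradet = FALSE, n_classes = 24L,
                            image_size = 640L) {
  if (n_classes <= 0) stop("n_classes must be positive", call. = FALSE)
  if (image_size %% 32 != 0) stop("image_size must be divisible by 32", call. = FALSE)
  structure(list(use_hrfn = isTRUE(use_hrfn), use_pcmsfa = isTRUE(use_pcmsfa),
                 use_integradet = isTRUE(use_integradet),
                 n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size)),
            class = "ablation_config")
}

#' @export
print.ablation_config <- function(x, ...) {
  mods <- c("HRFN", "PC-MSFA", "IntegraDet")[c(x$use_hrfn, x$use_pcmsfa, x$use_integradet)]
  cat(sprintf("<ablation_config> %s | nc=%d | %dpx\n",
              if (length(mods)) paste(mods, collapse = "+") else "baseline",
              x$n_classes, x$image_size))
  invisible(x)
}

# baseline decoupled head (regression branch with distributional boxes,
# depthwise-separable classification branch)
mk_detect <- function(ctx, nc, ch = c(64L, 128L, 256L), bins = 16L) {
  c2 <- 64L
  c3 <- max(ch[1], min(nc, 100L))
  levels <- lapply(ch, function(x) {
    box <- list(mk_conv(ctx, 3, x, c2), mk_conv(ctx, 3, c2, c2),
                mk_conv(ctx, 1, c2, 4 * bins, norm = "none", bias = TRUE, act = "none"))
    cls <- list(mk_conv(ctx, 3, x, x, groups = x),
                mk_conv(ctx, 1, x, c3),
                mk_conv(ctx, 3, c3, c3, groups = c3),
                mk_conv(ctx, 1, c3, c3),
                mk_conv(ctx, 1, c3, nc, norm = "none", bias = TRUE, act = "none"))
    cls[[5]]$params$b$value[] <- -log((1 - 0.01) / 0.01)
    list(box = box, cls = cls)
  })
  dfl <- mk_dfl(ctx, bins)
  list(nc = nc, bins = bins, dfl = dfl, fwd = function(pyr) {
    if (length(pyr) != 3) stop("head expects three pyramid levels", call. = FALSE)
    lapply(seq_along(pyr), function(l) {
      x <- pyr[[l]]
      b <- x
      for (m in levels[[l]]$box) b <- m$fwd(b)
      cl <- x
      for (m in levels[[l]]$cls) cl <- m$fwd(cl)
      list(reg = b, cls = cl)
    })
  })
}

#' Build a detector variant
#'
#' Constructs the full layer graph of the configured variant: the YOLO11n
#' scaffolding (stride-2 stem, C3k2/C2PSA backbone, SPPF, FPN/PAN neck,
#' decoupled head with 16-bin distributional box regression), with each
#' enabled flag substituting its module. Topology is deterministic; `seed`
#' affects only weight initialization.
#'
#' @param config An [ablation_config()].
#' @param seed Weight-initialization seed.
#' @return A `detector_model` environment.
#' @export
build_model <- function(config = ablation_config(), seed = 0L) {
  stopifnot(inherits(config, "ablation_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ctx <- new_ctx()
  blk <- function(cin, cout, c3k = FALSE, e = 0.5) {
    if (config$use_pcmsfa) mk_pcmsfa(ctx, cin, cout, 1L)
    else mk_c3k2(ctx, cin, cout, 1L, c3k, e)
  }
  down <- function(cin, cout) {
    if (config$use_hrfn) mk_drfd(ctx, cin, cout)
    else mk_conv(ctx, 3, cin, cout, stride = 2)
  }
  if (config$use_hrfn) {
    stem <- mk_srfd(ctx, 32L, 16L, 32L)
    stem_fwd <- function(x) stem$fwd(x)$quarter
  } else {
    s0 <- mk_conv(ctx, 3, 3, 16, stride = 2)
    s1 <- mk_conv(ctx, 3, 16, 32, stride = 2)
    stem_fwd <- function(x) s1$fwd(s0$fwd(x))
  }
  b2 <- blk(32, 64, FALSE, 0.25)
  d3 <- down(64, 64)
  b4 <- blk(64, 128, FALSE, 0.25)
  d5 <- down(128, 128)
  b6 <- blk(128, 128, TRUE)
  d7 <- down(128, 256)
  b8 <- blk(256, 256, TRUE)
  sppf <- mk_sppf(ctx, 256, 256)
  psa <- mk_c2psa(ctx, 256, 256, 1)
  n13 <- blk(384, 128, FALSE)
  n16 <- blk(256, 64, FALSE)
  nd17 <- mk_conv(ctx, 3, 64, 64, stride = 2)
  n19 <- blk(192, 128, FALSE)
  nd20 <- mk_conv(ctx, 3, 128, 128, stride = 2)
  n22 <- blk(384, 256, TRUE)
  head <- if (config$use_integradet) {
    mk_integradet(ctx, config$n_classes)
  } else {
    mk_detect(ctx, config$n_classes)
  }
  model <- new.env(parent = emptyenv())
  model$ctx <- ctx
  model$config <- config
  model$seed <- seed
  model$strides <- c(8L, 16L, 32L)
  model$head <- head
  model$forward <- function(x) {
    p2 <- b2$fwd(stem_fwd(x))
    p3 <- b4$fwd(d3$fwd(p2))
    p4 <- b6$fwd(d5$fwd(p3))
    p5 <- psa$fwd(sppf$fwd(b8$fwd(d7$fwd(p4))))
    u1 <- ag_concat(list(ag_upsample(p5), p4))
    f13 <- n13$fwd(u1)
    u2 <- ag_concat(list(ag_upsample(f13), p3))
    f16 <- n16$fwd(u2)
    f19 <- n19$fwd(ag_concat(list(nd17$fwd(f16), f13)))
    f22 <- n22$fwd(ag_concat(list(nd20$fwd(f19), p5)))
    head$fwd(list(f16, f19, f22))
  }
  class(model) <- "detector_model"
  model
}

#' @export
print.detector_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("  parameters (deployment count): %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count model parameters
#'
#' By default reports the deployment (fused) count: batch-normalization
#' affine pairs fold into the preceding convolution's bias, so each
#' conv+BN pair contributes `k^2 * Cin * Cout / groups + Cout`;
#' GroupNorm affine terms (which do not fold) contribute `2C`; raw
#' convolution/linear biases and the 16 fixed distributional-decoding
#' weights are included. `fused = FALSE` gives the train-time count with
#' both BN affine vectors.
#'
#' @param model A [build_model()] result (or any block carrying a `ctx`).
#' @param fused Report the deployment count (default) or the train-time
#'   count.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, fused = TRUE) {
  ctx <- if (inherits(model, "detector_model")) model$ctx else model$ctx
  sum(vapply(ctx$atoms, atom_count, 0, fused = fused))
}

#' Estimate forward-pass GFLOPs
#'
#' Closed-form count under the `2 x multiply-accumulate` convention on the
#' deployment graph: convolution and linear layers contribute
#' `2 k^2 (Cin/g) Cout Hout Wout`; pooling, activations, normalization,
#' upsampling, attention matrix products and the deformable sampling
#' arithmetic are not counted — the convention under which the YOLO11n
#' baseline at 640 px reports its published figure.
#'
#' @param model A [build_model()] result.
#' @param image_size Input side length (defaults to the config's).
#' @return GFLOPs (numeric).
#' @export
estimate_gflops <- function(model, image_size = NULL) {
  if (is.null(image_size)) image_size <- model$config$image_size
  if (image_size %% 32 != 0) stop("image_size must be divisible by 32", call. = FALSE)
  macs <- ag_collect_macs(
    model$forward(agshape(3L, image_size, image_size))
  )
  2 * macs / 1e9
}

# published reference values for the eight-variant ablation table
ablation_reference <- function() {
  tibble::tibble(
    variant = 1:8,
    hrfn = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    pcmsfa = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    integradet = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
    params_expected = c(2586832, 2594288, 2633688, 2201699,
                        2641144, 2209155, 2516072, 2270699),
    gflops_expected = c(6.3, 7.6, 7.7, 7.9, 8.9, 9.2, 9.3, 10.5)
  )
}

#' Audit every ablation variant against the published reference values
#'
#' Builds all eight variants (nc = 24), counts parameters and estimates
#' GFLOPs at the given size, and compares with the published values.
#' Mismatches are report rows, not errors.
#'
#' @param image_size Input size for the FLOPs estimate.
#' @param n_classes Class count (the published table uses 24).
#' @param gflops Also compute the FLOPs column (slightly slower).
#' @return Tibble with computed and expected values and match flags.
#' @export
audit_ablation <- function(image_size = 640L, n_classes = 24L,
                                 gflops = TRUE) {
  ref <- ablation_reference()
  rows <- purrr::pmap_dfr(ref, function(variant, hrfn, pcmsfa, integradet,
                                        params_expected, gflops_expected) {
    cfg <- ablation_config(hrfn, pcmsfa, integradet, n_classes = n_classes,
                           image_size = image_size)
    m <- build_model(cfg, seed = 0L)
    p <- count_parameters(m)
    g <- if (gflops) round(estimate_gflops(m, image_size), 1) else NA_real_
    tibble::tibble(
      variant = variant, hrfn = hrfn, pcmsfa = pcmsfa, integradet = integradet,
      params = p, params_expected = params_expected,
      params_match = p == params_expected,
      gflops = g, gflops_expected = gflops_expected,
      gflops_match = !is.na(g) && g == gflops_expected
    )
  })
  class(rows) <- c("ablation_audit", class(rows))
  rows
}

#' @export
glance.ablation_audit <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x),
    params_matched = sum(x$params_match),
    gflops_matched = sum(x$gflops_match, na.rm = TRUE)
  )
}

#' Serialize an audit report to JSON
#'
#' @param audit An [audit_ablation()] table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_audit_json <- function(audit, path) {
  jsonlite::write_json(tibble::as_tibble(audit), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export the variant's layer plan as YAML
#'
#' Writes the layer graph in the familiar from/repeats/module/args detection
#' config dialect, with the enabled substitutions (`SRFD`, `DRFD`,
#' `PC_MSFA`, `IntegraDet`) in place of the baseline blocks.
#'
#' @param config An [ablation_config()].
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_model_yaml <- function(config, path) {
  blk <- if (config$use_pcmsfa) "PC_MSFA" else "C3k2"
  dwn <- if (config$use_hrfn) "DRFD" else "Conv"
  head <- if (config$use_integradet) "IntegraDet" else "Detect"
  stem <- if (config$use_hrfn) {
    list(list(from = -1, repeats = 1, module = "SRFD", args = list(32)))
  } else {
    list(list(from = -1, repeats = 1, module = "Conv", args = list(16, 3, 2)),
         list(from = -1, repeats = 1, module = "Conv", args = list(32, 3, 2)))
  }
  row <- function(from, module, args) list(from = from, repeats = 1,
                                           module = module, args = args)
  backbone <- c(stem, list(
    row(-1, blk, list(64)), row(-1, dwn, list(64, 3, 2)),
    row(-1, blk, list(128)), row(-1, dwn, list(128, 3, 2)),
    row(-1, blk, list(128)), row(-1, dwn, list(256, 3, 2)),
    row(-1, blk, list(256)), row(-1, "SPPF", list(256, 5)),
    row(-1, "C2PSA", list(256))
  ))
  neck_head <- list(
    row(-1, "Upsample", list(2)), row(list(-1, "P4"), "Concat", list()),
    row(-1, blk, list(128)),
    row(-1, "Upsample", list(2)), row(list(-1, "P3"), "Concat", list()),
    row(-1, blk, list(64)),
    row(-1, "Conv", list(64, 3, 2)), row(list(-1, "N13"), "Concat", list()),
    row(-1, blk, list(128)),
    row(-1, "Conv", list(128, 3, 2)), row(list(-1, "P5"), "Concat", list()),
    row(-1, blk, list(256)),
    row(list("N16", "N19", "N22"), head, list(config$n_classes))
  )
  yaml::write_yaml(list(nc = config$n_classes,
                        image_size = config$image_size,
                        backbone = backbone, head = neck_head), path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with the config embedded; weights round-trip
#' exactly.
#'
#' @param model A [build_model()] result.
#' @param path Checkpoint path.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, seed = model$seed,
               values = lapply(model$ctx$params, function(p) p$value)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = ck$seed)
  stopifnot(length(model$ctx$params) == length(ck$values))
  for (i in seq_along(ck$values)) model$ctx$params[[i]]$value <- ck$values[[i]]
  model
}
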