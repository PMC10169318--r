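# Five-stage residual feature extractor with a fine/coarse skip
# concatenation.
#
# Stage 1 is a 7x7/stride-2 convolution (64 kernels at full scale), batch
# norm, ReLU and a 3x3/stride-2 max pool. Stages 2-5 are bottleneck
# residual stages. The extractor's output is the concatenation of the
# flattened stage-2 feature map (shallow, fine, local detail) with the
# flattened stage-5 map (deep, coarse, global context): granule detection
# needs both the local texture of a deposit and the large-scale tissue
# context around it.

#' Backbone specification
#'
#' `"full"` reproduces the ResNet-50 stage layout: stage 2 is one
#' convolutional + two identity blocks with filters `[64, 64, 256]`,
#' stage 3 is 1+3 with `[128, 128, 512]`, stage 4 is 1+5 with
#' `[256, 256, 1024]`, stage 5 is 1+2 with `[512, 512, 2048]`, on a
#' 224x224x3 input. `"tiny"` preserves the topology (same stages, same
#' block counts, same stage-2 skip) with all channel counts divided by 8
#' and a 64x64 input, sized for CPU test runs.
#'
#' @param scale `"full"` or `"tiny"`.
#' @param input_size square input side in pixels (defaults: 224 full,
#'   64 tiny).
#' @return a `gn_backbone_spec` object.
#' @export
backbone_spec <- function(scale = c("tiny", "full"), input_size = NULL) {
  scale <- match.arg(scale)
  div <- if (scale == "full") 1L else 8L
  input_size <- as.integer(input_size %||% if (scale == "full") 224L else 64L)
  if (input_size < 32L || input_size %% 32L != 0L)
    stopf("input_size must be a positive multiple of 32 (got %d)", input_size)
  stages <- list(
    stage2 = list(filters = c(64L, 64L, 256L) %/% div,   n_identity = 2L, stride = 1L),
    stage3 = list(filters = c(128L, 128L, 512L) %/% div, n_identity = 3L, stride = 2L),
    stage4 = list(filters = c(256L, 256L, 1024L) %/% div, n_identity = 5L, stride = 2L),
    stage5 = list(filters = c(512L, 512L, 2048L) %/% div, n_identity = 2L, stride = 2L)
  )
  structure(list(scale = scale, input_size = input_size,
                 stem_filters = 64L %/% div, stages = stages),
            class = "gn_backbone_spec")
}

# Per-stage spatial side lengths: stage 1 halves twice (conv + pool),
# stages 3-5 halve once each.
stage_sides <- function(spec) {
  s1 <- spec$input_size %/% 4L
  c(stage1 = s1, stage2 = s1, stage3 = s1 %/% 2L, stage4 = s1 %/% 4L,
    stage5 = s1 %/% 8L)
}

#' Length of the concatenated stage-2 + stage-5 feature vector
#' @param spec a [backbone_spec()].
#' @return integer vector length.
#' @export
flat_length <- function(spec) {
  sides <- stage_sides(spec)
  as.integer(sides[["stage2"]]^2 * spec$stages$stage2$filters[3] +
               sides[["stage5"]]^2 * spec$stages$stage5$filters[3])
}

#' Build the feature extractor
#'
#' Initializes all stage weights from a seeded He-normal draw; batch-norm
#' layers are frozen at identity running statistics so feature extraction
#' is deterministic. Pretrained initialization is accepted as an argument
#' for forward compatibility but no weight source ships with the package.
#'
#' @param spec a [backbone_spec()].
#' @param init `"random"` (seeded) or `"pretrained"`.
#' @param seed integer seed for the random initialization.
#' @return a `gn_backbone` extractor.
#' @export
build_backbone <- function(spec, init = c("random", "pretrained"), seed = 0L) {
  init <- match.arg(init)
  if (init == "pretrained")
    stopf(paste("no pretrained weight archive is available in this",
                "installation; use init = \"random\""))
  weights <- with_seed(seed, {
    stem <- list(conv = init_kernel(7L, 7L, 3L, spec$stem_filters),
                 bn = bn_params(spec$stem_filters))
    in_ch <- spec$stem_filters
    stages <- lapply(spec$stages, function(st) {
      specs <- c(list(residual_block_spec("convolutional", st$filters,
                                          stride = st$stride)),
                 replicate(st$n_identity,
                           residual_block_spec("identity", st$filters),
                           simplify = FALSE))
      blocks <- lapply(specs, function(bs) {
        w <- init_block_weights(bs, in_ch)
        in_ch <<- bs$filters[3]
        list(spec = bs, weights = w)
      })
      blocks
    })
    list(stem = stem, stages = stages)
  })
  structure(list(spec = spec, weights = weights, seed = as.integer(seed),
                 built = TRUE),
            class = "gn_backbone")
}

#' @export
print.gn_backbone <- function(x, ...) {
  sides <- stage_sides(x$spec)
  cat(sprintf("<gn_backbone> scale=%s input=%dx%dx3 flat=%d\n",
              x$spec$scale, x$spec$input_size, x$spec$input_size,
              flat_length(x$spec)))
  for (nm in names(x$spec$stages)) {
    st <- x$spec$stages[[nm]]
    cat(sprintf("  %s: 1 conv + %d identity blocks, filters [%s] -> %dx%dx%d\n",
                nm, st$n_identity, paste(st$filters, collapse = ","),
                sides[[nm]], sides[[nm]], st$filters[3]))
  }
  invisible(x)
}

#' Prepare an image for the backbone
#'
#' Resizes a grayscale pixel matrix to the spec's square input size
#' (bilinear) and replicates it to 3 channels, matching the extractor's
#' `input_size x input_size x 3` input contract.
#'
#' @param pixels numeric matrix in `[0, 1]`, or an `ImageSample`.
#' @param spec a [backbone_spec()].
#' @return array `[input_size, input_size, 3]`.
#' @export
preprocess_image <- function(pixels, spec) {
  if (inherits(pixels, "gn_image_sample")) pixels <- pixels$pixels
  if (!is.matrix(pixels)) stopf("pixels must be a 2-D grayscale matrix")
  n <- spec$input_size
  if (nrow(pixels) != n || ncol(pixels) != n)
    pixels <- as.matrix(EBImage::resize(EBImage::Image(pixels), w = n, h = n))
  array(rep(as.vector(pixels), 3L), c(n, n, 3L))
}

#' Extract per-stage feature maps and the concatenated feature vector
#'
#' Runs the five stages in inference mode (batch norm with frozen running
#' statistics) and returns every stage's activation array plus the flat
#' vector `c(as.vector(stage2), as.vector(stage5))`. Flatten order is R's
#' native column-major array order (rows fastest, then columns, then
#' channels), fixed so feature vectors are reusable across sessions.
#'
#' @param extractor a built [build_backbone()] extractor.
#' @param image an `ImageSample`, a grayscale matrix, or a prepared
#'   `[H, W, 3]` array.
#' @return a `gn_feature_maps` list with elements `stage1`..`stage5`,
#'   `flat`, and `pooled5` (global average pooled stage-5 channels).
#' @export
extract_features <- function(extractor, image) {
  if (!inherits(extractor, "gn_backbone") || !isTRUE(extractor$built))
    stopf("extractor has not been built; call build_backbone() first")
  spec <- extractor$spec
  x <- if (is.array(image) && length(dim(image)) == 3L) image
       else preprocess_image(image, spec)
  if (!identical(dim(x), c(spec$input_size, spec$input_size, 3L)))
    stopf("prepared input must be [%d, %d, 3]", spec$input_size,
          spec$input_size)
  w <- extractor$weights
  h <- conv2d(x, w$stem$conv, stride = 2L, pad = 3L)
  h <- relu(batch_norm(h, w$stem$bn))
  s1 <- max_pool2d(h, size = 3L, stride = 2L, pad = 1L)
  acts <- list(stage1 = s1)
  h <- s1
  for (nm in names(w$stages)) {
    for (blk in w$stages[[nm]]) {
      h <- if (blk$spec$kind == "convolutional")
        convolutional_block(h, blk$spec, blk$weights, stage = nm)
      else identity_block(h, blk$spec, blk$weights, stage = nm)
    }
    acts[[nm]] <- h
  }
  acts$flat <- c(as.vector(acts$stage2), as.vector(acts$stage5))
  acts$pooled5 <- global_avg_pool(acts$stage5)
  class(acts) <- "gn_feature_maps"
  acts
}

#' Feature matrix for a dataset
#'
#' @param extractor a built extractor.
#' @param samples list of `ImageSample`s.
#' @param pooled if `TRUE`, return the global-average-pooled stage-5
#'   channel vectors instead of the full concatenated skip features.
#' @return matrix with one row per sample.
#' @export
feature_matrix <- function(extractor, samples, pooled = FALSE) {
  rows <- lapply(samples, function(s) {
    fm <- extract_features(extractor, s)
    if (pooled) fm$pooled5 else fm$flat
  })
  do.call(rbind, rows)
}

#' Export channel-tiled feature-map montages
#'
#' Reshapes each stage's 3-D activation array to a 2-D picture: channels
#' become small grayscale patches tiled on a near-square grid (each patch
#' min-max normalized; grid cells beyond the last channel are filled with
#' 0). One 8-bit PNG per stage.
#'
#' @param featmaps a `gn_feature_maps` set.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
export_feature_maps <- function(featmaps, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stopf("cannot create output directory '%s'", out_dir)
  stages <- grep("^stage", names(featmaps), value = TRUE)
  paths <- character(0)
  for (nm in stages) {
    a <- featmaps[[nm]]
    d <- dim(a); C <- d[3]
    ncol_grid <- ceiling(sqrt(C)); nrow_grid <- ceiling(C / ncol_grid)
    canvas <- matrix(0, nrow_grid * d[1], ncol_grid * d[2])
    for (c in seq_len(C)) {
      patch <- a[, , c]
      rng <- range(patch)
      if (diff(rng) > 0) patch <- (patch - rng[1]) / diff(rng)
      else patch <- patch * 0
      i <- (c - 1L) %/% ncol_grid; j <- (c - 1L) %% ncol_grid
      canvas[i * d[1] + seq_len(d[1]), j * d[2] + seq_len(d[2])] <- patch
    }
    p <- file.path(out_dir, paste0("feature_map_", nm, ".png"))
    EBImage::writeImage(EBImage::Image(canvas), p, type = "png", bits.per.sample = 8L)
    paths <- c(paths, p)
  }
  invisible(paths)
}
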