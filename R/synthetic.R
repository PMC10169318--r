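# Synthetic transmission-electron-micrograph generator.
#
# Real TEM data of renal biopsies is not redistributable, so the package
# ships a generator that emulates the visual structure the classifier must
# learn: a mid-gray background with band-limited low-frequency texture,
# darker curvilinear membrane-like lines, and — in positive images —
# electron-dense deposits rendered as dark filled ellipses with blurred
# edges, placed along the membrane curves. The generator makes no claim of
# biological fidelity; it provides a controllable, seeded, learnable task.

#' Parameters of the synthetic micrograph generator
#'
#' @param image_size square image side in pixels.
#' @param n_granules integer range `c(min, max)`: number of deposits painted
#'   in a positive image.
#' @param granule_radius range `c(min, max)` of the deposit equivalent
#'   radius in pixels (radius of the circle with the same area as the
#'   painted ellipse).
#' @param granule_intensity_drop fraction in `(0, 1]` by which deposit
#'   pixels are darkened relative to the local background (deposits are
#'   electron-dense, hence darker).
#' @param background_texture_scale correlation length in pixels of the
#'   low-frequency background texture.
#' @param noise_sd standard deviation of the additive pixel noise, in
#'   gray-level units of the `[0, 1]` scale.
#' @param membrane_curves number of membrane-like curvilinear structures.
#' @param seed default integer seed used when the generating functions are
#'   not given one explicitly.
#' @return a validated `gn_synth_params` object.
#' @export
synth_params <- function(image_size = 224L,
                         n_granules = c(3L, 8L),
                         granule_radius = c(5, 12),
                         granule_intensity_drop = 0.65,
                         background_texture_scale = 16,
                         noise_sd = 0.05,
                         membrane_curves = 3L,
                         seed = 0L) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) stopf("image_size must be >= 32 pixels")
  n_granules <- as.integer(rep_len(n_granules, 2L))
  if (any(n_granules < 1L) || n_granules[1] > n_granules[2])
    stopf("n_granules must be a positive non-decreasing range")
  granule_radius <- as.numeric(rep_len(granule_radius, 2L))
  if (granule_radius[1] < 1 || granule_radius[1] > granule_radius[2])
    stopf("granule_radius must be a non-decreasing range with minimum >= 1 px")
  if (granule_radius[2] > image_size / 4)
    stopf("granule_radius too large for image_size")
  if (granule_intensity_drop <= 0 || granule_intensity_drop > 1)
    stopf("granule_intensity_drop must be in (0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (background_texture_scale < 1) stopf("background_texture_scale must be >= 1")
  structure(list(image_size = image_size, n_granules = n_granules,
                 granule_radius = granule_radius,
                 granule_intensity_drop = granule_intensity_drop,
                 background_texture_scale = background_texture_scale,
                 noise_sd = noise_sd,
                 membrane_curves = as.integer(membrane_curves),
                 seed = as.integer(seed)),
            class = "gn_synth_params")
}

# Gaussian blur whose brush never exceeds the image side (EBImage errors
# on filters larger than the image).
gblur_safe <- function(m, sigma) {
  side <- min(dim(m))
  radius <- min(2L * ceiling(3 * sigma) + 1L, side - (side + 1L) %% 2L)
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma, radius = radius))
}

# Band-limited texture: Gaussian-filtered white noise, standardized and
# squashed through tanh so the background stays within
# base +/- amplitude — deposits must remain the only near-black structure.
synth_background <- function(n, scale, base = 0.55, amplitude = 0.12) {
  noise <- matrix(stats::rnorm(n * n), n, n)
  tex <- gblur_safe(noise, sigma = scale / 2)
  tex <- tanh(tex / max(stats::sd(tex), 1e-12))
  base + amplitude * tex
}

# A membrane-like curve: a smoothed random walk with slowly drifting
# heading. Returns integer pixel coordinates along the path.
synth_curve <- function(n) {
  len <- round(1.8 * n)
  theta <- stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(len, sd = 0.08))
  x <- stats::runif(1, 0.15 * n, 0.85 * n) + cumsum(cos(theta))
  y <- stats::runif(1, 0.15 * n, 0.85 * n) + cumsum(sin(theta))
  keep <- x >= 2 & x <= n - 1 & y >= 2 & y <= n - 1
  cbind(row = round(x[keep]), col = round(y[keep]))
}

# Rasterize a filled rotated ellipse with equivalent radius r (so the
# painted area is ~ pi r^2 regardless of eccentricity).
ellipse_mask <- function(n, center, r, ecc, angle) {
  a <- r * ecc; b <- r / ecc
  half <- ceiling(max(a, b)) + 1L
  rows <- max(1L, center[1] - half):min(n, center[1] + half)
  cols <- max(1L, center[2] - half):min(n, center[2] + half)
  dr <- outer(rows - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2])
  u <- dr * cos(angle) + dc * sin(angle)
  v <- -dr * sin(angle) + dc * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  list(rows = rows, cols = cols, inside = inside)
}

#' Generate one labeled synthetic micrograph
#'
#' Deterministic for a fixed seed: the same `(label, params, seed)` triple
#' yields bit-identical pixels. Positive images receive `n` deposits with
#' `n` drawn from `params$n_granules`; deposit centers lie on the membrane
#' curves, and deposits are rejection-placed so that no two masks touch
#' (every painted blob is one connected component of the internal mask).
#'
#' @param label `"Positive"` or `"Negative"`.
#' @param params a [synth_params()] object.
#' @param seed integer seed (defaults to `params$seed`).
#' @return an `ImageSample`: list with `pixels` (matrix in `[0, 1]`),
#'   `label`, and `meta` (seed, params, the noise-free deposit mask, and a
#'   per-deposit table of centers and radii).
#' @export
generate_image <- function(label = c("Positive", "Negative"), params = synth_params(),
                           seed = NULL) {
  label <- match.arg(label)
  if (!inherits(params, "gn_synth_params"))
    params <- do.call(synth_params, as.list(params))
  seed <- as.integer(seed %||% params$seed)
  n <- params$image_size
  with_seed(seed, {
    img <- synth_background(n, params$background_texture_scale)
    # membranes: darken thin curvilinear paths, then soften
    curve_pts <- do.call(rbind, lapply(seq_len(params$membrane_curves),
                                       function(i) synth_curve(n)))
    memb <- matrix(0, n, n)
    if (!is.null(curve_pts) && nrow(curve_pts) > 0)
      memb[curve_pts] <- 1
    memb <- gblur_safe(memb, sigma = 1)
    img <- img - 0.1 * pmin(memb / max(max(memb), 1e-12), 1)

    mask <- matrix(FALSE, n, n)
    granules <- data.frame(row = integer(0), col = integer(0),
                           radius = numeric(0))
    if (label == "Positive") {
      k <- if (params$n_granules[1] == params$n_granules[2]) params$n_granules[1]
           else sample(params$n_granules[1]:params$n_granules[2], 1L)
      rmax <- params$granule_radius[2]
      margin <- ceiling(1.3 * rmax) + 2L
      cand <- if (!is.null(curve_pts)) curve_pts else cbind(row = integer(0), col = integer(0))
      ok <- cand[, 1] > margin & cand[, 1] < n - margin &
            cand[, 2] > margin & cand[, 2] < n - margin
      cand <- cand[ok, , drop = FALSE]
      placed <- 0L; attempts <- 0L
      while (placed < k && attempts < 500L) {
        attempts <- attempts + 1L
        center <- if (nrow(cand) > 0 && stats::runif(1) < 0.8)
          cand[sample(nrow(cand), 1L), ]
        else c(sample((margin + 1L):(n - margin), 1L),
               sample((margin + 1L):(n - margin), 1L))
        # half-pixel inset so the rasterized equivalent radius stays inside
        # the requested range despite pixelation
        r_lo <- params$granule_radius[1] + 0.5
        r_hi <- max(r_lo, params$granule_radius[2] - 0.5)
        r <- stats::runif(1, r_lo, r_hi)
        if (nrow(granules) > 0) {
          d <- sqrt((granules$row - center[1])^2 + (granules$col - center[2])^2)
          # eccentricity <= 1.15, so 1.2 * (r1 + r2) + 3 guarantees a
          # >= 2 px gap between rasterized masks (no component merging)
          if (any(d < 1.2 * (granules$radius + r) + 3)) next
        }
        em <- ellipse_mask(n, as.integer(center), r,
                           ecc = stats::runif(1, 1, 1.15),
                           angle = stats::runif(1, 0, pi))
        mask[em$rows, em$cols] <- mask[em$rows, em$cols] | em$inside
        granules <- rbind(granules,
                          data.frame(row = center[1], col = center[2], radius = r))
        placed <- placed + 1L
      }
      if (placed < k)
        stopf("could not place %d non-overlapping deposits; reduce radius or count", k)
      soft <- gblur_safe(mask * 1, sigma = 1)
      img <- img * (1 - params$granule_intensity_drop * pmin(soft, 1))
    }
    if (params$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, sd = params$noise_sd), n, n)
    img <- pmin(pmax(img, 0), 1)
    structure(list(pixels = img, label = label,
                   meta = list(seed = seed, params = params,
                               granule_mask = mask, granules = granules)),
              class = "gn_image_sample")
  })
}

#' Generate a balanced labeled dataset
#'
#' Per-sample seeds are derived deterministically from the master seed,
#' the within-class index and the label, so the dataset is reproducible
#' bit-for-bit and independent of generation order.
#'
#' @param n_per_class number of images per class (>= 1).
#' @param params a [synth_params()] object.
#' @param seed master integer seed.
#' @return list of `2 * n_per_class` `ImageSample`s (positives first);
#'   each sample's `meta$id` is a stable identifier.
#' @export
generate_dataset <- function(n_per_class, params = synth_params(), seed = 0L) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stopf("n_per_class must be >= 1")
  out <- vector("list", 2L * n_per_class)
  k <- 0L
  for (label in c("Positive", "Negative")) {
    salt <- if (label == "Positive") 1L else 2L
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      s <- generate_image(label, params, seed = derive_seed(seed, i, salt))
      s$meta$id <- sprintf("%s_%04d", tolower(label), i)
      out[[k]] <- s
    }
  }
  out
}

#' Labels of a sample list as a 0/1 vector (Positive = 1)
#' @param samples list of `ImageSample`s.
#' @return integer vector.
#' @export
sample_labels <- function(samples) {
  as.integer(vapply(samples, function(s) s$label, "") == "Positive")
}

#' Write a dataset to disk as 8-bit grayscale PNGs plus a CSV manifest
#'
#' @param samples list of `ImageSample`s.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest path. Manifest columns: `filename`,
#'   `label`, `seed`, `params_hash`.
#' @export
write_dataset <- function(samples, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stopf("cannot create output directory '%s'", out_dir)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    fn <- paste0(s$meta$id %||% sprintf("sample_%04d", i), ".png")
    EBImage::writeImage(EBImage::Image(s$pixels), file.path(out_dir, fn),
                        type = "png", bits.per.sample = 8L)
    data.frame(filename = fn, label = s$label,
               seed = s$meta$seed %||% NA_integer_,
               params_hash = params_hash(s$meta$params))
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()] (or any image dir + manifest)
#'
#' @param dir directory containing the images and `manifest.csv`
#'   (columns `filename` and `label`; other columns are carried into meta).
#' @return list of `ImageSample`s.
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stopf("no manifest.csv in '%s'", dir)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- EBImage::readImage(file.path(dir, manifest$filename[i]))
    px <- as.matrix(img)
    if (length(dim(img)) > 2L) px <- as.matrix(img[, , 1])
    structure(list(pixels = px, label = manifest$label[i],
                   meta = list(id = sub("\\.[^.]+$", "", manifest$filename[i]),
                               file = manifest$filename[i])),
              class = "gn_image_sample")
  })
}

# FNV-1a over the canonical deparse of the parameter list; stable across
# sessions (no serialization involved).
params_hash <- function(params) {
  s <- paste(deparse(unclass(params)), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Blob-count baseline classifier
#'
#' A deliberately simple reference classifier for the synthetic task: blur
#' the image, threshold it at a dark-intensity cutoff, count connected
#' components at least `min_area` pixels large, and call the image Positive
#' when at least one such dark blob exists. Used as a learnability check:
#' any model worth training should beat or match it at low noise.
#'
#' @param samples list of `ImageSample`s.
#' @param cutoff gray-level threshold below which pixels count as dense.
#' @param min_area minimum blob area in pixels.
#' @return integer 0/1 predictions (1 = Positive).
#' @export
blob_count_classifier <- function(samples, cutoff = 0.3, min_area = 10) {
  vapply(samples, function(s) {
    sm <- gblur_safe(s$pixels, sigma = 2)
    lab <- EBImage::bwlabel(EBImage::Image(sm < cutoff))
    areas <- tabulate(as.integer(lab))
    as.integer(any(areas >= min_area))
  }, integer(1))
}
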