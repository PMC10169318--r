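test_that("generation is deterministic and negatives contain no deposits", {
  p <- synth_params(image_size = 64L, granule_radius = c(3, 6),
                    n_granules = c(1L, 3L))
  a <- generate_image("Negative", p, seed = 1)
  b <- generate_image("Negative", p, seed = 1)
  expect_identical(a$pixels, b$pixels)
  expect_false(any(a$meta$granule_mask))
  expect_identical(nrow(a$meta$granules), 0L)
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))

  pos1 <- generate_image("Positive", p, seed = 2)
  pos2 <- generate_image("Positive", p, seed = 2)
  expect_identical(pos1$pixels, pos2$pixels)
  expect_true(any(pos1$meta$granule_mask))
})

test_that("deposit masks are darker inside than outside, by construction", {
  p <- synth_params(image_size = 96L)
  for (seed in 2:5) {
    s <- generate_image("Positive",
                        synth_params(image_size = 96L, n_granules = c(2L, 4L),
                                     granule_radius = c(4, 8)), seed = seed)
    m <- s$meta$granule_mask
    expect_lt(mean(s$pixels[m]), mean(s$pixels[!m]))
  }
})

test_that("every painted deposit's fitted radius lies in the requested range", {
  p <- synth_params(image_size = 160L, granule_radius = c(5, 9),
                    n_granules = c(3L, 6L))
  for (seed in c(3, 13, 23)) {
    s <- generate_image("Positive", p, seed = seed)
    comp <- measure_components(s$meta$granule_mask)
    expect_identical(nrow(comp), nrow(s$meta$granules))
    expect_true(all(comp$radius >= 5 & comp$radius <= 9))
  }
})

test_that("datasets are exactly balanced, sized, and reproducible", {
  p <- synth_params(image_size = 32L, granule_radius = c(2, 4),
                    n_granules = c(1L, 2L), background_texture_scale = 6,
                    membrane_curves = 1L)
  ds <- generate_dataset(10, p, seed = 0)
  expect_length(ds, 20L)
  expect_identical(sum(sample_labels(ds)), 10L)
  ds2 <- generate_dataset(10, p, seed = 0)
  for (i in seq_along(ds))
    expect_identical(ds[[i]]$pixels, ds2[[i]]$pixels)

  expect_length(generate_dataset(1, p, seed = 0), 2L)
  expect_identical(sort(unique(vapply(generate_dataset(1, p, seed = 0),
                                      function(s) s$label, ""))),
                   c("Negative", "Positive"))
})

test_that("the reference corpus geometry (455 per class -> 910) is reproduced", {
  p <- synth_params(image_size = 32L, granule_radius = c(2, 4),
                    n_granules = c(1L, 2L), background_texture_scale = 6,
                    membrane_curves = 1L)
  ds <- generate_dataset(455, p, seed = 0)
  expect_length(ds, 910L)
  expect_identical(sum(sample_labels(ds)), 455L)
  expect_identical(anyDuplicated(vapply(ds, function(s) s$meta$id, "")), 0L)
})

test_that("per-sample seeds depend only on (master seed, index, label)", {
  expect_identical(derive_seed(7, 3, 1L), derive_seed(7, 3, 1L))
  expect_false(derive_seed(7, 3, 1L) == derive_seed(7, 3, 2L))
  expect_false(derive_seed(7, 3, 1L) == derive_seed(8, 3, 1L))
  seeds <- vapply(1:200, function(i) derive_seed(0, i, 1L), integer(1))
  expect_identical(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("invalid generator parameters are rejected", {
  expect_error(synth_params(granule_radius = c(0.5, 3)), "radius")
  expect_error(synth_params(granule_intensity_drop = 0), "intensity_drop")
  expect_error(synth_params(granule_intensity_drop = 1.2), "intensity_drop")
  expect_error(synth_params(n_granules = c(3, 1)), "n_granules")
  expect_error(synth_params(noise_sd = -0.1), "noise_sd")
  expect_error(generate_dataset(0, synth_params()), "n_per_class")
})

test_that("the blob-count baseline solves the default low-noise task", {
  ds <- generate_dataset(25, synth_params(), seed = 5)
  acc <- mean(blob_count_classifier(ds) == sample_labels(ds))
  expect_gte(acc, 0.95)
})

test_that("round-tripping a dataset through PNG + manifest preserves labels", {
  dir <- withr::local_tempdir()
  p <- synth_params(image_size = 48L, granule_radius = c(3, 6),
                    n_granules = c(1L, 2L))
  ds <- generate_dataset(3, p, seed = 4)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_dataset(dir)
  expect_length(back, 6L)
  expect_identical(sample_labels(back), sample_labels(ds))
  # 8-bit quantization: pixels match to half a gray level
  for (i in seq_along(ds))
    expect_lt(max(abs(back[[i]]$pixels - ds[[i]]$pixels)), 1 / 255)
})
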