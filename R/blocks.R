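# Residual units of the ResNet-50 family.
#
# Both block types run a three-convolution bottleneck main path
# (1x1 -> 3x3 -> 1x1, each followed by batch norm, ReLU after the first two)
# and add a shortcut before the final ReLU:
#   identity block:       H(x) = ReLU(F(x, {Wi}) + x)
#   convolutional block:  H(x) = ReLU(F(x, {Wi}) + Ws x)
# where Ws is a learned 1x1 projection (with batch norm) that matches the
# shortcut to the main path's channels and stride.

#' Residual block specification
#'
#' @param kind `"identity"` (shortcut adds the unmodified input) or
#'   `"convolutional"` (shortcut applies a strided 1x1 projection `Ws`).
#' @param filters integer triple: channels of the three bottleneck
#'   convolutions, e.g. `c(64, 64, 256)`.
#' @param stride stride of the block (applied in the first 1x1 convolution
#'   and the shortcut projection); must be 1 for identity blocks.
#' @return a `gn_block_spec` object.
#' @export
residual_block_spec <- function(kind = c("identity", "convolutional"),
                                filters, stride = 1L) {
  kind <- match.arg(kind)
  filters <- as.integer(filters)
  if (length(filters) != 3L || any(filters < 1L))
    stopf("filters must be a triple of positive channel counts")
  stride <- as.integer(stride)
  if (stride < 1L) stopf("stride must be >= 1")
  if (kind == "identity" && stride != 1L)
    stopf("identity blocks cannot change spatial resolution (stride must be 1)")
  structure(list(kind = kind, filters = filters, stride = stride),
            class = "gn_block_spec")
}

# He-normal kernel initializer (fan-in scaling), the standard choice for
# ReLU networks; keeps activation variance roughly constant through depth.
init_kernel <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Initialize weights for one residual block
#'
#' Draws He-normal kernels from the current RNG stream; batch-norm layers
#' start at frozen identity statistics (`mean = 0`, `var = 1`, `gamma = 1`,
#' `beta = 0`).
#'
#' @param spec a [residual_block_spec()].
#' @param in_channels channels of the block input.
#' @return a weight list consumable by [identity_block()] /
#'   [convolutional_block()].
#' @export
init_block_weights <- function(spec, in_channels) {
  f <- spec$filters
  if (spec$kind == "identity" && in_channels != f[3])
    stopf("identity block requires input channels (%d) = output channels (%d)",
          in_channels, f[3])
  w <- list(
    conv1 = init_kernel(1L, 1L, in_channels, f[1]), bn1 = bn_params(f[1]),
    conv2 = init_kernel(3L, 3L, f[1], f[2]),        bn2 = bn_params(f[2]),
    conv3 = init_kernel(1L, 1L, f[2], f[3]),        bn3 = bn_params(f[3])
  )
  if (spec$kind == "convolutional") {
    w$shortcut <- init_kernel(1L, 1L, in_channels, f[3])
    w$bn_s <- bn_params(f[3])
  }
  w
}

# F(x, {Wi}): the bottleneck main path shared by both block kinds.
block_main_path <- function(x, weights, stride) {
  h <- conv2d(x, weights$conv1, stride = stride)
  h <- relu(batch_norm(h, weights$bn1))
  h <- conv2d(h, weights$conv2, stride = 1L, pad = 1L)
  h <- relu(batch_norm(h, weights$bn2))
  h <- conv2d(h, weights$conv3)
  batch_norm(h, weights$bn3)
}

#' Apply an identity residual block
#'
#' Computes `ReLU(F(x, {Wi}) + x)`: the shortcut adds the unmodified input,
#' so spatial dimensions and channel count are preserved. With a zero
#' residual branch, identity batch norm and non-negative input the block is
#' an exact pass-through.
#'
#' @param x activation array `[H, W, C]`.
#' @param spec a [residual_block_spec()] of kind `"identity"`.
#' @param weights weight list from [init_block_weights()] (or hand-set).
#' @param stage optional stage label used in error messages.
#' @return activation array `[H, W, C]`.
#' @export
identity_block <- function(x, spec, weights, stage = "?") {
  if (spec$kind != "identity") stopf("spec is not an identity block")
  if (dim(x)[3] != spec$filters[3])
    stopf("stage %s identity block: input has %d channels, block outputs %d",
          stage, dim(x)[3], spec$filters[3])
  relu(block_main_path(x, weights, stride = 1L) + x)
}

#' Apply a convolutional residual block
#'
#' Computes `ReLU(F(x, {Wi}) + Ws x)` where the shortcut projection `Ws`
#' (a strided 1x1 convolution plus batch norm) maps the input to the main
#' path's output channels and resolution.
#'
#' @inheritParams identity_block
#' @return activation array `[H/stride, W/stride, filters[3]]`.
#' @export
convolutional_block <- function(x, spec, weights, stage = "?") {
  if (spec$kind != "convolutional") stopf("spec is not a convolutional block")
  if (dim(x)[3] != dim(weights$conv1)[3])
    stopf("stage %s convolutional block: input has %d channels, expected %d",
          stage, dim(x)[3], dim(weights$conv1)[3])
  main <- block_main_path(x, weights, stride = spec$stride)
  short <- conv2d(x, weights$shortcut, stride = spec$stride)
  short <- batch_norm(short, weights$bn_s)
  relu(main + short)
}
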