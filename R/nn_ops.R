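# Tensor primitives for the residual backbone.
#
# Activations are dense 3-D arrays [height, width, channels]. Convolutions
# are evaluated by im2col: gather every receptive-field patch into a row of
# a matrix, then one BLAS matrix product against the reshaped kernel. This
# is the standard lowering used by CPU deep-learning runtimes and is what
# makes a full-scale 50-layer forward pass take seconds rather than hours.

#' 2-D convolution (single image, multi-channel)
#'
#' @param x activation array `[H, W, C_in]`.
#' @param W kernel array `[kh, kw, C_in, C_out]`.
#' @param bias optional length-`C_out` bias vector.
#' @param stride positive integer stride (same in both dimensions).
#' @param pad non-negative integer zero-padding on every side.
#' @return activation array `[H', W', C_out]` with
#'   `H' = (H + 2 pad - kh) %/% stride + 1`.
#' @export
conv2d <- function(x, W, bias = NULL, stride = 1L, pad = 0L) {
  d <- dim(x); kd <- dim(W)
  if (length(d) != 3L || length(kd) != 4L)
    stopf("conv2d expects a 3-D input and a 4-D kernel")
  if (d[3] != kd[3])
    stopf("channel mismatch: input has %d channels, kernel expects %d",
          d[3], kd[3])
  stride <- as.integer(stride); pad <- as.integer(pad)
  if (stride < 1L) stopf("stride must be >= 1")
  patches <- im2col(x, kd[1], kd[2], stride, pad, fill = 0)
  out <- patches$mat %*% matrix(W, kd[1] * kd[2] * kd[3], kd[4])
  if (!is.null(bias)) out <- sweep(out, 2L, bias, "+")
  array(out, c(patches$Ho, patches$Wo, kd[4]))
}

# Lower a padded 3-D array into the patch matrix [Ho*Wo, kh*kw*C].
# Column order is (kh fastest, then kw, then channel), matching the memory
# layout of a kernel array dim = c(kh, kw, C, ...).
im2col <- function(x, kh, kw, stride, pad, fill = 0) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  if (pad > 0L) {
    xp <- array(fill, c(Hp, Wp, C))
    xp[(pad + 1L):(pad + H), (pad + 1L):(pad + W), ] <- x
  } else xp <- x
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) stopf("kernel larger than padded input")
  hs <- seq.int(1L, by = stride, length.out = Ho)
  ws <- seq.int(1L, by = stride, length.out = Wo)
  starts <- as.vector(outer(hs, (ws - 1L) * Hp, "+"))
  offs <- as.vector(outer(as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * Hp, "+")),
                          (0:(C - 1L)) * (Hp * Wp), "+"))
  # flatten the index matrix: an n x 3 numeric matrix would otherwise be
  # interpreted as per-row (i, j, k) coordinates into the 3-D array
  list(mat = matrix(xp[as.vector(outer(starts, offs, "+"))], Ho * Wo, kh * kw * C),
       Ho = Ho, Wo = Wo)
}

#' Max pooling
#'
#' @inheritParams conv2d
#' @param size pooling window side length.
#' @return pooled activation array.
#' @export
max_pool2d <- function(x, size = 3L, stride = 2L, pad = 1L) {
  d <- dim(x); C <- d[3]
  p <- im2col(x, as.integer(size), as.integer(size), as.integer(stride),
              as.integer(pad), fill = -Inf)
  k2 <- as.integer(size)^2
  # p$mat is [Ho*Wo, size*size*C]; reduce each channel's k2 columns by max
  out <- matrix(0, nrow(p$mat), C)
  for (c in seq_len(C)) {
    block <- p$mat[, ((c - 1L) * k2 + 1L):(c * k2), drop = FALSE]
    out[, c] <- do.call(pmax, c(asplit(block, 2L), list(na.rm = FALSE)))
  }
  array(out, c(p$Ho, p$Wo, C))
}

#' Global average pooling
#'
#' Collapses the spatial dimensions, returning one mean per channel.
#' @param x activation array `[H, W, C]`.
#' @return numeric vector of length `C`.
#' @export
global_avg_pool <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

relu <- function(x) pmax(x, 0)

#' Batch-normalization parameters
#'
#' Inference-mode batch normalization with frozen running statistics:
#' `y = gamma * (x - mean) / sqrt(var + eps) + beta`, applied per channel.
#' `bn_identity()` returns parameters that make the layer an exact no-op
#' (`eps = 0`), used for algebraic pass-through checks.
#'
#' @param channels number of channels.
#' @param gamma,beta,mean,var per-channel parameter vectors (recycled).
#' @param eps numerical-stability constant.
#' @return a `gn_bn` parameter list.
#' @export
bn_params <- function(channels, gamma = 1, beta = 0, mean = 0, var = 1,
                      eps = 1e-5) {
  structure(list(gamma = rep_len(gamma, channels),
                 beta = rep_len(beta, channels),
                 mean = rep_len(mean, channels),
                 var = rep_len(var, channels),
                 eps = eps), class = "gn_bn")
}

#' @rdname bn_params
#' @export
bn_identity <- function(channels) bn_params(channels, eps = 0)

batch_norm <- function(x, bn) {
  d <- dim(x); C <- d[3]
  scale <- bn$gamma / sqrt(bn$var + bn$eps)
  shift <- bn$beta - bn$mean * scale
  m <- matrix(x, d[1] * d[2], C)
  m <- sweep(sweep(m, 2L, scale, "*"), 2L, shift, "+")
  array(m, d)
}
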