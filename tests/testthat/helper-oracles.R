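# Independent oracles used to cross-check the implementation. These are
# deliberately naive (loops, exhaustive enumeration) and share no code
# with the package internals they verify.

# Direct quadruple-loop 2-D convolution.
conv2d_naive <- function(x, W, stride = 1L, pad = 0L) {
  d <- dim(x); kd <- dim(W)
  Hp <- d[1] + 2L * pad; Wp <- d[2] + 2L * pad
  xp <- array(0, c(Hp, Wp, d[3]))
  xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  Ho <- (Hp - kd[1]) %/% stride + 1L
  Wo <- (Wp - kd[2]) %/% stride + 1L
  out <- array(0, c(Ho, Wo, kd[4]))
  for (oc in seq_len(kd[4]))
    for (i in seq_len(Ho))
      for (j in seq_len(Wo)) {
        acc <- 0
        for (ic in seq_len(d[3]))
          for (u in seq_len(kd[1]))
            for (v in seq_len(kd[2]))
              acc <- acc + xp[(i - 1L) * stride + u, (j - 1L) * stride + v, ic] *
                W[u, v, ic, oc]
        out[i, j, oc] <- acc
      }
  out
}

bn_naive <- function(x, bn) {
  out <- x
  for (c in seq_len(dim(x)[3]))
    out[, , c] <- bn$gamma[c] * (x[, , c] - bn$mean[c]) /
      sqrt(bn$var[c] + bn$eps) + bn$beta[c]
  out
}

relu_naive <- function(x) { x[x < 0] <- 0; x }

# Residual block forward written directly from the defining equations,
# using only the naive primitives above.
block_naive <- function(x, spec, weights) {
  h <- conv2d_naive(x, weights$conv1, stride = spec$stride)
  h <- relu_naive(bn_naive(h, weights$bn1))
  h <- conv2d_naive(h, weights$conv2, stride = 1L, pad = 1L)
  h <- relu_naive(bn_naive(h, weights$bn2))
  h <- bn_naive(conv2d_naive(h, weights$conv3), weights$bn3)
  short <- if (spec$kind == "identity") x
           else bn_naive(conv2d_naive(x, weights$shortcut,
                                      stride = spec$stride), weights$bn_s)
  relu_naive(h + short)
}

# Tiny SMO solver for the soft-margin dual: repeated analytic pairwise
# updates with box clipping, suitable for n <= ~10. Returns alpha and the
# dual objective.
smo_oracle <- function(K, y, C, sweeps = 5000L, tol = 1e-12) {
  n <- length(y)
  a <- rep(0, n)
  Q <- K * outer(y, y)
  for (sweep in seq_len(sweeps)) {
    delta <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (eta <= 1e-15) next
      f <- as.vector(Q %*% a)              # f_k = y_k * decision_k (no bias)
      dec <- y * f                          # decision values
      Ei <- dec[i] - y[i]; Ej <- dec[j] - y[j]
      aj_new <- a[j] + y[j] * (Ei - Ej) / eta
      # bounds keeping y.a constant
      if (y[i] != y[j]) {
        L <- max(0, a[j] - a[i]); H <- min(C, C + a[j] - a[i])
      } else {
        L <- max(0, a[i] + a[j] - C); H <- min(C, a[i] + a[j])
      }
      aj_new <- min(max(aj_new, L), H)
      ai_new <- a[i] + y[i] * y[j] * (a[j] - aj_new)
      delta <- delta + abs(aj_new - a[j])
      a[j] <- aj_new; a[i] <- ai_new
    }
    if (delta < tol) break
  }
  list(alpha = a, objective = sum(a) - 0.5 * as.numeric(t(a * y) %*% K %*% (a * y)))
}

dual_objective_of <- function(alpha, K, y)
  sum(alpha) - 0.5 * as.numeric(t(alpha * y) %*% K %*% (alpha * y))

# AUROC as the exhaustive pairwise concordance statistic: fraction of
# (positive, negative) pairs ranked correctly, ties counting one half.
concordance_auroc <- function(y, s) {
  pos <- s[y == 1L]; neg <- s[y == 0L]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Connected-component measurement of a binary mask: per-component pixel
# area and equivalent radius sqrt(area / pi).
measure_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- tabulate(as.integer(lab))
  data.frame(area = areas, radius = sqrt(areas / pi))
}

# Small helpers to build hand-set block weights with exact-identity batch
# norm, for algebraic checks.
zero_block_weights <- function(spec, in_channels) {
  w <- init_block_weights(spec, in_channels)
  for (nm in c("conv1", "conv2", "conv3")) w[[nm]][] <- 0
  for (nm in c("bn1", "bn2", "bn3"))
    w[[nm]] <- bn_identity(length(w[[nm]]$gamma))
  if (!is.null(w$shortcut)) {
    w$shortcut[] <- 0
    w$bn_s <- bn_identity(length(w$bn_s$gamma))
  }
  w
}

random_block_weights <- function(spec, in_channels, seed) {
  set.seed(seed)
  w <- init_block_weights(spec, in_channels)
  # randomize batch-norm statistics too, so the oracle checks the full
  # inference formula rather than the identity special case
  for (nm in c("bn1", "bn2", "bn3", "bn_s")) {
    if (is.null(w[[nm]])) next
    ch <- length(w[[nm]]$gamma)
    w[[nm]] <- bn_params(ch, gamma = stats::runif(ch, 0.5, 1.5),
                         beta = stats::rnorm(ch, sd = 0.2),
                         mean = stats::rnorm(ch, sd = 0.2),
                         var = stats::runif(ch, 0.5, 2))
  }
  w
}

tiny_synth <- function(noise_sd = 0.03)
  synth_params(image_size = 64L, n_granules = c(2L, 4L),
               granule_radius = c(4, 8), background_texture_scale = 12,
               noise_sd = noise_sd, membrane_curves = 2L)
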