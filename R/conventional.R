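# Conventional baseline: the unmodified five-stage backbone (no skip
# concatenation) with a fully connected softmax classifier on the
# global-average-pooled stage-5 features.
#
# The backbone runs as a frozen feature extractor; the classification head
# (one fully connected layer + softmax over the two classes) is trained by
# minibatch Adam on the cross-entropy loss. With no pretrained weight
# archive, the backbone weights are a seeded random draw and only the head
# learns — a randomized-network linear probe, the standard design when a
# deep trunk is frozen.

#' Training configuration for the softmax head
#'
#' The default learning rate, optimizer, loss and epoch count follow the
#' transfer-learning configuration (Adam, cross-entropy, 10 epochs,
#' learning rate 1e-5). Note that 1e-5 is sized for fine-tuning a
#' pretrained trunk; when training a randomly initialized head from
#' scratch, pass a head-scale rate (e.g. 0.05) or the weights will barely
#' move in 10 epochs.
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size minibatch size.
#' @param seed integer seed for shuffling and head initialization.
#' @param optimizer,loss tags; only `"adam"` and `"cross-entropy"` are
#'   implemented.
#' @return a `gn_train_config` object.
#' @export
train_config <- function(learning_rate = 1e-5, epochs = 10L,
                         batch_size = 16L, seed = 0L,
                         optimizer = "adam", loss = "cross-entropy") {
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  if (!identical(optimizer, "adam")) stopf("only the adam optimizer is implemented")
  if (!identical(loss, "cross-entropy")) stopf("only cross-entropy loss is implemented")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 optimizer = optimizer, loss = loss),
            class = "gn_train_config")
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Minibatch Adam on multinomial logistic regression (softmax head).
# X: n x d standardized features; y01: 0/1 labels. Returns W (d x 2), b (2),
# and the per-epoch mean cross-entropy trace.
train_softmax_head <- function(X, y01, cfg) {
  n <- nrow(X); d <- ncol(X)
  Y <- cbind(1 - y01, y01)               # column 2 = P(Positive)
  with_seed(cfg$seed, {
    W <- matrix(stats::rnorm(d * 2L, sd = 0.01), d, 2L)
    b <- c(0, 0)
    mW <- vW <- matrix(0, d, 2L); mb <- vb <- c(0, 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0L
    trace <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        Z <- sweep(Xb %*% W, 2L, b, "+")
        P <- t(apply(Z, 1L, softmax))
        G <- (P - Yb) / length(idx)       # d CE / d logits
        gW <- crossprod(Xb, G); gb <- colSums(G)
        t <- t + 1L
        mW <- beta1 * mW + (1 - beta1) * gW; vW <- beta2 * vW + (1 - beta2) * gW^2
        mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
        W <- W - cfg$learning_rate * (mW / (1 - beta1^t)) /
          (sqrt(vW / (1 - beta2^t)) + eps)
        b <- b - cfg$learning_rate * (mb / (1 - beta1^t)) /
          (sqrt(vb / (1 - beta2^t)) + eps)
      }
      Z <- sweep(X %*% W, 2L, b, "+")
      P <- t(apply(Z, 1L, softmax))
      trace[epoch] <- -mean(log(pmax(P[cbind(seq_len(n), y01 + 1L)], 1e-12)))
    }
    list(W = W, b = b, loss_trace = trace)
  })
}

#' Train the conventional baseline model
#'
#' @param samples labeled `ImageSample`s (both classes required).
#' @param spec a [backbone_spec()]; the backbone is built with
#'   `seed = cfg$seed` and frozen.
#' @param cfg a [train_config()].
#' @param extractor optionally, a pre-built backbone to reuse (its spec
#'   must match).
#' @param features optionally, a precomputed pooled stage-5 feature matrix
#'   for `samples` (rows aligned), to avoid re-extracting.
#' @return a `gn_conventional` model (frozen extractor + trained softmax
#'   head + scaler + loss trace).
#' @export
train_conventional <- function(samples, spec = backbone_spec("tiny"),
                               cfg = train_config(), extractor = NULL,
                               features = NULL) {
  y01 <- sample_labels(samples)
  if (length(unique(y01)) < 2L)
    stopf("training requires both classes; got a single-class dataset")
  if (is.null(extractor)) extractor <- build_backbone(spec, seed = cfg$seed)
  if (is.null(features)) features <- feature_matrix(extractor, samples, pooled = TRUE)
  scaler <- fit_scaler(features)
  Xs <- apply_scaler(features, scaler)
  head <- train_softmax_head(Xs, y01, cfg)
  structure(list(extractor = extractor, scaler = scaler, W = head$W,
                 b = head$b, loss_trace = head$loss_trace, cfg = cfg,
                 trained = TRUE),
            class = "gn_conventional")
}

#' Probability of the Positive class under the conventional model
#'
#' @param model a trained `gn_conventional`.
#' @param image an `ImageSample` (or grayscale matrix); alternatively pass
#'   `pooled` to skip feature extraction.
#' @param pooled optional precomputed pooled stage-5 feature vector.
#' @return `P(Positive)` in `[0, 1]`; `P(Positive) + P(Negative) = 1` by
#'   construction.
#' @export
predict_proba <- function(model, image = NULL, pooled = NULL) {
  if (!inherits(model, "gn_conventional") || !isTRUE(model$trained))
    stopf("model has not been trained")
  if (is.null(pooled)) {
    fm <- extract_features(model$extractor, image)
    pooled <- fm$pooled5
  }
  x <- (pooled - model$scaler$mean) / model$scaler$sd
  p <- softmax(as.vector(x %*% model$W) + model$b)
  unname(p[2])
}

#' @rdname predict_proba
#' @param features matrix of pooled stage-5 rows.
#' @return numeric vector of `P(Positive)`.
#' @export
predict_proba_matrix <- function(model, features) {
  apply(features, 1L, function(r) predict_proba(model, pooled = r))
}
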