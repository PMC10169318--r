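# ANN stacking combiner.
#
# The multi-model takes the two base models' scalar outputs — the improved
# (skip + SVM) model's logistic-linked decision score and the conventional
# model's softmax P(Positive) — and learns the mapping from that pair to
# the ground-truth label with a small feed-forward network: 2 input
# neurons, one hidden layer, one sigmoid output. Because the base models'
# scores relate nonlinearly to the truth, the combiner is given a hidden
# layer rather than a linear weighting.

#' Fit the 2-input stacking combiner
#'
#' Trains a 2 - `hidden` - 1 network (sigmoid activations throughout) by
#' full-batch gradient descent on cross-entropy. Training stops early when
#' the loss improvement over 25 consecutive epochs falls below `1e-8`.
#'
#' @param scores_improved numeric vector in `(0, 1)`: improved-model scores.
#' @param scores_conventional numeric vector in `(0, 1)`: conventional-model
#'   scores.
#' @param labels 0/1 ground-truth labels (both classes required).
#' @param seed integer seed for weight initialization.
#' @param hidden hidden-layer width (>= 1).
#' @param learning_rate gradient-descent step size.
#' @param epochs maximum epochs.
#' @return a `gn_combiner` model (weights + loss trace).
#' @export
fit_combiner <- function(scores_improved, scores_conventional, labels,
                         seed = 0L, hidden = 4L, learning_rate = 2,
                         epochs = 2000L) {
  s1 <- as.numeric(scores_improved); s2 <- as.numeric(scores_conventional)
  y <- as.numeric(labels)
  if (length(s1) != length(s2) || length(s1) != length(y))
    stopf("scores_improved, scores_conventional and labels must have equal length")
  assert_finite(c(s1, s2), "combiner inputs")
  if (!all(y %in% c(0, 1))) stopf("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stopf("combiner training requires both classes")
  hidden <- as.integer(hidden)
  if (hidden < 1L) stopf("hidden width must be >= 1")
  X <- cbind(s1, s2)
  n <- nrow(X)
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(2L * hidden, sd = 1), 2L, hidden)
    b1 <- stats::rnorm(hidden, sd = 0.1)
    W2 <- matrix(stats::rnorm(hidden, sd = 1), hidden, 1L)
    b2 <- 0
    trace <- numeric(0)
    best <- Inf; stall <- 0L
    for (epoch in seq_len(epochs)) {
      H <- stats::plogis(sweep(X %*% W1, 2L, b1, "+"))   # n x hidden
      p <- stats::plogis(as.vector(H %*% W2) + b2)       # n
      loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
      trace <- c(trace, loss)
      if (loss < best - 1e-8) { best <- loss; stall <- 0L } else stall <- stall + 1L
      if (stall >= 25L) break
      d_out <- (p - y) / n                                # d CE / d logit
      gW2 <- crossprod(H, d_out); gb2 <- sum(d_out)
      dH <- (d_out %*% t(W2)) * H * (1 - H)
      gW1 <- crossprod(X, dH); gb1 <- colSums(dH)
      W1 <- W1 - learning_rate * gW1; b1 <- b1 - learning_rate * gb1
      W2 <- W2 - learning_rate * gW2; b2 <- b2 - learning_rate * gb2
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, hidden = hidden,
                   loss_trace = trace, trained = TRUE),
              class = "gn_combiner")
  })
}

#' Combiner forward pass on score pairs
#'
#' @param combiner a fitted `gn_combiner`.
#' @param scores_improved,scores_conventional score vectors in `(0, 1)`.
#' @return final scores in `[0, 1]`.
#' @export
combiner_score <- function(combiner, scores_improved, scores_conventional) {
  if (!inherits(combiner, "gn_combiner") || !isTRUE(combiner$trained))
    stopf("combiner has not been trained")
  X <- cbind(as.numeric(scores_improved), as.numeric(scores_conventional))
  H <- stats::plogis(sweep(X %*% combiner$W1, 2L, combiner$b1, "+"))
  stats::plogis(as.vector(H %*% combiner$W2) + combiner$b2)
}

#' Assemble the stacked multi-model
#'
#' @param improved a fitted `gn_svm` (with its feature extractor attached
#'   via `extractor`).
#' @param conventional a trained `gn_conventional`.
#' @param combiner a fitted `gn_combiner`.
#' @param extractor the skip-feature backbone used by the improved model.
#' @return a `gn_stacked` model.
#' @export
stacked_model <- function(improved, conventional, combiner, extractor) {
  for (ok in list(c(inherits(improved, "gn_svm"), "improved model"),
                  c(inherits(conventional, "gn_conventional") &&
                    isTRUE(conventional$trained), "conventional model"),
                  c(inherits(combiner, "gn_combiner") &&
                    isTRUE(combiner$trained), "combiner")))
    if (!as.logical(ok[1])) stopf("%s is not trained", ok[2])
  structure(list(improved = improved, conventional = conventional,
                 combiner = combiner, extractor = extractor),
            class = "gn_stacked")
}

#' Predict with the stacked multi-model
#'
#' Runs both base models on the image, feeds their two scalar scores to
#' the combiner, and thresholds the final score at 0.5 for the hard label.
#'
#' @param model a `gn_stacked` model.
#' @param image an `ImageSample` or grayscale matrix.
#' @return list with `score` in `[0, 1]`, `label` (0/1),
#'   `score_improved`, `score_conventional`.
#' @export
combine_predict <- function(model, image) {
  if (!inherits(model, "gn_stacked")) stopf("model is not a gn_stacked model")
  fm <- extract_features(model$extractor, image)
  s_imp <- svm_score(model$improved, matrix(fm$flat, nrow = 1L))
  s_conv <- if (identical(model$conventional$extractor$spec,
                          model$extractor$spec) &&
                identical(model$conventional$extractor$seed,
                          model$extractor$seed))
    predict_proba(model$conventional, pooled = fm$pooled5)
  else predict_proba(model$conventional, image)
  s <- combiner_score(model$combiner, s_imp, s_conv)
  list(score = s, label = as.integer(s >= 0.5),
       score_improved = s_imp, score_conventional = s_conv)
}
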