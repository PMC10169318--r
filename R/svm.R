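# Support-vector-machine head on concatenated deep features.
#
# The classifier solves the soft-margin dual
#   max_a  W(a) = sum_i a_i - 1/2 sum_ij a_i a_j y_i y_j K(x_i, x_j)
#   s.t.   sum_i a_i y_i = 0,  0 <= a_i <= C
# and predicts with f(x) = sum_i a_i y_i K(x_i, x) + b. The quadratic
# program is delegated to the libsvm SMO solver (via e1071); the decision
# function, the kernels, feature standardization and the dual bookkeeping
# are implemented here so the fitted model can be audited against the dual
# constraints directly.

#' Kernel specification
#'
#' @param kernel `"radial"`, `"linear"` or `"polynomial"`.
#' @param gamma RBF / polynomial scale; `NULL` selects the
#'   `1 / (d * mean feature variance)` heuristic at fit time.
#' @param degree,coef0 polynomial kernel parameters.
#' @return a `gn_kernel` list.
#' @export
kernel_spec <- function(kernel = c("radial", "linear", "polynomial"),
                        gamma = NULL, degree = 3, coef0 = 0) {
  kernel <- match.arg(kernel)
  structure(list(kernel = kernel, gamma = gamma, degree = degree,
                 coef0 = coef0), class = "gn_kernel")
}

#' Kernel Gram matrix between row sets
#'
#' @param X,Y numeric matrices with matching column counts.
#' @param spec a [kernel_spec()] with `gamma` resolved.
#' @return `nrow(X) x nrow(Y)` kernel matrix.
#' @export
kernel_matrix <- function(X, Y, spec) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  switch(spec$kernel,
    linear = X %*% t(Y),
    radial = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
      exp(-spec$gamma * pmax(d2, 0))
    },
    polynomial = (spec$gamma * (X %*% t(Y)) + spec$coef0)^spec$degree)
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}

#' Fit the SVM head
#'
#' Standardizes features per dimension (statistics from the training rows
#' only), resolves the kernel scale, and solves the soft-margin dual with
#' the SMO solver. The returned model stores the support vectors, dual
#' coefficients, bias and scaler; [svm_dual_diagnostics()] verifies the box
#' and equality constraints post-fit.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels vector in `{-1, +1}` (or 0/1, which is mapped to -1/+1).
#' @param C soft-margin penalty (> 0).
#' @param kernel a [kernel_spec()].
#' @param standardize standardize features before the kernel (recommended
#'   for raw deep activations, whose per-dimension scales vary wildly).
#' @return a fitted `gn_svm` model.
#' @export
fit_svm <- function(features, labels, C = 1, kernel = kernel_spec(),
                    standardize = TRUE) {
  features <- as.matrix(features)
  assert_finite(features, "features")
  y <- as.integer(labels)
  y[y == 0L] <- -1L
  if (!all(y %in% c(-1L, 1L))) stopf("labels must be in {-1, +1} (or 0/1)")
  if (length(y) != nrow(features)) stopf("labels/features length mismatch")
  if (length(unique(y)) < 2L)
    stopf("training requires both classes; got a single-class dataset")
  if (C <= 0) stopf("penalty C must be > 0")

  scaler <- if (standardize) fit_scaler(features) else NULL
  Xs <- apply_scaler(features, scaler)
  kern <- kernel
  if (is.null(kern$gamma)) {
    v <- mean(apply(Xs, 2L, stats::var))
    kern$gamma <- 1 / (ncol(Xs) * max(v, 1e-12))
  }
  fit <- e1071::svm(x = Xs, y = factor(y, levels = c(-1L, 1L)),
                    type = "C-classification", scale = FALSE,
                    kernel = kern$kernel, cost = C, gamma = kern$gamma,
                    degree = kern$degree, coef0 = kern$coef0)
  # e1071 orders coefs by its internal class order; recover alpha_i * y_i
  # with our +1/-1 convention from the stored labels.
  sv_idx <- fit$index
  coefs <- as.vector(fit$coefs)            # alpha_i * y_i (libsvm sign)
  y_sv <- y[sv_idx]
  # libsvm's first class is the first level seen; its decision may be for
  # -1 vs +1 — normalize so that positive decision means class +1
  flip <- if (fit$labels[1] == 2L) 1 else -1  # levels c(-1,1): label index 1 is "-1"
  alpha_signed <- flip * coefs
  b <- flip * (-fit$rho)
  model <- structure(list(
    support_vectors = Xs[sv_idx, , drop = FALSE],
    alpha = abs(alpha_signed),
    sv_labels = y_sv,
    alpha_signed = alpha_signed,
    bias = b,
    kernel = kern,
    C = C,
    scaler = scaler,
    n_features = ncol(features),
    n_train = nrow(features)
  ), class = "gn_svm")
  model
}

#' SVM decision value
#'
#' Computes `f(x) = sum_i alpha_i y_i K(x_i, x) + b` from the stored
#' support-vector expansion. Classification is `sign(f)`; a decision value
#' of exactly 0 is classified Positive (ties break toward the positive
#' class).
#'
#' @param model a fitted `gn_svm`.
#' @param features one feature vector or a matrix of rows.
#' @return numeric decision value(s).
#' @export
svm_decision <- function(model, features) {
  if (!inherits(model, "gn_svm")) stopf("model is not a fitted gn_svm")
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1L)
  if (ncol(X) != model$n_features)
    stopf("feature dimension %d does not match training dimension %d",
          ncol(X), model$n_features)
  assert_finite(X, "features")
  Xs <- apply_scaler(X, model$scaler)
  K <- kernel_matrix(model$support_vectors, Xs, model$kernel)
  as.vector(crossprod(K, model$alpha_signed)) + model$bias
}

#' @rdname svm_decision
#' @export
svm_predict <- function(model, features) {
  ifelse(svm_decision(model, features) >= 0, 1L, 0L)
}

#' SVM score in (0, 1) via a logistic link
#'
#' Maps the continuous decision value through `1 / (1 + exp(-f))`, giving
#' the numeric base-model output the stacking combiner consumes.
#'
#' @inheritParams svm_decision
#' @return numeric score(s) in `(0, 1)`.
#' @export
svm_score <- function(model, features) {
  stats::plogis(svm_decision(model, features))
}

#' Dual objective and constraint residuals of a fitted SVM
#'
#' Recomputes `W(alpha)` and the dual-feasibility diagnostics from the
#' stored expansion: the equality residual `sum_i alpha_i y_i` and the
#' worst box-constraint violation `max(0, alpha - C, -alpha)`.
#'
#' @param model a fitted `gn_svm`.
#' @return list with `objective`, `eq_residual`, `box_violation`,
#'   `n_support`.
#' @export
svm_dual_diagnostics <- function(model) {
  K <- kernel_matrix(model$support_vectors, model$support_vectors,
                     model$kernel)
  s <- model$alpha_signed                 # alpha_i * y_i
  obj <- sum(model$alpha) - 0.5 * as.numeric(t(s) %*% K %*% s)
  list(objective = obj,
       eq_residual = sum(s),
       box_violation = max(0, model$alpha - model$C, -model$alpha),
       n_support = length(model$alpha))
}
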