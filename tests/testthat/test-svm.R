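test_that("a separable toy is fit perfectly with feasible dual variables", {
  X <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  y <- c(-1, -1, 1, 1)
  m <- fit_svm(X, y, C = 10, kernel_spec("linear"), standardize = FALSE)
  expect_identical(svm_predict(m, X), as.integer(y == 1))
  d <- svm_dual_diagnostics(m)
  expect_lt(abs(d$eq_residual), 1e-6)
  expect_identical(d$box_violation, 0)
})

test_that("the fitted dual objective matches the SMO oracle on XOR", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(-1, 1, 1, -1)
  kern <- kernel_spec("radial", gamma = 1)
  m <- fit_svm(X, y, C = 10, kern, standardize = FALSE)
  expect_identical(svm_predict(m, X), as.integer(y == 1))
  K <- kernel_matrix(X, X, kern)
  oracle <- smo_oracle(K, y, C = 10)
  got <- svm_dual_diagnostics(m)
  expect_equal(got$objective, oracle$objective, tolerance = 1e-4)
})

test_that("contradictory duplicated points drive alpha to the box bounds", {
  X <- rbind(c(1, 1), c(1, 1))
  y <- c(-1, 1)
  m <- fit_svm(X, y, C = 1, kernel_spec("linear"), standardize = FALSE)
  expect_true(all(abs(m$alpha) < 1e-8 | abs(m$alpha - 1) < 1e-8))
  # the two-variable dual is W(a) = 2a maximized at a = C
  expect_equal(sort(m$alpha), c(1, 1), tolerance = 1e-8)
  expect_equal(mean(svm_predict(m, X) == as.integer(y == 1)), 0.5)
})

test_that("the decision function reproduces the kernel expansion by hand", {
  # hand-built 3-support-vector linear model: f(x) = sum a_i y_i <x_i, x> + b
  sv <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  alpha <- c(0.5, 0.25, 0.75); ys <- c(1, 1, -1); b <- 0.1
  m <- structure(list(support_vectors = sv, alpha = alpha, sv_labels = ys,
                      alpha_signed = alpha * ys, bias = b,
                      kernel = kernel_spec("linear"), C = 1, scaler = NULL,
                      n_features = 2L, n_train = 3L), class = "gn_svm")
  x <- c(2, -1)
  manual <- sum(alpha * ys * (sv %*% x)) + b
  expect_equal(svm_decision(m, x), manual, tolerance = 1e-12)
  # symmetric support sets with balanced alpha score 0 at the midpoint
  m$support_vectors <- rbind(c(1, 0), c(-1, 0))
  m$alpha <- c(0.5, 0.5); m$sv_labels <- c(1, -1)
  m$alpha_signed <- c(0.5, -0.5); m$bias <- 0
  expect_lt(abs(svm_decision(m, c(0, 5))), 1e-9)
})

test_that("support-vector signs agree with labels on separable fits", {
  set.seed(7)
  X <- rbind(matrix(rnorm(20, -3), 10, 2), matrix(rnorm(20, 3), 10, 2))
  y <- rep(c(-1, 1), each = 10)
  m <- fit_svm(X, y, C = 10, kernel_spec("radial", gamma = 0.5),
               standardize = FALSE)
  dec <- svm_decision(m, m$support_vectors)
  expect_identical(sign(dec), as.numeric(m$sv_labels))
})

test_that("no random feasible alpha beats the fitted dual objective", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 6L
    X <- matrix(rnorm(n * 2), n, 2)
    y <- c(rep(-1, 3), rep(1, 3))
    kern <- kernel_spec("radial", gamma = 0.7)
    C <- 5
    m <- fit_svm(X, y, C = C, kern, standardize = FALSE)
    obj_fit <- svm_dual_diagnostics(m)$objective
    K <- kernel_matrix(X, X, kern)
    for (draw in 1:40) {
      a <- runif(n, 0, C)
      # project onto the equality constraint, then clip back to the box
      a <- a - y * sum(a * y) / n
      a <- pmin(pmax(a, 0), C)
      a <- a - y * sum(a * y) / n
      if (any(a < -1e-9) || any(a > C + 1e-9)) next
      expect_lte(dual_objective_of(a, K, y), obj_fit + 1e-6)
    }
  }
})

test_that("feature scaling with a rescaled C leaves linear-kernel predictions unchanged", {
  set.seed(3)
  X <- matrix(rnorm(24), 12, 2)
  y <- rep(c(-1, 1), 6)
  m1 <- fit_svm(X, y, C = 2, kernel_spec("linear"), standardize = FALSE)
  s <- 10
  m2 <- fit_svm(X * s, y, C = 2 / s^2, kernel_spec("linear"),
                standardize = FALSE)
  Xnew <- matrix(rnorm(10), 5, 2)
  expect_identical(svm_predict(m1, Xnew), svm_predict(m2, Xnew * s))
})

test_that("logistic-linked scores live in (0, 1) and preserve ranking", {
  X <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  y <- c(-1, -1, 1, 1)
  m <- fit_svm(X, y, C = 10, kernel_spec("linear"), standardize = FALSE)
  sc <- svm_score(m, X)
  expect_true(all(sc > 0 & sc < 1))
  expect_identical(order(sc), order(svm_decision(m, X)))
})

test_that("degenerate inputs are rejected with informative errors", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(fit_svm(X, rep(1, 5), C = 1), "both classes")
  expect_error(fit_svm(matrix(c(1, NA, 3, 4), 2, 2), c(-1, 1), C = 1),
               "non-finite")
  expect_error(fit_svm(X, c(-1, 1, 1, -1, 1), C = -2), "C must be")
  m <- fit_svm(X, c(-1, 1, 1, -1, 1), C = 1)
  expect_error(svm_decision(m, c(1, 2, 3)), "dimension")
})
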