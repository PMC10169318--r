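# Helper: build prediction vectors realizing a given confusion matrix.
vectors_for <- function(TP, FN, FP, TN) {
  list(y_true = c(rep(1L, TP + FN), rep(0L, FP + TN)),
       y_pred = c(rep(1L, TP), rep(0L, FN), rep(1L, FP), rep(0L, TN)))
}

test_that("confusion counts follow the four-outcome taxonomy", {
  cm <- confusion_matrix(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(c(cm$TP, cm$FN, cm$FP, cm$TN), c(2L, 0L, 0L, 2L))
  cm2 <- confusion_matrix(c(1, 0), c(0, 1))
  expect_identical(c(cm2$TP, cm2$FN, cm2$FP, cm2$TN), c(0L, 1L, 1L, 0L))
  v <- vectors_for(39, 43, 26, 56)
  cm3 <- confusion_matrix(v$y_true, v$y_pred)
  expect_identical(c(cm3$TP, cm3$FN, cm3$FP, cm3$TN), c(39L, 43L, 26L, 56L))
  expect_identical(cm3$TP + cm3$FN + cm3$FP + cm3$TN, 164L)
  expect_error(confusion_matrix(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(new_confusion(-1, 0, 0, 0), "nonnegative")
})

test_that("scalar metrics match their defining ratios and edge identities", {
  cm <- new_confusion(39, 43, 26, 56)
  expect_equal(recall(cm), 39 / 82)
  expect_equal(precision(cm), 39 / 65)
  expect_equal(accuracy(cm), 95 / 164)
  expect_equal(f1_score(cm), 2 * (39 / 65) * (39 / 82) / (39 / 65 + 39 / 82))
  expect_equal(recall(new_confusion(5, 0, 3, 2)), 1)
  expect_equal(precision(new_confusion(5, 2, 0, 3)), 1)
  expect_equal(accuracy(new_confusion(4, 0, 0, 6)), 1)
  # harmonic mean of equals is the common value; F1 <= arithmetic mean
  expect_equal(f1_score(0.7, 0.7), 0.7)
  set.seed(4)
  for (i in 1:20) {
    p <- runif(1, 0.05, 1); r <- runif(1, 0.05, 1)
    expect_lte(f1_score(p, r), (p + r) / 2 + 1e-12)
  }
})

test_that("undefined metrics raise rather than returning silent zeros", {
  expect_error(recall(new_confusion(0, 0, 3, 5)), "undefined")
  expect_error(precision(new_confusion(0, 4, 0, 5)), "undefined")
  expect_error(accuracy(new_confusion(0, 0, 0, 0)), "undefined")
  expect_error(f1_score(0, 0), "undefined")
  expect_error(roc_curve(c(1, 1), c(0.2, 0.8)), "both classes")
})

test_that("ROC endpoints, monotonicity and AUROC limits hold", {
  y <- c(1, 1, 1, 0, 0, 0)
  perfect <- roc_curve(y, c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  expect_equal(perfect$auroc, 1.0)
  inverted <- roc_curve(y, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  expect_equal(inverted$auroc, 0.0)
  r <- roc_curve(y, c(0.9, 0.8, 0.4, 0.6, 0.3, 0.1))
  pts <- r$points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(r$auroc, concordance_auroc(y, c(0.9, 0.8, 0.4, 0.6, 0.3, 0.1)),
               tolerance = 1e-12)
})

test_that("trapezoidal AUROC equals pairwise concordance, with and without ties", {
  set.seed(20)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    y <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
    s <- if (i %% 2 == 0) round(runif(n), 1) else runif(n)   # force ties half the time
    expect_equal(auroc(y, s), concordance_auroc(y, s), tolerance = 1e-9)
  }
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- sample(0:1, 50, replace = TRUE)
  y[1:2] <- 0:1
  s <- runif(50)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(auroc(y, s), ref, tolerance = 1e-12)
})

test_that("label swap with negated scores mirrors AUROC", {
  set.seed(12)
  y <- c(0L, 1L, sample(0:1, 18, replace = TRUE))
  s <- runif(20)   # continuous: ties almost surely absent
  expect_equal(auroc(1L - y, s), 1 - auroc(y, s), tolerance = 1e-12)
  expect_equal(auroc(y, -s), 1 - auroc(y, s), tolerance = 1e-12)
})

test_that("random scores on balanced labels give chance-level AUROC", {
  withr::with_seed(44, {
    aucs <- replicate(30, auroc(rep(0:1, 50), runif(100)))
    se <- sd(aucs) / sqrt(length(aucs))
    expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.01)
  })
})

test_that("evaluate_model reports are internally consistent", {
  set.seed(3)
  y <- rep(c(0, 1), 20)
  s <- pmin(pmax(y * 0.5 + runif(40) * 0.6, 0), 1)
  ev <- evaluate_model(y, s)
  cm <- ev$confusion
  expect_identical(cm$TP + cm$FN + cm$FP + cm$TN, 40L)
  expect_equal(unname(ev$metrics["precision"]), precision(cm))
  expect_equal(unname(ev$metrics["f1"]), f1_score(cm))
  expect_equal(ev$metrics_2dp, round(ev$metrics, 2))
})
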