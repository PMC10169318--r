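test_that("a perfectly informative first input is learned exactly", {
  set.seed(2)
  y <- rep(c(0, 1), 20)
  s1 <- ifelse(y == 1, 0.95, 0.05)
  s2 <- runif(40)
  comb <- fit_combiner(s1, s2, y, seed = 1)
  pred <- as.integer(combiner_score(comb, s1, s2) >= 0.5)
  expect_identical(pred, as.integer(y))
})

test_that("the hidden layer realizes AND of the two inputs", {
  corners <- expand.grid(s1 = c(0.05, 0.95), s2 = c(0.05, 0.95))
  y <- as.integer(round(corners$s1) & round(corners$s2))
  # replicate the four patterns so full-batch gradients are well scaled
  idx <- rep(1:4, each = 8)
  comb <- fit_combiner(corners$s1[idx], corners$s2[idx], y[idx],
                       seed = 4, hidden = 2L)
  pred <- as.integer(combiner_score(comb, corners$s1, corners$s2) >= 0.5)
  expect_identical(pred, y)
})

test_that("output is a bounded sigmoid for any finite inputs", {
  comb <- fit_combiner(c(0.1, 0.9, 0.2, 0.8), c(0.2, 0.8, 0.9, 0.1),
                       c(0, 1, 0, 1), seed = 5)
  extremes <- expand.grid(a = c(-1e6, 0, 0.5, 1, 1e6),
                          b = c(-1e6, 0, 0.5, 1, 1e6))
  s <- combiner_score(comb, extremes$a, extremes$b)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("training is reproducible per seed and rejects degenerate input", {
  s1 <- runif(20); s2 <- runif(20); y <- rep(c(0, 1), 10)
  a <- fit_combiner(s1, s2, y, seed = 9)
  b <- fit_combiner(s1, s2, y, seed = 9)
  expect_identical(a$W1, b$W1)
  expect_identical(a$loss_trace, b$loss_trace)
  expect_error(fit_combiner(s1, s2, rep(1, 20), seed = 1), "both classes")
  expect_error(fit_combiner(s1[1:5], s2, y, seed = 1), "equal length")
  expect_error(fit_combiner(c(s1[-1], NA), s2, y, seed = 1), "non-finite")
  expect_error(fit_combiner(s1, s2, y, seed = 1, hidden = 0L), "hidden")
})

test_that("stacking two error-prone base models loses nothing on held-out data", {
  # base models err independently at rate 0.2 on n = 200 held-out samples
  withr::with_seed(31, {
    n <- 200L
    y_fit <- rep(c(0L, 1L), n / 2)
    flip <- function(y) ifelse(runif(length(y)) < 0.2, 1L - y, y)
    noisy_score <- function(y) pmin(pmax(
      ifelse(flip(y) == 1L, 0.8, 0.2) + rnorm(length(y), sd = 0.05),
      0.01), 0.99)
    s1_fit <- noisy_score(y_fit); s2_fit <- noisy_score(y_fit)
    comb <- fit_combiner(s1_fit, s2_fit, y_fit, seed = 8)
    y_new <- rep(c(0L, 1L), n / 2)
    s1_new <- noisy_score(y_new); s2_new <- noisy_score(y_new)
    acc1 <- mean(as.integer(s1_new >= 0.5) == y_new)
    acc2 <- mean(as.integer(s2_new >= 0.5) == y_new)
    acc_stack <- mean(as.integer(combiner_score(comb, s1_new, s2_new) >= 0.5)
                      == y_new)
    expect_gte(acc_stack, max(acc1, acc2) - 0.02)
  })
})

test_that("pass-through combiner wiring makes the stack follow the improved model", {
  ds <- generate_dataset(8, tiny_synth(), seed = 17)
  bb <- build_backbone(backbone_spec("tiny"), seed = 17)
  feats <- granulenet:::extract_both(bb, ds)
  y <- sample_labels(ds)
  improved <- fit_svm(feats$flat, y, C = 1)
  conventional <- train_conventional(ds, cfg = train_config(
    learning_rate = 0.05, seed = 17), extractor = bb, features = feats$pooled)
  # hand-wired combiner: a steep sigmoid on (s1 - 0.5), ignoring s2
  comb <- structure(list(W1 = matrix(c(200, 0), 2, 1), b1 = -100,
                         W2 = matrix(200, 1, 1), b2 = -100,
                         hidden = 1L, trained = TRUE),
                    class = "gn_combiner")
  stack <- stacked_model(improved, conventional, comb, bb)
  for (i in c(1L, 5L)) {
    out <- combine_predict(stack, ds[[i]])
    expect_identical(out$label, as.integer(out$score_improved >= 0.5))
    expect_true(out$score >= 0 && out$score <= 1)
    again <- combine_predict(stack, ds[[i]])
    expect_identical(out$score, again$score)
  }
})
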