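toy2 <- function() {
  x <- rbind(c(0, 0), c(1, 1))
  colnames(x) <- c("f1", "f2")
  x
}

test_that("the symmetric two-point problem has a midpoint boundary", {
  fit <- train_svm(toy2(), c("normal", "abnormal"), gamma = 0.5, cost = 10)
  expect_equal(fit$fit$tot.nSV, 2L)     # both points are support vectors
  mid <- c(f1 = 0.5, f2 = 0.5)
  expect_equal(predict(fit, mid)$decision_value, 0, tolerance = 1e-6)
  # each training point classifies as itself
  pr <- predict(fit, toy2())
  expect_equal(pr$label, c("normal", "abnormal"))
})

test_that("a linearly separable toy set is fit to 100% training accuracy", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60, 0, 0.3), 30),
             matrix(rnorm(60, 4, 0.3), 30))
  colnames(x) <- c("a", "b")
  y <- rep(c("normal", "abnormal"), each = 30)
  fit <- train_svm(x, y, cost = 10)
  expect_equal(predict(fit, x)$label, y)
})

test_that("decision values negate when training labels are swapped", {
  set.seed(8)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("n", "ab"), 20)
  flip <- ifelse(y == "n", "ab", "n")
  f1 <- train_svm(x, y, gamma = 0.7, cost = 2)
  f2 <- train_svm(x, flip, gamma = 0.7, cost = 2)
  d1 <- predict(f1, x)$decision_value
  d2 <- predict(f2, x)$decision_value
  # e1071 orders decision values by factor levels, identical for both
  # fits here, so the flipped problem's decision function is the negative
  expect_equal(d1, -d2, tolerance = 1e-6)
})

test_that("the Gaussian kernel matrix is positive semidefinite", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(15 * 4), 15, 4)
    d2 <- as.matrix(stats::dist(x))^2
    K <- exp(-0.8 * d2)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("prediction is invariant to feature column order", {
  set.seed(13)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("normal", "abnormal"), 10)
  fit <- train_svm(x, y)
  shuffled <- x[, c("c", "a", "b")]
  expect_equal(predict(fit, x), predict(fit, shuffled))
})

test_that("gamma -> 0 collapses the decision to the majority class", {
  set.seed(3)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("maj", "min"), c(15, 5))
  fit <- train_svm(x, y, gamma = 1e-9, cost = 1)
  probe <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_true(all(predict(fit, probe)$label == "maj"))
})

test_that("degenerate training inputs error clearly", {
  x <- toy2()
  expect_error(train_svm(x, c("a", "a")), "two classes")
  xx <- x; xx[1, 1] <- NA
  expect_error(train_svm(xx, c("a", "b")), "finite")
  fit <- train_svm(x, c("a", "b"))
  bad <- matrix(1, 1, 2, dimnames = list(NULL, c("f1", "zz")))
  expect_error(predict(fit, bad), "schema")
})

test_that("phantom texture features are separable: 5-fold CV >= 90%", {
  ds <- make_dataset(20, 40, phantom_spec(), seed = 2024)
  labels <- vapply(ds, `[[`, "", "label")
  feats <- lapply(ds, function(p) slice_features(p$image))
  x <- do.call(rbind, feats)
  set.seed(77)
  folds <- sample(rep(1:5, length.out = length(ds)))
  correct <- 0L
  for (k in 1:5) {
    fit <- train_svm(x[folds != k, ], labels[folds != k])
    pr <- predict(fit, x[folds == k, , drop = FALSE])
    correct <- correct + sum(pr$label == labels[folds == k])
  }
  expect_gte(correct / length(ds), 0.9)
})

test_that("end-to-end evaluation: perfect and permuted baselines", {
  ds <- make_dataset(8, 16, phantom_spec(), seed = 11)
  res <- evaluate_pipeline(ds, seed = 3)
  # all-correct predictions give accuracy 100 with no false calls
  if (res$confusion$fp == 0L && res$confusion$fn == 0L) {
    expect_equal(res$metrics[["accuracy"]], 100)
  }
  expect_equal(res$confusion$tp + res$confusion$tn +
                 res$confusion$fp + res$confusion$fn, length(res$test_idx))

  # label permutation collapses accuracy towards chance
  labels <- vapply(ds, `[[`, "", "label")
  feats <- do.call(rbind, lapply(ds, function(p) slice_features(p$image)))
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    sh <- sample(labels)
    tr <- c(1:6, 9:20)           # fixed split, both classes present
    te <- setdiff(seq_along(labels), tr)
    fit <- train_svm(feats[tr, ], sh[tr])
    mean(predict(fit, feats[te, , drop = FALSE])$label == sh[te])
  }, numeric(1))
  expect_lt(mean(accs), 0.8)
  expect_gt(mean(accs), 0.2)
})

test_that("evaluate_pipeline rejects one-class cohorts", {
  ds <- make_dataset(4, 0, phantom_spec(), seed = 1)
  expect_error(evaluate_pipeline(ds), "both")
})
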