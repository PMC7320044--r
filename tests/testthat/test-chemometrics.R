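test_that("Kennard-Stone selects extremes first and splits 70/30", {
  # 1-D points 0..9: seed pair is {0, 9}; third pick is the maximin midpoint 4
  X <- matrix(0:9, ncol = 1)
  sp <- kennard_stone_split(X, 0.70)
  expect_length(sp$train_rows, 7L)
  expect_length(sp$validation_rows, 3L)
  expect_equal(sp$train_rows[1:2], c(1L, 10L))
  expect_equal(sp$train_rows[3], 5L) # value 4 beats value 5 by lowest index
  expect_setequal(c(sp$train_rows, sp$validation_rows), 1:10)
  # deterministic
  expect_identical(sp, kennard_stone_split(X, 0.70))
})

test_that("Kennard-Stone matches the brute-force maximin oracle (property)", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    n_train <- floor(0.7 * n)
    got <- kennard_stone_split(X, 0.70)$train_rows
    expect_equal(got, oracle_kennard_stone(X, n_train), info = paste("seed", seed))
  }
})

test_that("Kennard-Stone defers duplicates until distinct values are used", {
  X <- matrix(rep(0:5, each = 2), ncol = 1) # each value twice
  sp <- kennard_stone_split(X, 0.70) # 8 training rows
  first6 <- sp$train_rows[1:6]
  expect_setequal(X[first6, 1], 0:5)
})

test_that("Kennard-Stone validates its inputs", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(kennard_stone_split(X, 0), "between 0 and 1")
  expect_error(kennard_stone_split(X, 1.2), "between 0 and 1")
  expect_error(kennard_stone_split(X[1:2, ], 0.7), "at least 3")
  expect_error(kennard_stone_split(X, 0.2), "fewer than 2")
})

test_that("venetian blinds interleave rows mod n_splits", {
  f <- venetian_blinds_folds(20, 10)
  for (k in 1:10) expect_equal(which(f == k), c(k, k + 10L))
  expect_equal(venetian_blinds_folds(10, 10), 1:10) # leave-one-out pattern
  expect_error(venetian_blinds_folds(9, 10), "fewer splits")
})

test_that("PCA handles rank-1 input and honours its invariants", {
  set.seed(4)
  v <- rnorm(30)
  X <- outer(c(1, 2, 3, 4), v) + 5 # rank-1 plus constant mean
  p <- pca_fit(X, 2)
  expect_equal(p$explained_variance_pct[1], 100, tolerance = 1e-8)
  expect_equal(p$explained_variance_pct[2], 0, tolerance = 1e-8)
  # orthonormal loadings, centred scores
  p2 <- pca_fit(random_spectra(20, 40, seed = 7), 5)
  expect_equal(crossprod(p2$loadings), diag(5), tolerance = 1e-8)
  expect_lt(max(abs(colSums(p2$scores))), 1e-8)
  expect_true(all(diff(p2$explained_variance_all) <= 1e-10))
  expect_lte(sum(p2$explained_variance_all), 100 + 1e-8)
  # sign convention: largest-magnitude loading element positive
  for (k in 1:5) expect_gt(p2$loadings[which.max(abs(p2$loadings[, k])), k], 0)
  expect_error(pca_fit(matrix(1, 4, 3), 2), "zero-variance")
  expect_error(pca_fit(random_spectra(5, 3), 5), "K must satisfy")
})

test_that("PCA agrees with a covariance eigendecomposition oracle", {
  X <- random_spectra(30, 50, seed = 12)
  K <- 6
  p <- pca_fit(X, K)
  Xc <- sweep(X, 2, colMeans(X))
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  ev_oracle <- 100 * eg$values / sum(eg$values)
  expect_equal(p$explained_variance_pct, ev_oracle[1:K], tolerance = 1e-6)
  for (k in 1:K) {
    w <- eg$vectors[, k]
    w <- w * sign(w[which.max(abs(w))])
    expect_equal(p$loadings[, k], w, tolerance = 1e-6)
    expect_equal(p$scores[, k], as.numeric(Xc %*% w), tolerance = 1e-6)
  }
})

test_that("pca_transform reproduces training scores and projects new data", {
  X <- random_spectra(15, 25, seed = 2)
  p <- pca_fit(X, 4)
  expect_equal(pca_transform(p, X), p$scores, tolerance = 1e-12)
  expect_equal(dim(pca_transform(p, X[1:3, ], K = 2)), c(3L, 2L))
  expect_error(pca_transform(p, X, K = 9), "exceeds")
})

test_that("LDA Mahalanobis assignment matches the hand-inverted 2x2 oracle", {
  # classes A, B with identical within-class deviations around their means;
  # pooled covariance is correlated, so Euclidean and Mahalanobis disagree
  dev <- rbind(c(-1, -0.9), c(1, 0.9), c(0.3, -0.3), c(-0.3, 0.3))
  scores <- rbind(dev, sweep(dev, 2, c(-2, 0)))
  labels <- rep(c("A", "B"), each = 4)
  fit <- lda_fit(scores, labels, ridge = 0)
  # hand-computed pooled covariance: 2 * crossprod(dev) / (8 - 2)
  S <- 2 * crossprod(dev) / 6
  expect_equal(fit$pooled_cov, S, tolerance = 1e-12)
  p <- c(1.2, 1.3)
  invS <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) /
    (S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1])
  d2 <- function(v) drop(t(v) %*% invS %*% v)
  dA <- d2(p - c(0, 0)); dB <- d2(p - c(2, 0))
  got <- lda_classify(fit, rbind(p))
  expect_equal(got$df, dB - dA, tolerance = 1e-9)
  expect_equal(got$class, "A") # Mahalanobis prefers A...
  expect_lt(sum((p - c(2, 0))^2), sum(p^2)) # ...though Euclid would say B
})

test_that("LDA degenerate geometry: class means and midpoints", {
  set.seed(6)
  sc <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 5), 5, 2))
  labs <- rep(c("a", "b"), each = 5)
  fit <- lda_fit(sc, labs)
  at_mean <- lda_classify(fit, rbind(fit$class_means["a", ]))
  expect_equal(at_mean$class, "a")
  expect_gt(at_mean$df, 0)
  mid <- (fit$class_means["a", ] + fit$class_means["b", ]) / 2
  tie <- lda_classify(fit, rbind(mid))
  expect_equal(tie$df, 0, tolerance = 1e-9)
  expect_equal(tie$class, "a") # tie-break to the smaller label
  expect_error(lda_fit(sc, rep("a", 10)), "two classes")
  expect_error(lda_fit(sc, c("a", rep("b", 9))), ">= 2 training samples")
})

test_that("PC-count selection finds separation on PC1 and reports all K", {
  set.seed(31)
  n <- 40
  cls <- rep(c("A", "B"), n / 2) # alternating so folds stay stratified
  X <- cbind(ifelse(cls == "A", 0, 10) + rnorm(n, 0, 0.3),
             matrix(rnorm(n * 9), n, 9))
  sel <- select_n_pcs(X, cls, candidates = 1:5, n_splits = 10)
  expect_equal(sel$best_K, 1L)
  expect_length(sel$cv_accuracy, 5L)
  expect_equal(unname(sel$cv_accuracy["1"]), 100)
  expect_true(all(is.finite(sel$cum_explained_variance)))
  expect_true(all(diff(sel$cum_explained_variance) >= -1e-9))
})

test_that("PC-count selection on a no-signal null stays near chance", {
  set.seed(77)
  X <- matrix(rnorm(60 * 12), 60, 12)
  cls <- rep(c("A", "B"), 30)
  sel <- select_n_pcs(X, cls, candidates = 1:4, n_splits = 10)
  expect_true(all(sel$cv_accuracy > 20 & sel$cv_accuracy < 80))
})

test_that("figures of merit implement the confusion-count formulas", {
  perfect <- figures_of_merit(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(perfect$accuracy_pct, 100)
  expect_equal(perfect$sensitivity_pct, 100)
  expect_equal(perfect$specificity_pct, 100)
  fom <- figures_of_merit(list(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(round(fom$accuracy_pct, 2), 80.00)
  expect_equal(round(fom$sensitivity_pct, 2), 75.00)
  expect_equal(round(fom$specificity_pct, 2), 83.33)
  # empty-positive edge: sensitivity undefined, not zero
  edge <- figures_of_merit(list(TP = 0, FN = 0, TN = 5, FP = 0))
  expect_equal(edge$accuracy_pct, 100)
  expect_true(is.na(edge$sensitivity_pct))
  expect_equal(edge$undefined, "sensitivity")
  expect_error(figures_of_merit(list(TP = -1, TN = 1, FP = 0, FN = 0)),
               "non-negative")
})

test_that("figures of merit: enumerated tables and label-swap symmetry", {
  for (tp in 0:3) for (tn in 0:3) for (fp in 0:2) for (fn in 0:2) {
    tot <- tp + tn + fp + fn
    if (tot == 0) next
    fom <- figures_of_merit(list(TP = tp, TN = tn, FP = fp, FN = fn))
    expect_equal(fom$accuracy_pct, 100 * (tp + tn) / tot)
    if (tp + fn > 0) expect_equal(fom$sensitivity_pct, 100 * tp / (tp + fn))
    if (tn + fp > 0) expect_equal(fom$specificity_pct, 100 * tn / (tn + fp))
    # swapping the positive class swaps sensitivity and specificity
    sw <- figures_of_merit(list(TP = tn, TN = tp, FP = fn, FN = fp))
    expect_equal(sw$accuracy_pct, fom$accuracy_pct)
    if (tp + fn > 0) expect_equal(sw$specificity_pct, fom$sensitivity_pct)
  }
})

test_that("confusion counts tally predictions against truth", {
  truth <- c("OAC", "OAC", "BO", "BO", "BO")
  pred <- c("OAC", "BO", "BO", "OAC", "BO")
  cc <- confusion_counts(truth, pred, positive = "OAC")
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 1L, TN = 2L, FP = 1L, FN = 1L))
  expect_error(confusion_counts(truth, pred, positive = "XX"), "absent")
})

test_that("pcalda couples the PCA and LDA stages coherently", {
  sc <- tiny_preset(seed = 3)
  sm <- unfold(generate_map(sc))
  fit <- pcalda(sm, k = 2)
  expect_s3_class(fit, "pcalda")
  expect_equal(fit$k, 2L)
  pred <- predict(fit, sm)
  expect_equal(pred$class, fit$fitted$class)
  expect_gt(mean(pred$class == sm$labels), 0.95)
  # loadings surface through coef()
  expect_equal(dim(coef(fit)), c(length(sc$axis), 2L))
})
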