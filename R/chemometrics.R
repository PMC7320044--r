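#' Kennard-Stone training/validation split
#'
#' Deterministic maximin sample selection: the pair at maximal Euclidean
#' distance seeds the training set; each further training sample is the one
#' maximising its minimum distance to the samples already selected. Ties are
#' broken by the lowest row index. `floor(fraction * n)` rows go to training;
#' the rest form the validation set.
#'
#' @param X Spectra (`n x m` matrix or [spectra_matrix()]), pre-processed.
#' @param fraction Target training fraction in (0, 1); default 0.70.
#' @return A `ks_split` object: `train_rows` (in selection order),
#'   `validation_rows` (ascending), `fraction`.
#' @export
kennard_stone_split <- function(X, fraction = 0.70) {
  X <- as_spectra_X(X)
  n <- nrow(X)
  if (n < 3L) stop("Kennard-Stone needs at least 3 samples")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1")
  }
  n_train <- floor(fraction * n)
  if (n_train < 2L) stop("training fraction selects fewer than 2 samples")
  D <- unname(as.matrix(stats::dist(X)))
  # seed pair: maximal distance; ties -> smallest (i, j), i < j
  mx <- max(D)
  cand <- which(D == mx, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- as.integer(cand[1, ])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- as.integer(which.max(mind)) # first index wins ties -> lowest row
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  structure(list(train_rows = sel,
                 validation_rows = setdiff(seq_len(n), sel),
                 fraction = fraction),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("Kennard-Stone split: %d training / %d validation (fraction %.2f)\n",
              length(x$train_rows), length(x$validation_rows), x$fraction))
  invisible(x)
}

#' Venetian-blinds cross-validation folds
#'
#' Interleaved fold assignment used for model optimisation: row `i` (1-based,
#' in the given row order) goes to fold `((i - 1) mod n_splits) + 1`.
#'
#' @param n Number of rows.
#' @param n_splits Number of folds (default 10).
#' @return Integer vector of fold ids of length `n`.
#' @export
venetian_blinds_folds <- function(n, n_splits = 10) {
  n <- as.integer(n); n_splits <- as.integer(n_splits)
  if (n_splits < 2L) stop("`n_splits` must be >= 2")
  if (n < n_splits) {
    stop("n (", n, ") is smaller than the number of splits (", n_splits,
         "); use fewer splits")
  }
  rep_len(seq_len(n_splits), n)
}

#' Principal component analysis of spectra
#'
#' Fits PCA on training spectra only: the training mean is subtracted and the
#' centred matrix decomposed by singular value decomposition. The per-PC
#' explained variance is `100 * sigma_k^2 / sum(sigma^2)` over all singular
#' values. Loadings follow the sign convention that each loading's
#' largest-magnitude element is positive.
#'
#' @param X Training spectra (`n x m` matrix or [spectra_matrix()]).
#' @param K Number of components to keep, `<= min(n - 1, m)`.
#' @return A `raman_pca` object: `mean`, `loadings` (`m x K`, orthonormal),
#'   `scores` (training, `n x K`), `explained_variance_pct` (length K),
#'   `explained_variance_all`, `K`.
#' @export
pca_fit <- function(X, K) {
  X <- as_spectra_X(X)
  n <- nrow(X); m <- ncol(X)
  K <- as.integer(K)
  if (K < 1L || K > min(n - 1L, m)) {
    stop("K must satisfy 1 <= K <= min(n - 1, m) = ", min(n - 1L, m))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total <- sum(Xc^2)
  if (total <= .Machine$double.eps * n * m) {
    stop("zero-variance input: explained variance is undefined")
  }
  sv <- svd(Xc, nu = 0, nv = K)
  V <- sv$v
  # sign convention: largest-|element| of each loading positive
  for (k in seq_len(K)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  ev_all <- 100 * sv$d^2 / sum(sv$d^2)
  structure(list(mean = mu, loadings = V, scores = Xc %*% V,
                 explained_variance_pct = ev_all[seq_len(K)],
                 explained_variance_all = ev_all, K = K),
            class = "raman_pca")
}

#' Project spectra onto a fitted PCA model
#'
#' Applies the training mean and loadings to new spectra (validation rows use
#' training parameters only).
#'
#' @param model A `raman_pca` from [pca_fit()].
#' @param X Spectra to project.
#' @param K Number of components (default: all fitted).
#' @return `n x K` score matrix.
#' @export
pca_transform <- function(model, X, K = model$K) {
  stopifnot(inherits(model, "raman_pca"))
  X <- as_spectra_X(X)
  if (ncol(X) != length(model$mean)) stop("wavenumber count mismatch")
  if (K > model$K) stop("K exceeds the number of fitted components")
  sweep(X, 2, model$mean) %*% model$loadings[, seq_len(K), drop = FALSE]
}

#' @export
predict.raman_pca <- function(object, newdata, K = object$K, ...) {
  pca_transform(object, newdata, K = K)
}

#' @export
print.raman_pca <- function(x, ...) {
  cat(sprintf("PCA model: %d components, %.2f%% cumulative explained variance\n",
              x$K, sum(x$explained_variance_pct)))
  invisible(x)
}

#' Two-class linear discriminant analysis in PC-score space
#'
#' Fits class means and the pooled within-class covariance of the training
#' scores (`S_pooled = sum_c sum_{i in c} (s_i - mu_c)(s_i - mu_c)' / (n - 2)`
#' plus a small ridge), assuming equal priors. Classification is by smaller
#' Mahalanobis squared distance; the discriminant function (DF) reported per
#' sample is `D^2(s, class2) - D^2(s, class1)` with classes in lexicographic
#' order, so `df > 0` means assignment to the first class. Equidistant
#' samples go to the lexicographically smaller label.
#'
#' @param scores Training score matrix (`n x K`).
#' @param labels Length-n class labels (exactly two classes, each with >= 2
#'   samples).
#' @param ridge Diagonal regulariser added to the pooled covariance.
#' @return A `raman_lda` object: `classes`, `class_means`, `pooled_cov`,
#'   `ridge`.
#' @export
lda_fit <- function(scores, labels, ridge = 1e-8) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (nrow(scores) != length(labels)) stop("scores/labels length mismatch")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("exactly two classes required, got ", length(classes))
  }
  sizes <- table(factor(labels, levels = classes))
  if (any(sizes < 2L)) {
    stop("each class needs >= 2 training samples (",
         paste(sprintf("%s: %d", classes, sizes), collapse = ", "), ")")
  }
  K <- ncol(scores)
  mu <- rbind(colMeans(scores[labels == classes[1], , drop = FALSE]),
              colMeans(scores[labels == classes[2], , drop = FALSE]))
  rownames(mu) <- classes
  S <- matrix(0, K, K)
  for (c in classes) {
    Zc <- sweep(scores[labels == c, , drop = FALSE], 2, mu[c, ])
    S <- S + crossprod(Zc)
  }
  S <- S / (nrow(scores) - 2) + diag(ridge, K)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    stop("pooled covariance is singular even after ridge regularisation")
  }
  structure(list(classes = classes, class_means = mu, pooled_cov = S,
                 ridge = ridge, chol = ch),
            class = "raman_lda")
}

#' Classify scores with a fitted LDA model
#'
#' @param model A `raman_lda` from [lda_fit()].
#' @param scores Score matrix to classify (`n x K`).
#' @return Data frame with `class` (assigned label) and `df` (discriminant
#'   function value; positive means the first, lexicographically smaller,
#'   class).
#' @export
lda_classify <- function(model, scores) {
  stopifnot(inherits(model, "raman_lda"))
  scores <- as.matrix(scores)
  if (ncol(scores) != ncol(model$class_means)) {
    stop("score dimensionality does not match the fitted model")
  }
  d1 <- stats::mahalanobis(scores, model$class_means[1, ], model$pooled_cov)
  d2 <- stats::mahalanobis(scores, model$class_means[2, ], model$pooled_cov)
  df <- d2 - d1
  cls <- ifelse(df >= 0, model$classes[1], model$classes[2])
  data.frame(class = cls, df = df, stringsAsFactors = FALSE)
}

#' @export
predict.raman_lda <- function(object, newdata, ...) {
  lda_classify(object, newdata)
}

#' Select the number of principal components by venetian-blinds CV
#'
#' For each candidate K, a PCA-LDA model is refit on each fold-complement of
#' the training rows and evaluated on the held-out fold; accuracy is pooled
#' over folds. The selected K is the smallest candidate within 0.5 percentage
#' points of the maximum cross-validated accuracy (parsimony rule).
#'
#' @param X_train Training spectra (rows in the order to be interleaved,
#'   normally Kennard-Stone selection order).
#' @param labels Per-row class labels.
#' @param candidates Candidate component counts (default 1..15, clipped to
#'   what the fold sizes allow).
#' @param n_splits Number of venetian-blinds folds (default 10).
#' @param ridge LDA covariance ridge.
#' @return List with `best_K`, `cv_accuracy` (named per candidate, %),
#'   `cum_explained_variance` (cumulative training explained variance per
#'   candidate, %), and `folds`.
#' @export
select_n_pcs <- function(X_train, labels, candidates = 1:15, n_splits = 10,
                         ridge = 1e-8) {
  X <- as_spectra_X(X_train)
  labels <- as.character(labels)
  n <- nrow(X)
  folds <- venetian_blinds_folds(n, n_splits)
  kmax_global <- min(max(candidates), ncol(X), n - max(table(folds)) - 1L)
  candidates <- sort(unique(as.integer(candidates)))
  candidates <- candidates[candidates >= 1L & candidates <= kmax_global]
  if (length(candidates) == 0L) stop("no feasible candidate K")
  kmax <- max(candidates)
  correct <- stats::setNames(rep(0, length(candidates)),
                             as.character(candidates))
  for (f in seq_len(n_splits)) {
    tr <- folds != f
    pca <- pca_fit(X[tr, , drop = FALSE], kmax)
    s_tr <- pca$scores
    s_te <- pca_transform(pca, X[!tr, , drop = FALSE])
    for (ki in seq_along(candidates)) {
      K <- candidates[ki]
      lda <- lda_fit(s_tr[, seq_len(K), drop = FALSE], labels[tr], ridge)
      pred <- lda_classify(lda, s_te[, seq_len(K), drop = FALSE])
      correct[ki] <- correct[ki] + sum(pred$class == labels[!tr])
    }
  }
  cv_acc <- 100 * correct / n
  best_K <- candidates[which(cv_acc >= max(cv_acc) - 0.5)[1]]
  pca_full <- pca_fit(X, kmax)
  cum_ev <- cumsum(pca_full$explained_variance_all)[candidates]
  list(best_K = best_K,
       cv_accuracy = cv_acc,
       cum_explained_variance = stats::setNames(cum_ev, as.character(candidates)),
       folds = folds)
}

#' Confusion counts from truth and prediction
#'
#' @param truth,predicted Class label vectors of equal length.
#' @param positive Label counted as the positive class (e.g. `"OAC"`).
#' @return A `confusion_counts` object with fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (!positive %in% c(truth, predicted)) {
    stop("positive class '", positive, "' absent from labels")
  }
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, positive = positive),
            class = "confusion_counts")
}

#' Classification figures of merit
#'
#' Accuracy, sensitivity and specificity as percentages:
#' `accuracy = (TP + TN) / (TP + FP + TN + FN) * 100`,
#' `sensitivity = TP / (TP + FN) * 100`,
#' `specificity = TN / (TN + FP) * 100`.
#' A metric whose denominator is zero is flagged as undefined (`NA`), never
#' silently zeroed.
#'
#' @param counts A [confusion_counts()] (or list with `TP`, `TN`, `FP`, `FN`).
#' @param digits Decimal places used when printing (default 2); stored values
#'   are unrounded.
#' @return A `raman_fom` object with `accuracy_pct`, `sensitivity_pct`,
#'   `specificity_pct`, `undefined` (character vector of flagged metrics) and
#'   the input `counts`.
#' @export
figures_of_merit <- function(counts, digits = 2) {
  k <- counts[c("TP", "TN", "FP", "FN")]
  if (any(vapply(k, function(z) is.null(z) || z < 0 || z != round(z),
                 logical(1)))) {
    stop("counts must be non-negative integers TP, TN, FP, FN")
  }
  tp <- k$TP; tn <- k$TN; fp <- k$FP; fn <- k$FN
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated spectra (all counts zero)")
  undefined <- character(0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  structure(list(accuracy_pct = 100 * (tp + tn) / total,
                 sensitivity_pct = sens, specificity_pct = spec,
                 undefined = undefined, counts = counts, digits = digits),
            class = "raman_fom")
}

#' @export
print.raman_fom <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else
    sprintf(paste0("%.", x$digits, "f%%"), v)
  cat(sprintf("accuracy %s, sensitivity %s, specificity %s\n",
              fmt(x$accuracy_pct), fmt(x$sensitivity_pct),
              fmt(x$specificity_pct)))
  invisible(x)
}
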