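#' Fit a PCA-LDA classifier on spectra
#'
#' The central model of the package: principal component analysis reduces the
#' pre-processed spectra to `k` scores, and a two-class linear discriminant
#' with Mahalanobis distances and equal priors is fitted in that score space.
#' Validation spectra are projected with the training mean and loadings only.
#'
#' @param X Training spectra (`n x m` matrix or [spectra_matrix()]; if a
#'   labelled `spectra_matrix`, `labels` may be omitted).
#' @param labels Per-row class labels (exactly two classes).
#' @param k Number of principal components retained for the discriminant.
#' @param ridge Diagonal regulariser for the pooled covariance.
#' @return A `pcalda` object with components `pca` (`raman_pca`), `lda`
#'   (`raman_lda`), `k`, `labels`, `fitted` (training predictions).
#' @examples
#' sc <- case_presets("case3", map_rows = 8, map_cols = 8)
#' sm <- unfold(generate_map(sc))
#' fit <- pcalda(sm$X, sm$labels, k = 2)
#' fit
#' @export
pcalda <- function(X, labels = NULL, k = 2, ridge = 1e-8) {
  if (inherits(X, "spectra_matrix") && is.null(labels)) labels <- X$labels
  if (is.null(labels)) stop("`labels` required")
  Xm <- as_spectra_X(X)
  pca <- pca_fit(Xm, k)
  lda <- lda_fit(pca$scores, labels, ridge = ridge)
  fitted <- lda_classify(lda, pca$scores)
  structure(list(pca = pca, lda = lda, k = pca$K,
                 labels = as.character(labels), fitted = fitted,
                 call = match.call()),
            class = "pcalda")
}

#' Predict tissue classes for new spectra
#'
#' @param object A fitted [pcalda()] model.
#' @param newdata Spectra to classify (`n x m` matrix or [spectra_matrix()]).
#' @param ... Unused.
#' @return Data frame with `class` and discriminant-function value `df`
#'   (positive = first class in lexicographic order).
#' @export
predict.pcalda <- function(object, newdata, ...) {
  scores <- pca_transform(object$pca, as_spectra_X(newdata))
  lda_classify(object$lda, scores)
}

#' @export
print.pcalda <- function(x, ...) {
  cat(sprintf("PCA-LDA model: %d PCs (%.2f%% cumulative explained variance)\n",
              x$k, sum(x$pca$explained_variance_pct)))
  cat("classes:", paste(x$lda$classes, collapse = " vs "), "\n")
  acc <- 100 * mean(x$fitted$class == x$labels)
  cat(sprintf("training accuracy: %.2f%%\n", acc))
  invisible(x)
}

#' @export
summary.pcalda <- function(object, ...) {
  counts <- confusion_counts(object$labels, object$fitted$class,
                             positive = object$lda$classes[2])
  structure(list(k = object$k,
                 explained_variance_pct = object$pca$explained_variance_pct,
                 classes = object$lda$classes,
                 class_sizes = table(object$labels),
                 training_counts = counts,
                 training_fom = figures_of_merit(counts)),
            class = "summary.pcalda")
}

#' @export
print.summary.pcalda <- function(x, ...) {
  cat(sprintf("PCA-LDA with %d PCs\n", x$k))
  cat("explained variance (%):",
      paste(sprintf("%.2f", x$explained_variance_pct), collapse = ", "),
      sprintf(" (cumulative %.2f)\n", sum(x$explained_variance_pct)))
  cat("class sizes:", paste(sprintf("%s: %d", names(x$class_sizes),
                                    x$class_sizes), collapse = ", "), "\n")
  cat("training ")
  print(x$training_fom)
  invisible(x)
}

#' Coefficients of a PCA-LDA model
#'
#' Returns the spectral loadings of the retained principal components — the
#' wavenumber-space directions the discriminant operates on.
#' @param object A [pcalda()] model.
#' @param ... Unused.
#' @export
coef.pcalda <- function(object, ...) object$pca$loadings

#' Discriminant-function plot
#'
#' Scatter of the per-spectrum discriminant function values by sample index,
#' coloured by true class, with the decision boundary at zero — the standard
#' DF plot used to visualise two-class separation.
#'
#' @param x A [pcalda()] model.
#' @param newdata Optional spectra (with a labelled [spectra_matrix()]) to
#'   plot instead of the training set.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pcalda <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) {
    df <- x$fitted$df; labs <- x$labels
  } else {
    pred <- predict(x, newdata)
    df <- pred$df
    labs <- if (inherits(newdata, "spectra_matrix")) newdata$labels else
      rep(NA_character_, length(df))
  }
  cols <- ifelse(labs == x$lda$classes[1], "#1b63a5", "#c23b22")
  graphics::plot(seq_along(df), df, col = cols, pch = 19,
                 xlab = "spectrum index", ylab = "discriminant function", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::legend("topright", legend = x$lda$classes,
                   col = c("#1b63a5", "#c23b22"), pch = 19, bty = "n")
  invisible(x)
}
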