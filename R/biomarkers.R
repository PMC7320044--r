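# Interpretive outputs: class mean spectra, difference-between-mean (DBM)
# spectra, marker-band tables cross-annotated with PCA loadings, and raw vs
# PCA-recovered map images.

#' Per-class mean spectra
#'
#' @param mat A labelled [spectra_matrix()].
#' @return Matrix with one row per class (rownames = class labels, sorted).
#' @export
class_mean_spectra <- function(mat) {
  stopifnot(inherits(mat, "spectra_matrix"))
  if (is.null(mat$labels)) stop("spectra matrix carries no class labels")
  classes <- sort(unique(mat$labels))
  out <- t(vapply(classes, function(cl) {
    rows <- mat$labels == cl
    if (!any(rows)) stop("empty class ", cl)
    colMeans(mat$X[rows, , drop = FALSE])
  }, numeric(ncol(mat$X))))
  rownames(out) <- classes
  out
}

#' Difference-between-mean (DBM) spectrum
#'
#' The mean spectrum of the first class minus the mean spectrum of the
#' second, computed on pre-processed intensities; its extrema locate the
#' bands that discriminate the two tissue types. Swapping `class_order`
#' negates the result.
#'
#' @param mat A labelled, pre-processed [spectra_matrix()].
#' @param class_order Character vector of the two class labels, `(class1,
#'   class2)`; default: sorted labels.
#' @return A `dbm_result` object: `dbm` (length-m vector), `class_order`,
#'   `axis`.
#' @export
dbm_spectrum <- function(mat, class_order = NULL) {
  means <- class_mean_spectra(mat)
  if (is.null(class_order)) class_order <- rownames(means)
  if (length(class_order) != 2L || !all(class_order %in% rownames(means))) {
    stop("`class_order` must name the two classes present")
  }
  structure(list(dbm = means[class_order[1], ] - means[class_order[2], ],
                 class_order = class_order, axis = mat$axis),
            class = "dbm_result")
}

#' @export
print.dbm_result <- function(x, ...) {
  cat(sprintf("DBM spectrum: %s - %s, %d wavenumbers, max |DBM| = %.4g\n",
              x$class_order[1], x$class_order[2], length(x$dbm),
              max(abs(x$dbm))))
  invisible(x)
}

# indices of strict interior local maxima of y
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}

# topographic prominence of each peak index: height above the higher of the
# two key saddles (minima between the peak and the nearest higher ground, or
# the record boundaries)
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(i) {
    lo <- i; left_min <- y[i]
    while (lo > 1L && y[lo] <= y[i]) {
      lo <- lo - 1L
      left_min <- min(left_min, y[lo])
      if (y[lo] > y[i]) break
    }
    hi <- i; right_min <- y[i]
    n <- length(y)
    while (hi < n && y[hi] <= y[i]) {
      hi <- hi + 1L
      right_min <- min(right_min, y[hi])
      if (y[hi] > y[i]) break
    }
    y[i] - max(left_min, right_min)
  }, numeric(1))
}

# static band-assignment table: wavenumber windows -> tentative biochemical
# assignment, carried as metadata on marker tables
band_assignments <- function() {
  data.frame(
    lo = c(895, 960, 998, 1060, 1125, 1290, 1440, 1452, 1459, 1655),
    hi = c(905, 974, 1008, 1072, 1135, 1300, 1450, 1458, 1466, 1685),
    assignment = c(
      "C-O-C skeletal mode, monosaccharides (beta-glucose)",
      "lipids",
      "C-C skeletal, phenylalanine",
      "proline / collagen",
      "phospholipid structural changes (trans vs gauche)",
      "CH2 angular deformation / phosphodioxy (PO2-)",
      "CH2/CH3 angular deformation, collagen",
      "CH2 deoxyribose",
      "CH2 angular deformation, disaccharides",
      "amide I"),
    stringsAsFactors = FALSE)
}

lookup_assignment <- function(wn) {
  tab <- band_assignments()
  vapply(wn, function(w) {
    hit <- which(tab$lo <= w & w <= tab$hi)
    if (length(hit)) tab$assignment[hit[1]] else NA_character_
  }, character(1))
}

#' Pick discriminant marker bands from a DBM spectrum
#'
#' Local maxima of `|DBM|` with topographic prominence of at least
#' `min_prominence_frac * max(|DBM|)` are selected greedily in decreasing
#' `|DBM|`, skipping candidates closer than `min_separation` to an already
#' accepted band, and truncated to `n_peaks`. Each marker is annotated with
#' the PC1/PC2 loading magnitudes at its wavenumber and a tentative
#' biochemical assignment. The selection is invariant to uniform scaling of
#' the DBM spectrum.
#'
#' @param dbm A [dbm_spectrum()] result.
#' @param pca Optional `raman_pca` supplying loadings for annotation.
#' @param n_peaks Maximum number of markers (default 7).
#' @param min_separation Minimum distance between markers (cm^-1, default 8).
#' @param min_prominence_frac Prominence threshold as a fraction of
#'   `max(|DBM|)` (default 0.05).
#' @return A `marker_table` data frame with columns `wavenumber`,
#'   `dbm_amplitude` (signed), `pc1_loading`, `pc2_loading` (absolute loading
#'   magnitudes, `NA` when unavailable) and `assignment`, sorted by
#'   wavenumber. A flat DBM gives an empty table with a warning.
#' @export
pick_marker_peaks <- function(dbm, pca = NULL, n_peaks = 7, min_separation = 8,
                              min_prominence_frac = 0.05) {
  stopifnot(inherits(dbm, "dbm_result"))
  if (n_peaks < 1) stop("`n_peaks` must be >= 1")
  a <- abs(dbm$dbm)
  empty <- data.frame(wavenumber = numeric(0), dbm_amplitude = numeric(0),
                      pc1_loading = numeric(0), pc2_loading = numeric(0),
                      assignment = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("marker_table", "data.frame")
  if (max(a) == 0) {
    warning("flat DBM spectrum: no marker bands")
    return(empty)
  }
  cand <- local_maxima(a)
  if (length(cand)) {
    prom <- peak_prominence(a, cand)
    cand <- cand[prom >= min_prominence_frac * max(a)]
  }
  if (!length(cand)) return(empty)
  # greedy: decreasing |DBM|, ties to the lower wavenumber
  cand <- cand[order(-a[cand], cand)]
  axis <- as.numeric(dbm$axis)
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) >= n_peaks) break
    if (all(abs(axis[i] - axis[kept]) >= min_separation)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  l1 <- l2 <- rep(NA_real_, length(kept))
  if (!is.null(pca)) {
    l1 <- abs(pca$loadings[kept, 1])
    if (pca$K >= 2L) l2 <- abs(pca$loadings[kept, 2])
  }
  out <- data.frame(wavenumber = axis[kept], dbm_amplitude = dbm$dbm[kept],
                    pc1_loading = l1, pc2_loading = l2,
                    assignment = lookup_assignment(axis[kept]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' PCA score and reconstruction map images
#'
#' Folds per-pixel PCA quantities back onto the spatial grid. In `"score"`
#' mode the image is the score on PC `k`; in `"reconstruction"` mode the
#' spectra are rebuilt from the first `k` components
#' (`X_hat = scores %*% t(loadings) + mean`) and imaged at the requested
#' `band`. Pixel values are mean relative intensities on the scale of the
#' input spectra.
#'
#' @param map A [hyperspec_map()] (normally the pre-processed map the PCA was
#'   fitted on).
#' @param pca A `raman_pca` from [pca_fit()].
#' @param k PC index (`"score"` mode) or number of components used for the
#'   rebuild (`"reconstruction"` mode; defaults to all fitted).
#' @param mode `"score"` or `"reconstruction"`.
#' @param band Wavenumber imaged in `"reconstruction"` mode; must lie on the
#'   map axis (within half an axis step).
#' @return Numeric `rows x cols` matrix with attributes `mode`, `k` and
#'   (reconstruction) `band`.
#' @export
recovered_map <- function(map, pca, k = if (mode == "score") 1L else pca$K,
                          mode = c("score", "reconstruction"), band = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "hyperspec_map"), inherits(pca, "raman_pca"))
  k <- as.integer(k)
  if (k < 1L || k > pca$K) stop("k exceeds the number of fitted PCs")
  sm <- unfold(map)
  d <- dim(map$intensities)
  scores <- pca_transform(pca, sm$X)
  if (mode == "score") {
    img <- matrix(scores[, k], nrow = d[1], ncol = d[2], byrow = TRUE)
    attr(img, "mode") <- "score"; attr(img, "k") <- k
    return(img)
  }
  if (is.null(band)) stop("`band` is required in reconstruction mode")
  step <- if (length(map$axis) > 1L) min(diff(map$axis)) else 1
  j <- which.min(abs(as.numeric(map$axis) - band))
  if (abs(map$axis[j] - band) > step / 2) {
    stop("band ", band, " cm^-1 is not on the map axis")
  }
  xhat <- scores[, seq_len(k), drop = FALSE] %*%
    t(pca$loadings[, seq_len(k), drop = FALSE])
  vals <- xhat[, j] + pca$mean[j]
  img <- matrix(vals, nrow = d[1], ncol = d[2], byrow = TRUE)
  attr(img, "mode") <- "reconstruction"; attr(img, "k") <- k
  attr(img, "band") <- map$axis[j]
  img
}
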