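#' Pre-processing parameters
#'
#' Defaults follow standard Raman practice: a 21-point, 2nd-order
#' Savitzky-Golay smoother followed by automatic weighted least squares
#' (AWLS) baseline correction. The AWLS smoothness penalty `awls_lambda`,
#' the iteration cap and the weight-change tolerance are tunables of this
#' implementation (the method itself fixes only the weighting rule).
#'
#' @param sg_window Odd Savitzky-Golay window length (points), > `sg_polyorder`.
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param awls_lambda Whittaker smoothness penalty (dimensionless, > 0).
#' @param awls_max_iter Maximum AWLS reweighting iterations.
#' @param awls_tol Convergence tolerance on the mean absolute weight change.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 21, sg_polyorder = 2,
                              awls_lambda = 1e5, awls_max_iter = 50,
                              awls_tol = 1e-6) {
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window %% 2L == 0L) stop("`sg_window` must be odd")
  if (sg_window <= sg_polyorder) stop("`sg_window` must exceed `sg_polyorder`")
  if (awls_lambda <= 0) stop("`awls_lambda` must be > 0")
  if (awls_max_iter < 1) stop("`awls_max_iter` must be >= 1")
  structure(list(sg_window = sg_window, sg_polyorder = sg_polyorder,
                 awls_lambda = awls_lambda, awls_max_iter = awls_max_iter,
                 awls_tol = awls_tol),
            class = "preprocess_config")
}

#' Unfold a map into a spectra matrix, and fold it back
#'
#' `unfold` flattens the `rows x cols x m` cube into an `n x m` matrix with
#' one spectrum per row, pixels taken in row-major order (pixel (0,1) becomes
#' matrix row 2). `refold` inverts it; `refold(unfold(map))` reproduces the
#' cube exactly.
#'
#' @param map A [hyperspec_map()].
#' @return `unfold` returns a [spectra_matrix()] carrying pixel coordinates
#'   and per-pixel labels.
#' @export
unfold <- function(map) {
  stopifnot(inherits(map, "hyperspec_map"))
  d <- dim(map$intensities)
  r <- d[1]; cc <- d[2]; m <- d[3]
  # row-major pixel order: row index varies slowest
  X <- matrix(aperm(map$intensities, c(3, 2, 1)), nrow = r * cc, ncol = m,
              byrow = TRUE)
  pix <- cbind(row = rep(0:(r - 1), each = cc), col = rep(0:(cc - 1), times = r))
  labels <- if (!is.null(map$labels)) as.character(t(map$labels)) else NULL
  spectra_matrix(X, map$axis, pixel_index = pix, labels = labels)
}

#' @rdname unfold
#' @param mat A [spectra_matrix()] with full `pixel_index` bookkeeping.
#' @param shape Optional `c(rows, cols)`; inferred from `pixel_index` when
#'   missing.
#' @param metadata Metadata list for the rebuilt map.
#' @export
refold <- function(mat, shape = NULL, metadata = list()) {
  stopifnot(inherits(mat, "spectra_matrix"))
  if (is.null(mat$pixel_index)) stop("refold needs `pixel_index` bookkeeping")
  if (is.null(shape)) {
    shape <- c(max(mat$pixel_index[, 1]) + 1L, max(mat$pixel_index[, 2]) + 1L)
  }
  r <- shape[1]; cc <- shape[2]
  n <- nrow(mat$X)
  if (n != r * cc) stop(sprintf("%d pixels expected, %d given", r * cc, n))
  key <- mat$pixel_index[, 1] * cc + mat$pixel_index[, 2]
  if (anyDuplicated(key)) stop("duplicate pixel rows in `pixel_index`")
  if (!setequal(key, 0:(n - 1L))) stop("pixel rows do not cover the full grid")
  ord <- order(key)
  cube <- aperm(array(t(mat$X[ord, , drop = FALSE]),
                      dim = c(ncol(mat$X), cc, r)), c(3, 2, 1))
  labels <- NULL
  if (!is.null(mat$labels)) {
    labels <- matrix(mat$labels[ord], nrow = r, ncol = cc, byrow = TRUE)
  }
  hyperspec_map(cube, mat$axis, labels = labels, metadata = metadata)
}

#' Savitzky-Golay smoothing
#'
#' Each point is replaced by the value, at its own position, of the
#' least-squares polynomial of degree `polyorder` fitted over the centred
#' `window`. The first and last half-windows are handled by evaluating the
#' terminal window fits at the off-centre positions, so the output keeps the
#' input length and the filter reproduces polynomials of degree
#' `<= polyorder` exactly.
#'
#' @param spectrum Numeric intensity vector.
#' @param window Odd window length (points).
#' @param polyorder Polynomial degree, `< window`.
#' @return Smoothed vector of the same length.
#' @export
sg_smooth <- function(spectrum, window = 21, polyorder = 2) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd")
  if (window <= polyorder) stop("`window` must exceed `polyorder`")
  if (length(spectrum) < window) {
    stop("spectrum shorter than the smoothing window")
  }
  if (any(!is.finite(spectrum))) stop("non-finite intensities")
  as.numeric(signal::sgolayfilt(as.numeric(spectrum), p = polyorder, n = window))
}

# Cached second-difference penalty lambda * t(D) %*% D for a given length.
awls_penalty <- function(m, lambda) {
  D <- Matrix::bandSparse(m - 2L, m, k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  lambda * Matrix::crossprod(D)
}

#' Automatic weighted least squares (AWLS) baseline correction
#'
#' Estimates the smooth fluorescence background of a Raman spectrum with an
#' iteratively reweighted Whittaker smoother. The baseline `z` minimises
#' `sum_i w_i (y_i - z_i)^2 + lambda * sum_i (d2 z)_i^2`; after each solve the
#' weights are reset automatically to 1 where `y <= z` (candidate baseline
#' points) and to a small `eps` where `y > z` (points suspected to belong to
#' bands), starting from all-ones weights. Iteration stops when the mean
#' absolute weight change drops below `tol` or after `max_iter` rounds;
#' non-convergence is reported, not an error.
#'
#' @param spectrum Numeric intensity vector (length >= 10, finite).
#' @param lambda Smoothness penalty (> 0); larger gives a stiffer baseline.
#' @param max_iter Maximum reweighting iterations.
#' @param tol Convergence tolerance on mean `|weight change|`.
#' @param eps Weight assigned to suspected band points.
#' @param penalty Optional precomputed penalty matrix (internal reuse).
#' @return List with `corrected` (spectrum minus baseline), `baseline`,
#'   `weights` (final), `iterations` and logical `converged`.
#' @export
awls_baseline <- function(spectrum, lambda = 1e5, max_iter = 50, tol = 1e-6,
                          eps = 1e-4, penalty = NULL) {
  y <- as.numeric(spectrum)
  m <- length(y)
  if (m < 10L) stop("spectrum too short for baseline estimation (need >= 10)")
  if (any(!is.finite(y))) stop("non-finite intensities")
  P <- if (is.null(penalty)) awls_penalty(m, lambda) else penalty
  w <- rep(1, m)
  z <- y
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    A <- P + Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y <= z, 1, eps)
    dw <- mean(abs(w_new - w))
    w <- w_new
    if (dw < tol) { converged <- TRUE; break }
  }
  list(corrected = y - z, baseline = z, weights = w, iterations = it,
       converged = converged)
}

#' Pre-process every spectrum of a matrix
#'
#' Applies [sg_smooth()] then [awls_baseline()] independently to each row, in
#' that order. Pixel bookkeeping, labels and the axis are preserved. A
#' per-row AWLS convergence report is attached as attribute
#' `"awls_convergence"` (data frame with `row`, `iterations`, `converged`).
#'
#' @param mat A [spectra_matrix()] (or plain matrix).
#' @param config A [preprocess_config()].
#' @return A [spectra_matrix()] of corrected spectra.
#' @export
preprocess_matrix <- function(mat, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  sm <- if (inherits(mat, "spectra_matrix")) mat else
    spectra_matrix(mat, seq_len(ncol(as.matrix(mat))))
  X <- sm$X
  n <- nrow(X); m <- ncol(X)
  out <- X
  report <- data.frame(row = integer(0), iterations = integer(0),
                       converged = logical(0))
  if (n > 0L) {
    P <- awls_penalty(m, config$awls_lambda)
    conv <- logical(n); iters <- integer(n)
    for (i in seq_len(n)) {
      res <- tryCatch({
        s <- sg_smooth(X[i, ], config$sg_window, config$sg_polyorder)
        awls_baseline(s, lambda = config$awls_lambda,
                      max_iter = config$awls_max_iter, tol = config$awls_tol,
                      penalty = P)
      }, error = function(e) {
        stop("pre-processing failed at row ", i, ": ", conditionMessage(e),
             call. = FALSE)
      })
      out[i, ] <- res$corrected
      conv[i] <- res$converged
      iters[i] <- res$iterations
    }
    report <- data.frame(row = seq_len(n), iterations = iters, converged = conv)
  }
  res <- spectra_matrix(out, sm$axis, pixel_index = sm$pixel_index,
                        labels = sm$labels)
  attr(res, "awls_convergence") <- report
  res
}
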