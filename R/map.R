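#' Hyperspectral map container
#'
#' A Raman map is a 3-D cube of intensities (`rows x cols x wavenumbers`)
#' with its wavenumber axis, an optional per-pixel class mask, and free-form
#' acquisition metadata.
#'
#' @param intensities Numeric 3-D array, `rows x cols x m`.
#' @param axis Wavenumber axis of length `m` (see [wn_axis()]).
#' @param labels Optional character matrix of per-pixel class labels with the
#'   same spatial shape as `intensities`.
#' @param metadata Named list of free-form metadata (laser wavelength, power,
#'   magnification, ...).
#' @return A `hyperspec_map` object (list with the fields above).
#' @export
hyperspec_map <- function(intensities, axis, labels = NULL, metadata = list()) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3-D array (rows x cols x wavenumbers)")
  }
  validate_axis(axis)
  if (dim(intensities)[3] != length(axis)) {
    stop("third dimension of `intensities` (", dim(intensities)[3],
         ") must equal the axis length (", length(axis), ")")
  }
  if (!is.null(labels)) {
    if (!is.matrix(labels) || !all(dim(labels) == dim(intensities)[1:2])) {
      stop("`labels` must be a matrix with the same spatial shape as the cube")
    }
    storage.mode(labels) <- "character"
  }
  structure(list(intensities = intensities, axis = axis, labels = labels,
                 metadata = metadata),
            class = "hyperspec_map")
}

#' @export
print.hyperspec_map <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("Raman hyperspectral map: %d x %d pixels, %d wavenumbers (%.6g-%.6g cm^-1)\n",
              d[1], d[2], d[3], min(x$axis), max(x$axis)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Spectra matrix container
#'
#' The unfolded form of a map: an `n x m` matrix with one spectrum per row,
#' per-row pixel coordinates (0-based, row-major) and optional per-row class
#' labels.
#'
#' @param X Numeric `n x m` matrix (n spectra, m wavenumbers).
#' @param axis Wavenumber axis of length `m`.
#' @param pixel_index Optional integer `n x 2` matrix of 0-based (row, col)
#'   pixel origins.
#' @param labels Optional character vector of per-row class labels.
#' @return A `spectra_matrix` object.
#' @seealso [unfold()], [refold()]
#' @export
spectra_matrix <- function(X, axis, pixel_index = NULL, labels = NULL) {
  X <- as.matrix(X)
  validate_axis(axis)
  if (ncol(X) != length(axis)) {
    stop("ncol(X) must equal the axis length")
  }
  if (!is.null(pixel_index)) {
    pixel_index <- as.matrix(pixel_index)
    if (nrow(pixel_index) != nrow(X) || ncol(pixel_index) != 2L) {
      stop("`pixel_index` must be an n x 2 matrix")
    }
    storage.mode(pixel_index) <- "integer"
    colnames(pixel_index) <- c("row", "col")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(X)) stop("`labels` must have one entry per row")
  }
  structure(list(X = X, axis = axis, pixel_index = pixel_index,
                 labels = labels),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("Spectra matrix: %d spectra x %d wavenumbers\n",
              nrow(x$X), ncol(x$X)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

# coerce helper used by matrix-facing functions
as_spectra_X <- function(X) {
  if (inherits(X, "spectra_matrix")) X$X else as.matrix(X)
}
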