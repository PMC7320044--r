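#' Construct a wavenumber axis
#'
#' Builds the spectral x-axis (Raman shift in cm^-1). The default covers the
#' fingerprint window 725--1813 cm^-1 at 1 cm^-1 spacing (1089 points), the
#' acquisition window assumed throughout the package.
#'
#' @param start First wavenumber (cm^-1).
#' @param end Last wavenumber (cm^-1); must exceed `start`.
#' @param step Spacing (cm^-1); must be positive.
#' @return Numeric vector of strictly increasing wavenumbers with attribute
#'   `"step"`.
#' @examples
#' ax <- wn_axis()
#' length(ax) # 1089
#' @export
wn_axis <- function(start = 725, end = 1813, step = 1) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("`step` must be a positive number")
  }
  if (end <= start) stop("`end` must exceed `start`")
  values <- seq(start, end, by = step)
  attr(values, "step") <- step
  values
}

# Validate an axis vector: strictly increasing, finite; if a declared step is
# attached, spacing must be uniform to 1e-9 relative tolerance.
validate_axis <- function(axis) {
  if (!is.numeric(axis) || length(axis) < 1L || any(!is.finite(axis))) {
    stop("wavenumber axis must be a finite numeric vector")
  }
  if (length(axis) > 1L) {
    d <- diff(axis)
    if (any(d <= 0)) stop("wavenumber axis must be strictly increasing")
    step <- attr(axis, "step")
    if (!is.null(step) && any(abs(d - step) > 1e-9 * abs(step))) {
      stop("axis spacing is not uniform at the declared step")
    }
  }
  invisible(axis)
}

# Parabolic (3-point) apex of the dominant local maximum of y on x.
# Returns the interpolated x-position of the apex.
peak_apex <- function(x, y) {
  n <- length(y)
  if (n < 3L) stop("calibration error: spectrum too short to locate a peak")
  i <- which.max(y)
  if (i == 1L || i == n) {
    stop("calibration error: no interior local maximum in reference spectrum")
  }
  if (y[i] < 3 * stats::median(y)) {
    stop("calibration error: dominant peak is < 3x the median intensity")
  }
  # exact quadratic through the three bracketing samples
  xs <- x[(i - 1L):(i + 1L)]
  ys <- y[(i - 1L):(i + 1L)]
  co <- solve(cbind(1, xs - x[i], (xs - x[i])^2), ys)
  if (co[3] >= 0) return(x[i]) # degenerate (flat top): keep grid position
  x[i] - co[2] / (2 * co[3])
}

#' Calibrate a wavenumber axis against a reference line
#'
#' Raman instruments are wavenumber-calibrated against a silicon wafer, whose
#' single sharp phonon line at 520.4 cm^-1 serves as the reference point. The
#' apex of the dominant peak in `reference_spectrum` is located by 3-point
#' parabolic interpolation around the discrete maximum, and the whole axis is
#' rigidly shifted by `reference_peak - apex`. A shift-only correction is
#' applied (no dispersion adjustment).
#'
#' @param axis Wavenumber axis to calibrate (numeric, strictly increasing).
#' @param reference_spectrum Intensities of the reference material, sampled on
#'   `reference_axis`.
#' @param reference_axis Axis on which `reference_spectrum` was recorded;
#'   defaults to `axis` (reference recorded in the same window).
#' @param reference_peak True position of the reference line (cm^-1);
#'   default 520.4, the silicon line.
#' @return The shifted axis, with attribute `"shift"` holding the applied
#'   offset (cm^-1).
#' @examples
#' ax <- wn_axis(400, 640, 1)
#' si <- exp(-((ax - 522.4) / 3)^2)
#' cal <- calibrate_axis(ax, si, ax)
#' attr(cal, "shift") # -2
#' @export
calibrate_axis <- function(axis, reference_spectrum, reference_axis = axis,
                           reference_peak = 520.4) {
  validate_axis(axis)
  validate_axis(reference_axis)
  if (length(reference_spectrum) != length(reference_axis)) {
    stop("reference spectrum and reference axis lengths differ")
  }
  apex <- peak_apex(as.numeric(reference_axis), as.numeric(reference_spectrum))
  shift <- reference_peak - apex
  out <- axis + shift
  attr(out, "step") <- attr(axis, "step")
  attr(out, "shift") <- shift
  out
}
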