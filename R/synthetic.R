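#' Describe a single Raman band
#'
#' @param center Band position (cm^-1); must lie inside the scenario axis.
#' @param height Band amplitude (arbitrary intensity units, >= 0).
#' @param width Full width at half maximum (cm^-1, > 0).
#' @param shape `"gaussian"` (default) or `"lorentzian"`.
#' @return A `peak_spec` object.
#' @export
peak_spec <- function(center, height, width, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center))
  if (!is.numeric(height) || height < 0) stop("peak height must be >= 0")
  if (!is.numeric(width) || width <= 0) stop("peak width (FWHM) must be > 0")
  structure(list(center = center, height = height, width = width, shape = shape),
            class = "peak_spec")
}

# Evaluate one peak on an axis. Gaussian parameterised by FWHM;
# Lorentzian is h * (w/2)^2 / ((x-c)^2 + (w/2)^2).
eval_peak <- function(peak, axis) {
  d <- axis - peak$center
  if (peak$shape == "gaussian") {
    peak$height * exp(-4 * log(2) * d^2 / peak$width^2)
  } else {
    hw <- peak$width / 2
    peak$height * hw^2 / (d^2 + hw^2)
  }
}

#' Describe the spectral profile of one tissue class
#'
#' A class profile is a set of Raman bands on a smooth polynomial background.
#' The background polynomial is evaluated on the axis rescaled to \[0, 1\], so
#' coefficients stay of order one regardless of the wavenumber range.
#' `global_scale` multiplies the whole profile (bands and background), which is
#' how an overall intensity difference between tissue types — such as
#' adenocarcinoma being brighter than Barrett's mucosa — is emulated.
#'
#' @param label Class identifier, e.g. `"BO"` or `"OAC"`.
#' @param peaks List of [peak_spec()] objects.
#' @param baseline_coeffs Polynomial coefficients (intercept first) for the
#'   background, evaluated on the unit-rescaled axis.
#' @param global_scale Multiplicative intensity factor (> 0).
#' @return A `class_profile` object.
#' @export
class_profile <- function(label, peaks, baseline_coeffs = c(0, 0, 0, 0),
                          global_scale = 1) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.list(peaks) || !all(vapply(peaks, inherits, logical(1), "peak_spec"))) {
    stop("`peaks` must be a list of peak_spec objects")
  }
  if (!is.numeric(global_scale) || global_scale <= 0) {
    stop("`global_scale` must be > 0")
  }
  structure(list(label = label, peaks = peaks,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 global_scale = global_scale),
            class = "class_profile")
}

# Noiseless spectrum of a profile on an axis, with optionally jittered
# baseline coefficients.
eval_profile <- function(profile, axis, coeffs = profile$baseline_coeffs) {
  u <- if (length(axis) > 1L) (axis - axis[1]) / (axis[length(axis)] - axis[1]) else 0
  base <- rep(0, length(axis))
  for (j in seq_along(coeffs)) base <- base + coeffs[j] * u^(j - 1)
  sig <- base
  for (p in profile$peaks) sig <- sig + eval_peak(p, axis)
  profile$global_scale * sig
}

#' Define a synthetic Raman-map scenario
#'
#' Bundles everything needed to generate a labelled two-class hyperspectral
#' map: the wavenumber axis, map size, the two class profiles, the spatial
#' lesion layout, and the noise model (i.i.d. additive Gaussian noise plus
#' per-pixel jitter of the baseline coefficients).
#'
#' @param class_profiles List of one or two [class_profile()] objects.
#' @param axis_start,axis_end,axis_step Wavenumber axis (cm^-1); defaults give
#'   the 725--1813 cm^-1 window at 1 cm^-1 spacing.
#' @param map_rows,map_cols Map size in pixels.
#' @param lesion_mask_kind Spatial layout of the second class:
#'   `"half_split"` (bottom half of the rows), `"blob"` (central ellipse) or
#'   `"checkerboard"`.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (intensity units).
#' @param baseline_jitter_sd Standard deviation of the per-pixel perturbation
#'   of each baseline coefficient.
#' @param seed Integer seed; identical scenario + seed gives bit-identical maps.
#' @return A `synthetic_scenario` object.
#' @seealso [generate_map()], [case_presets()]
#' @export
synthetic_scenario <- function(class_profiles,
                               axis_start = 725, axis_end = 1813, axis_step = 1,
                               map_rows = 20, map_cols = 20,
                               lesion_mask_kind = c("half_split", "blob",
                                                    "checkerboard"),
                               noise_sd = 0.02, baseline_jitter_sd = 0.05,
                               seed = 1) {
  lesion_mask_kind <- match.arg(lesion_mask_kind)
  if (axis_step <= 0) stop("`axis_step` must be > 0")
  if (map_rows < 1 || map_cols < 1) stop("map dimensions must be >= 1")
  if (!is.list(class_profiles) ||
      !all(vapply(class_profiles, inherits, logical(1), "class_profile"))) {
    stop("`class_profiles` must be a list of class_profile objects")
  }
  np <- length(class_profiles)
  if (np < 1L || np > 2L) {
    stop("a scenario takes one or two class profiles, got ", np)
  }
  if (noise_sd < 0 || baseline_jitter_sd < 0) stop("noise levels must be >= 0")
  axis <- wn_axis(axis_start, axis_end, axis_step)
  for (pr in class_profiles) {
    cen <- vapply(pr$peaks, `[[`, numeric(1), "center")
    if (any(cen < axis_start | cen > axis_end)) {
      stop("peak centers must lie within the axis range for class ", pr$label)
    }
  }
  if (np == 2L) {
    a <- class_profiles[[1]]; b <- class_profiles[[2]]
    same <- identical(lapply(a$peaks, `[`, c("center", "height")),
                      lapply(b$peaks, `[`, c("center", "height"))) &&
      isTRUE(all.equal(a$global_scale, b$global_scale))
    if (same) stop("the two class profiles must differ in at least one peak ",
                   "height/center or in global_scale")
    if (a$label == b$label) stop("class labels must differ")
  }
  structure(list(axis = axis, map_rows = as.integer(map_rows),
                 map_cols = as.integer(map_cols),
                 class_profiles = class_profiles,
                 lesion_mask_kind = lesion_mask_kind,
                 noise_sd = noise_sd, baseline_jitter_sd = baseline_jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# Character label matrix for the scenario's spatial layout; class 1 is the
# background, class 2 the lesion.
lesion_mask <- function(scenario) {
  r <- scenario$map_rows; cc <- scenario$map_cols
  labs <- vapply(scenario$class_profiles, `[[`, character(1), "label")
  if (length(labs) == 1L) {
    return(matrix(labs, r, cc))
  }
  idx <- switch(scenario$lesion_mask_kind,
    half_split = outer(seq_len(r), seq_len(cc),
                       function(i, j) i > r / 2),
    blob = outer(seq_len(r), seq_len(cc), function(i, j) {
      ((i - (r + 1) / 2) / (r / 3))^2 + ((j - (cc + 1) / 2) / (cc / 3))^2 <= 1
    }),
    checkerboard = outer(seq_len(r), seq_len(cc),
                         function(i, j) (i + j) %% 2 == 1)
  )
  m <- matrix(labs[1], r, cc)
  m[idx] <- labs[2]
  m
}

#' Generate a labelled synthetic Raman hyperspectral map
#'
#' Every pixel's noiseless spectrum is its class background polynomial plus
#' the sum of its class bands, times the class `global_scale`; per-pixel
#' baseline jitter and i.i.d. Gaussian noise are added on top. All randomness
#' flows from `scenario$seed`, so the same scenario reproduces the same map
#' bit for bit.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [hyperspec_map()] with a per-pixel label mask; the scenario is
#'   attached as metadata.
#' @examples
#' sc <- case_presets("case3")
#' m <- generate_map(sc)
#' dim(m$intensities)
#' @export
generate_map <- function(scenario) {
  if (!inherits(scenario, "synthetic_scenario")) {
    stop("`scenario` must be a synthetic_scenario object")
  }
  axis <- scenario$axis
  m <- length(axis)
  r <- scenario$map_rows; cc <- scenario$map_cols
  labs <- lesion_mask(scenario)
  profiles <- scenario$class_profiles
  names(profiles) <- vapply(profiles, `[[`, character(1), "label")

  set.seed(scenario$seed)
  cube <- array(0, dim = c(r, cc, m))
  # pure class spectra reused when there is no baseline jitter
  pure <- lapply(profiles, eval_profile, axis = axis)
  for (i in seq_len(r)) {
    for (j in seq_len(cc)) {
      pr <- profiles[[labs[i, j]]]
      if (scenario$baseline_jitter_sd > 0) {
        co <- pr$baseline_coeffs +
          stats::rnorm(length(pr$baseline_coeffs), 0, scenario$baseline_jitter_sd)
        cube[i, j, ] <- eval_profile(pr, axis, coeffs = co)
      } else {
        cube[i, j, ] <- pure[[labs[i, j]]]
      }
    }
  }
  if (scenario$noise_sd > 0) {
    cube <- cube + array(stats::rnorm(r * cc * m, 0, scenario$noise_sd),
                         dim = c(r, cc, m))
  }
  hyperspec_map(cube, axis, labels = labs,
                metadata = list(generator = "ramanmap synthetic",
                                lesion_mask_kind = scenario$lesion_mask_kind,
                                noise_sd = scenario$noise_sd,
                                baseline_jitter_sd = scenario$baseline_jitter_sd,
                                seed = scenario$seed))
}

# Bands shared by both tissue classes in every preset: a generic tissue-like
# fingerprint (nucleic acids, proteins, lipids, phosphate backbone).
preset_common_peaks <- function() {
  list(
    peak_spec(782,  0.45, 16), # DNA/RNA ring breathing
    peak_spec(855,  0.40, 14), # tyrosine / proline
    peak_spec(940,  0.35, 14), # C-C protein backbone
    peak_spec(1090, 0.55, 16), # phosphate / C-C stretch
    peak_spec(1210, 0.40, 18),
    peak_spec(1340, 0.60, 18), # CH deformation
    peak_spec(1400, 0.35, 14),
    peak_spec(1445, 0.90, 16), # CH2/CH3 deformation (strong tissue band)
    peak_spec(1585, 0.40, 14),
    peak_spec(1655, 0.80, 16), # amide I
    peak_spec(1745, 0.30, 14)  # lipid ester carbonyl
  )
}

#' Preset two-class scenarios mirroring the three patient cases
#'
#' Each preset builds a shared tissue-like fingerprint and raises the
#' malignant ("OAC") profile by +0.3 intensity units at that case's
#' discriminant marker bands:
#' \describe{
#'   \item{case1}{normal squamous epithelium vs OAC; markers at 900, 967,
#'     1296, 1445, 1456 and 1665 cm^-1.}
#'   \item{case2}{Barrett's oesophagus (BO) vs OAC; markers at 1003, 1066,
#'     1130, 1295, 1445, 1462 and 1672 cm^-1, with OAC additionally brighter
#'     overall (global scale 1.2).}
#'   \item{case3}{BO vs OAC; same markers as case2 but amide I at 1675 cm^-1,
#'     OAC global scale 1.15.}
#' }
#'
#' @param name One of `"case1"`, `"case2"`, `"case3"`.
#' @param ... Overrides passed on to [synthetic_scenario()] (e.g. `seed`,
#'   `map_rows`, `noise_sd`).
#' @return A [synthetic_scenario()].
#' @export
case_presets <- function(name, ...) {
  valid <- c("case1", "case2", "case3")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown preset; valid presets are: ", paste(valid, collapse = ", "))
  }
  markers <- switch(name,
    case1 = c(900, 967, 1296, 1445, 1456, 1665),
    case2 = c(1003, 1066, 1130, 1295, 1445, 1462, 1672),
    case3 = c(1003, 1066, 1130, 1295, 1445, 1462, 1675)
  )
  scale_oac <- switch(name, case1 = 1.0, case2 = 1.2, case3 = 1.15)
  benign_label <- if (name == "case1") "normal" else "BO"
  base_coeffs <- c(0.8, 1.2, -0.8, 0.3)
  common <- preset_common_peaks()
  # markers are +0.3 bands on the malignant profile, except the case-1
  # 1456 cm^-1 CH2-deoxyribose band, which is placed on the benign profile
  # instead: the DNA backbone signal is reduced in cancerous tissue, and the
  # opposite-signed difference keeps the 1445/1456 doublet resolvable in the
  # DBM spectrum after the default 21-point smoothing
  benign_markers <- if (name == "case1") 1456 else numeric(0)
  mk <- function(ctrs) lapply(ctrs, function(ctr) peak_spec(ctr, 0.3, 10))
  benign <- class_profile(benign_label, c(common, mk(benign_markers)),
                          base_coeffs, global_scale = 1)
  oac <- class_profile("OAC", c(common, mk(setdiff(markers, benign_markers))),
                       base_coeffs, global_scale = scale_oac)
  sc <- synthetic_scenario(list(benign, oac), ...)
  sc$preset <- name
  sc$marker_bands <- markers
  sc
}
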