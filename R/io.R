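# Text interchange formats. Proprietary instrument files (Renishaw .wdf, SPC)
# are out of scope; maps travel as a long-format CSV (row, col, wavenumber,
# intensity[, label]) with an optional JSON metadata sidecar, and spectra
# matrices as a wide CSV (wavenumber column + one column per spectrum).
# Numbers are written with 17 significant digits so roundtrips are lossless.

fmt17 <- function(x) formatC(x, digits = 17, format = "g", width = -1)

#' Write / read a hyperspectral map as long-format CSV
#'
#' The file has header `row,col,wavenumber,intensity[,label]` and one line per
#' pixel/wavenumber combination, 0-based pixel coordinates in row-major order.
#' Non-empty metadata is written to a JSON sidecar at `<path>.meta.json` and
#' read back if present. Writing then reading reproduces intensities, axis
#' and labels exactly.
#'
#' @param map A [hyperspec_map()].
#' @param path File path.
#' @return `write_map_long_csv` returns `path` invisibly;
#'   `read_map_long_csv` returns a [hyperspec_map()].
#' @export
write_map_long_csv <- function(map, path) {
  stopifnot(inherits(map, "hyperspec_map"))
  d <- dim(map$intensities)
  r <- d[1]; cc <- d[2]; m <- d[3]
  # row-major over pixels, axis fastest
  pix_row <- rep(0:(r - 1), each = cc * m)
  pix_col <- rep(rep(0:(cc - 1), each = m), times = r)
  wn <- rep(as.numeric(map$axis), times = r * cc)
  inten <- as.numeric(aperm(map$intensities, c(3, 2, 1)))
  lines <- paste(pix_row, pix_col, fmt17(wn), fmt17(inten), sep = ",")
  header <- "row,col,wavenumber,intensity"
  if (!is.null(map$labels)) {
    lab <- rep(as.character(t(map$labels)), each = m)
    lines <- paste(lines, lab, sep = ",")
    header <- paste0(header, ",label")
  }
  writeLines(c(header, lines), path)
  if (length(map$metadata)) {
    jsonlite::write_json(map$metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_map_long_csv
#' @export
read_map_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "wavenumber", "intensity")
  if (!all(need %in% names(df))) {
    stop("map CSV must have columns row, col, wavenumber, intensity")
  }
  has_label <- "label" %in% names(df)
  axis <- sort(unique(df$wavenumber))
  if (anyDuplicated(axis)) stop("non-monotone wavenumber axis")
  m <- length(axis)
  rows <- sort(unique(df$row)); cols <- sort(unique(df$col))
  r <- length(rows); cc <- length(cols)
  if (!identical(as.integer(rows), 0:(r - 1)) ||
      !identical(as.integer(cols), 0:(cc - 1))) {
    stop("pixel coordinates must cover a full 0-based grid")
  }
  key <- df$row * cc + df$col
  cnt <- tabulate(key + 1L, nbins = r * cc)
  if (any(cnt != m)) {
    bad <- which(cnt != m)[1] - 1L
    stop(sprintf("incomplete grid at pixel (%d,%d)", bad %/% cc, bad %% cc))
  }
  if (anyDuplicated(cbind(key, df$wavenumber))) {
    stop("duplicate pixel/wavenumber entries")
  }
  ord <- order(df$row, df$col, match(df$wavenumber, axis))
  df <- df[ord, , drop = FALSE]
  cube <- aperm(array(df$intensity, dim = c(m, cc, r)), c(3, 2, 1))
  labels <- NULL
  if (has_label) {
    labmat <- matrix(df$label[seq(1, nrow(df), by = m)], nrow = r, ncol = cc,
                     byrow = TRUE)
    per_pix <- tapply(df$label, df$row * cc + df$col,
                      function(z) length(unique(z)))
    if (any(per_pix != 1L)) {
      bad <- as.integer(names(per_pix)[per_pix != 1L][1])
      stop(sprintf("mixed labels for pixel (%d,%d)", bad %/% cc, bad %% cc))
    }
    labels <- labmat
  }
  ax <- axis
  if (m > 2L) {
    d <- diff(ax)
    if (max(abs(d - d[1])) <= 1e-9 * abs(d[1])) attr(ax, "step") <- d[1]
  }
  meta <- list()
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  hyperspec_map(cube, ax, labels = labels, metadata = meta)
}

#' Write / read a spectra matrix as wide-format CSV
#'
#' First column is the wavenumber; every other column is one spectrum. When
#' the matrix carries class labels, a second header line `label,<l1>,<l2>,...`
#' follows the column names. On reading, the table is transposed to the
#' package's `n x m` convention (n spectra in rows, m wavenumbers in columns).
#'
#' @param mat A [spectra_matrix()].
#' @param path File path.
#' @return `write_spectra_wide_csv` returns `path` invisibly;
#'   `read_spectra_wide_csv` returns a [spectra_matrix()].
#' @export
write_spectra_wide_csv <- function(mat, path) {
  stopifnot(inherits(mat, "spectra_matrix"))
  n <- nrow(mat$X)
  header <- paste(c("wavenumber", sprintf("s%d", seq_len(n))), collapse = ",")
  out <- header
  if (!is.null(mat$labels)) {
    out <- c(out, paste(c("label", mat$labels), collapse = ","))
  }
  body <- apply(cbind(as.numeric(mat$axis), t(mat$X)), 1,
                function(z) paste(fmt17(z), collapse = ","))
  writeLines(c(out, body), path)
  invisible(path)
}

#' @rdname write_spectra_wide_csv
#' @export
read_spectra_wide_csv <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 2L) stop("spectra CSV has no data rows")
  first <- strsplit(ln[2], ",", fixed = TRUE)[[1]]
  labels <- NULL
  skip <- 1L
  if (identical(first[1], "label")) {
    labels <- first[-1]
    skip <- 2L
  }
  df <- utils::read.csv(text = ln[-seq_len(skip)], header = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("non-numeric cells in spectra CSV")
  }
  axis <- df[[1]]
  if (anyDuplicated(axis)) stop("duplicate wavenumber rows in spectra CSV")
  ord <- order(axis)
  axis <- axis[ord]
  X <- t(as.matrix(df[ord, -1, drop = FALSE]))
  dimnames(X) <- NULL
  if (!is.null(labels) && length(labels) != nrow(X)) {
    stop("label header row length does not match the number of spectra")
  }
  if (length(axis) > 2L) {
    d <- diff(axis)
    if (max(abs(d - d[1])) <= 1e-9 * abs(d[1])) attr(axis, "step") <- d[1]
  }
  spectra_matrix(X, axis, labels = labels)
}
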