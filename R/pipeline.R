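REPORT_SCHEMA_VERSION <- "1.0"

#' Configuration for a full case analysis
#'
#' @param input A preset name (`"case1"`, `"case2"`, `"case3"`), a
#'   [synthetic_scenario()], a [hyperspec_map()], or a path to a long-format
#'   map CSV (see [read_map_long_csv()]).
#' @param preprocess A [preprocess_config()].
#' @param train_fraction Kennard-Stone training fraction (default 0.70).
#' @param n_splits Venetian-blinds folds for PC-count selection (default 10).
#' @param max_pcs Largest candidate PC count (default 15).
#' @param n_pcs Fixed PC count; when given, cross-validated selection is
#'   skipped and this K is used directly.
#' @param positive_class Label treated as positive in the figures of merit;
#'   default `"OAC"` when present, otherwise the lexicographically larger
#'   label.
#' @param seed Seed driving all randomness (synthetic map generation).
#' @param output_dir Optional directory for report files (see
#'   [write_case_report()]).
#' @return A `case_config` list.
#' @export
case_config <- function(input = "case3", preprocess = preprocess_config(),
                        train_fraction = 0.70, n_splits = 10, max_pcs = 15,
                        n_pcs = NULL, positive_class = NULL, seed = 1,
                        output_dir = NULL) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1")
  }
  stopifnot(inherits(preprocess, "preprocess_config"))
  if (n_splits < 2) stop("`n_splits` must be >= 2")
  if (max_pcs < 1) stop("`max_pcs` must be >= 1")
  if (!is.null(n_pcs) && n_pcs < 1) stop("`n_pcs` must be >= 1")
  structure(list(input = input, preprocess = preprocess,
                 train_fraction = train_fraction, n_splits = n_splits,
                 max_pcs = max_pcs, n_pcs = n_pcs,
                 positive_class = positive_class, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "case_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

resolve_input_map <- function(input, seed) {
  if (inherits(input, "hyperspec_map")) return(input)
  if (inherits(input, "synthetic_scenario")) return(generate_map(input))
  if (is.character(input) && length(input) == 1L) {
    if (input %in% c("case1", "case2", "case3")) {
      return(generate_map(case_presets(input, seed = seed)))
    }
    if (file.exists(input)) return(read_map_long_csv(input))
    stop("input '", input, "' is neither a preset name nor an existing file")
  }
  stop("unsupported `input`")
}

#' Run the full per-case analysis
#'
#' Executes the complete chain on one labelled map: load or generate the map,
#' unfold, pre-process (Savitzky-Golay + AWLS), Kennard-Stone 70/30 split,
#' PC-count selection by venetian-blinds cross-validation on the training set
#' (unless `n_pcs` is fixed), PCA-LDA fit on the training rows, evaluation of
#' training and validation figures of merit, difference-between-mean spectrum
#' and marker-band table from the training rows, and PC1-score plus
#' reconstruction map images. Validation rows are never used for model
#' fitting, component selection or marker extraction. All randomness flows
#' from `config$seed`, so identical configurations give identical reports.
#'
#' @param config A [case_config()].
#' @return A `raman_case` object; see [write_case_report()] for the file
#'   outputs.
#' @examples
#' \donttest{
#' res <- run_case(case_config("case3", n_pcs = 2, seed = 1))
#' res$validation_fom
#' }
#' @export
run_case <- function(config) {
  if (!inherits(config, "case_config")) {
    stop("`config` must be built with case_config()")
  }
  map <- stage("input", resolve_input_map(config$input, config$seed))
  if (is.null(map$labels)) stop("stage 'input': map carries no class labels")

  raw <- stage("unfold", unfold(map))
  pre <- stage("preprocess", preprocess_matrix(raw, config$preprocess))

  split <- stage("split", kennard_stone_split(pre, config$train_fraction))
  tr <- split$train_rows # KS selection order, kept for venetian blinds
  va <- split$validation_rows
  X_tr <- pre$X[tr, , drop = FALSE]
  lab_tr <- pre$labels[tr]
  X_va <- pre$X[va, , drop = FALSE]
  lab_va <- pre$labels[va]

  classes <- sort(unique(pre$labels))
  positive <- config$positive_class
  if (is.null(positive)) {
    positive <- if ("OAC" %in% classes) "OAC" else classes[length(classes)]
  }

  selection <- NULL
  if (is.null(config$n_pcs)) {
    selection <- stage("select_pcs",
      select_n_pcs(X_tr, lab_tr, candidates = seq_len(config$max_pcs),
                   n_splits = config$n_splits))
    best_K <- selection$best_K
  } else {
    best_K <- min(config$n_pcs, nrow(X_tr) - 1L, ncol(X_tr))
  }

  fit <- stage("pcalda", pcalda(X_tr, lab_tr, k = best_K))
  pred_tr <- fit$fitted
  pred_va <- stage("validate", predict(fit, X_va))

  counts_tr <- confusion_counts(lab_tr, pred_tr$class, positive)
  counts_va <- confusion_counts(lab_va, pred_va$class, positive)
  fom_tr <- figures_of_merit(counts_tr)
  fom_va <- figures_of_merit(counts_va)

  # biomarkers from training rows only (no validation leak)
  train_mat <- spectra_matrix(X_tr, pre$axis, labels = lab_tr)
  benign <- setdiff(classes, positive)[1]
  dbm <- stage("dbm", dbm_spectrum(train_mat, class_order = c(positive, benign)))
  marker_pca <- if (fit$pca$K >= 2L) fit$pca else
    pca_fit(X_tr, min(2L, nrow(X_tr) - 1L, ncol(X_tr)))
  markers <- stage("markers", pick_marker_peaks(dbm, marker_pca))

  pre_map <- refold(pre, dim(map$intensities)[1:2])
  strongest <- if (nrow(markers)) markers$wavenumber[which.max(abs(markers$dbm_amplitude))] else
    pre$axis[which.max(abs(dbm$dbm))]
  images <- stage("maps", list(
    pc1_score = recovered_map(pre_map, fit$pca, k = 1, mode = "score"),
    reconstruction = recovered_map(pre_map, fit$pca, k = fit$pca$K,
                                   mode = "reconstruction", band = strongest)))

  res <- structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("ramanmap")),
    config = config,
    classes = classes, positive_class = positive,
    split = split,
    pc_selection = selection, best_K = best_K,
    explained_variance_pct = fit$pca$explained_variance_pct,
    model = fit,
    training_counts = counts_tr, training_fom = fom_tr,
    validation_counts = counts_va, validation_fom = fom_va,
    predictions = data.frame(
      row = c(tr, va),
      set = rep(c("training", "validation"), c(length(tr), length(va))),
      truth = c(lab_tr, lab_va),
      predicted = c(pred_tr$class, pred_va$class),
      df = c(pred_tr$df, pred_va$df),
      stringsAsFactors = FALSE),
    dbm = dbm, markers = markers, images = images,
    awls_convergence = attr(pre, "awls_convergence")),
    class = "raman_case")
  if (!is.null(config$output_dir)) write_case_report(res, config$output_dir)
  res
}

#' @export
print.raman_case <- function(x, ...) {
  cat("Raman map case analysis\n")
  cat(sprintf("  classes: %s (positive: %s)\n",
              paste(x$classes, collapse = " vs "), x$positive_class))
  cat(sprintf("  split: %d training / %d validation\n",
              length(x$split$train_rows), length(x$split$validation_rows)))
  cat(sprintf("  PCs: %d (%.2f%% cumulative explained variance)\n",
              x$best_K, sum(x$explained_variance_pct)))
  cat("  validation "); print(x$validation_fom)
  cat(sprintf("  markers: %d bands (%s cm^-1)\n", nrow(x$markers),
              paste(round(x$markers$wavenumber), collapse = ", ")))
  invisible(x)
}

#' @export
summary.raman_case <- function(object, ...) {
  print(object)
  cat("  training "); print(object$training_fom)
  if (!is.null(object$pc_selection)) {
    cat("  CV accuracy by K (%):\n")
    print(round(object$pc_selection$cv_accuracy, 2))
  }
  invisible(object)
}

# JSON-serialisable view of the case report (deterministic field order)
case_report_list <- function(x) {
  cfg <- x$config
  list(
    schema_version = x$schema_version,
    package_version = x$package_version,
    config = list(
      input = if (is.character(cfg$input)) cfg$input else class(cfg$input)[1],
      sg_window = cfg$preprocess$sg_window,
      sg_polyorder = cfg$preprocess$sg_polyorder,
      awls_lambda = cfg$preprocess$awls_lambda,
      train_fraction = cfg$train_fraction,
      n_splits = cfg$n_splits, max_pcs = cfg$max_pcs,
      n_pcs = cfg$n_pcs, seed = cfg$seed),
    classes = x$classes, positive_class = x$positive_class,
    n_training = length(x$split$train_rows),
    n_validation = length(x$split$validation_rows),
    best_K = x$best_K,
    explained_variance_pct = x$explained_variance_pct,
    cumulative_explained_variance_pct = sum(x$explained_variance_pct),
    cv_accuracy = if (!is.null(x$pc_selection)) x$pc_selection$cv_accuracy,
    training = list(
      counts = x$training_counts[c("TP", "TN", "FP", "FN")],
      accuracy_pct = x$training_fom$accuracy_pct,
      sensitivity_pct = x$training_fom$sensitivity_pct,
      specificity_pct = x$training_fom$specificity_pct),
    validation = list(
      counts = x$validation_counts[c("TP", "TN", "FP", "FN")],
      accuracy_pct = x$validation_fom$accuracy_pct,
      sensitivity_pct = x$validation_fom$sensitivity_pct,
      specificity_pct = x$validation_fom$specificity_pct),
    markers = x$markers)
}

#' Write the file outputs of a case analysis
#'
#' Writes `report.json` (versioned machine-readable report), `markers.csv`,
#' `predictions.csv` and the two map images as CSV matrices
#' (`image_pc1_score.csv`, `image_reconstruction.csv`) into `dir`. Identical
#' analyses produce byte-identical reports.
#'
#' @param x A `raman_case` from [run_case()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case_report <- function(x, dir) {
  stopifnot(inherits(x, "raman_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(case_report_list(x), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  utils::write.csv(x$markers, file.path(dir, "markers.csv"), row.names = FALSE)
  utils::write.csv(x$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.table(x$images$pc1_score,
                     file.path(dir, "image_pc1_score.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(x$images$reconstruction,
                     file.path(dir, "image_reconstruction.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Plot a case analysis
#'
#' Two-panel base-graphics figure: the DBM spectrum with the selected marker
#' bands flagged, and the PC1-score image of the map.
#'
#' @param x A `raman_case`.
#' @param ... Unused.
#' @export
plot.raman_case <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$dbm$axis, x$dbm$dbm, type = "l",
                 xlab = "wavenumber (cm^-1)", ylab = "DBM intensity",
                 main = sprintf("DBM: %s - %s", x$dbm$class_order[1],
                                x$dbm$class_order[2]))
  graphics::abline(v = x$markers$wavenumber, col = "#c23b22", lty = 3)
  img <- x$images$pc1_score
  graphics::image(t(img[nrow(img):1, , drop = FALSE]), axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = "PC1 score image")
  invisible(x)
}
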