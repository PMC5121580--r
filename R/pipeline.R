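# End-to-end drivers: simulate or ingest -> align -> scale -> PCA ->
# repeated validation -> best model -> canonical roots -> marker table.

#' Configuration for a full analysis run
#'
#' @param mode `"synthetic"` (generate peak lists from `config`) or
#'   `"files"` (read a manifest written by [write_peak_lists()]).
#' @param config a [synthetic_config()] for synthetic mode; the default is
#'   the three-parchment-class study configuration.
#' @param manifest manifest path for file mode.
#' @param tolerance m/z alignment tolerance in Da.
#' @param row_range,col_range range-scaling target intervals.
#' @param n_pcs number of candidate principal components.
#' @param n_repeats outer validation repeats.
#' @param n_iterations bootstrap CV iterations per evaluation.
#' @param holdout_fraction per-class test / CV holdout fraction.
#' @param marker_method,marker_thresholds significance rule for
#'   [significant_weights()].
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir directory for run artifacts, or `NULL` to skip writing.
#' @return a validated `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       config = parchment_only_config(),
                       manifest = NULL, tolerance = 0.01,
                       row_range = c(0, 1), col_range = c(0, 1),
                       n_pcs = 20, n_repeats = 25, n_iterations = 100,
                       holdout_fraction = 0.2,
                       marker_method = "fixed",
                       marker_thresholds = c(0.1, 0.05),
                       seed = 1L, output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(manifest)) stop("file mode needs a manifest")
  if (tolerance <= 0) stop("tolerance must be positive")
  if (n_pcs < 1) stop("n_pcs must be >= 1")
  if (n_repeats < 1 || n_iterations < 1) stop("counts must be positive")
  if (holdout_fraction < 0 || holdout_fraction >= 1)
    stop("holdout_fraction must be in [0, 1)")
  if (diff(row_range) <= 0 || diff(col_range) <= 0)
    stop("scaling ranges must be increasing")
  structure(list(mode = mode, config = config, manifest = manifest,
                 tolerance = tolerance, row_range = row_range,
                 col_range = col_range, n_pcs = n_pcs,
                 n_repeats = n_repeats, n_iterations = n_iterations,
                 holdout_fraction = holdout_fraction,
                 marker_method = marker_method,
                 marker_thresholds = marker_thresholds,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the full classification analysis
#'
#' Generates (or reads) the peak lists, aligns them, runs the repeated
#' validation protocol, picks the model closest to the ideal NER point,
#' refits it, computes its canonical roots, back-projects them to per-m/z
#' marker weights and flags the significant ones. Deterministic given the
#' config seed. When `output_dir` is set, writes `records.csv`,
#' `summary.json`, `markers.csv`, `explained_variance.csv` and
#' `class_metrics.csv`.
#'
#' @param rc a [run_config()].
#' @return list with `aligned`, `records`, `summary_table`, `best`, `refit`,
#'   `canonical`, `markers`, `root_summary`, `metrics_test`.
#' @export
run_full_analysis <- function(rc = run_config()) {
  stopifnot(inherits(rc, "run_config"))
  seeds <- expand_seeds(rc$seed, 3L)
  spectra <- switch(rc$mode,
    synthetic = generate_dataset(rc$config, seeds[1]),
    files = read_peak_lists(rc$manifest))
  aligned <- align_spectra(spectra, rc$tolerance)
  records <- repeated_validation(aligned, n_repeats = rc$n_repeats,
                                 n_iterations = rc$n_iterations,
                                 holdout_fraction = rc$holdout_fraction,
                                 n_pcs = rc$n_pcs, seed = seeds[2],
                                 row_range = rc$row_range,
                                 col_range = rc$col_range)
  best <- pick_best_model(records)
  refit <- refit_record(aligned, best, n_iterations = rc$n_iterations,
                        holdout_fraction = rc$holdout_fraction,
                        n_pcs = rc$n_pcs, row_range = rc$row_range,
                        col_range = rc$col_range)
  sel <- refit$selected
  canon <- canonical_analysis(
    refit$train_scores[, sel, drop = FALSE], refit$train_labels)
  weights <- variable_weights(refit$pca$loadings[, sel, drop = FALSE],
                              canon$root_coefficients, mz = aligned$mz)
  markers <- significant_weights(weights, method = rc$marker_method,
                                 thresholds = rc$marker_thresholds)
  metrics_test <- class_metrics(refit$test_labels, refit$pred_test)
  out <- list(aligned = aligned, records = records,
              summary_table = summarize_records(records), best = best,
              refit = refit, canonical = canon, markers = markers,
              root_summary = interpret_roots(canon),
              metrics_test = metrics_test)
  if (!is.null(rc$output_dir)) .write_run_artifacts(out, rc)
  invisible(out)
}

.write_run_artifacts <- function(out, rc) {
  dir.create(rc$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(rc$output_dir, f)
  rec <- out$records
  rec$selected_pcs <- vapply(rec$selected_pcs, paste, character(1),
                             collapse = ";")
  utils::write.csv(rec, p("records.csv"), row.names = FALSE)
  utils::write.csv(out$markers, p("markers.csv"), row.names = FALSE)
  utils::write.csv(explained_variance_report(out$refit$pca),
                   p("explained_variance.csv"), row.names = FALSE)
  utils::write.csv(out$metrics_test$per_class, p("class_metrics.csv"),
                   row.names = FALSE)
  summary <- list(
    best_model = list(
      repeat_index = out$best$repeat_index,
      selected_pcs = out$best$selected_pcs[[1]],
      ner_train = out$best$ner_train, ner_cv = out$best$ner_cv,
      ner_test = out$best$ner_test,
      distance_to_ideal = out$best$distance_to_ideal),
    records = list(n_repeats = nrow(out$records),
                   ner_test_min = min(out$records$ner_test),
                   ner_test_max = max(out$records$ner_test)),
    significant_markers = out$markers$mz[rowSums(
      as.matrix(out$markers[grep("^flag_root", names(out$markers))])) > 0],
    seed = rc$seed)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Run the ion-source temperature study
#'
#' Generates (or accepts) a three-temperature dataset over the parchment
#' classes, aligns it, column-range-scales to `[-1, 1]` and fits one PCA
#' over all temperatures. Returns the annotated score table plus per-class
#' centroid displacement across temperatures (the glycerol class is
#' expected to move least).
#'
#' @param config a [synthetic_config()] with `temperature_levels`.
#' @param spectra optional pre-built list of temperature-annotated
#'   [peak_spectrum()] objects; overrides generation.
#' @param tolerance alignment tolerance (Da).
#' @param col_range scaling interval (the study used -1..1 here).
#' @param n_pcs components to keep.
#' @param seed integer seed.
#' @param output_dir optional artifact directory (`scores.csv`,
#'   `displacement.csv`, `explained_variance.csv`).
#' @return list with `aligned`, `pca`, `scores` (data frame with class and
#'   temperature), `displacement` (per-class mean centroid travel).
#' @export
run_temperature_study <- function(config = default_parchment_config(),
                                  spectra = NULL, tolerance = 0.01,
                                  col_range = c(-1, 1), n_pcs = 10,
                                  seed = 1L, output_dir = NULL) {
  if (is.null(spectra))
    spectra <- generate_temperature_dataset(config, seed = seed)
  if (all(is.na(vapply(spectra, `[[`, numeric(1), "temperature"))))
    stop("spectra carry no temperature metadata")
  aligned <- align_spectra(spectra, tolerance)
  scaled <- range_scale_columns(aligned, col_range[1], col_range[2])
  k <- min(n_pcs, nrow(scaled$X) - 1L, ncol(scaled$X))
  pca <- fit_pca(scaled, k)
  scores <- data.frame(sample_id = aligned$sample_ids,
                       class = aligned$labels,
                       temperature = aligned$temperature,
                       pca$training_scores)
  displacement <- .centroid_displacement(pca$training_scores,
                                         aligned$labels, aligned$temperature)
  out <- list(aligned = aligned, pca = pca, scores = scores,
              displacement = displacement)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(scores, file.path(output_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(displacement, file.path(output_dir, "displacement.csv"),
                     row.names = FALSE)
    utils::write.csv(explained_variance_report(pca),
                     file.path(output_dir, "explained_variance.csv"),
                     row.names = FALSE)
  }
  invisible(out)
}

# mean pairwise distance between a class's per-temperature centroids in
# score space: how far the class travels as source temperature changes.
.centroid_displacement <- function(scores, labels, temperature) {
  classes <- sort(unique(labels))
  rows <- lapply(classes, function(g) {
    sel <- labels == g
    cent <- rowsum(scores[sel, , drop = FALSE], temperature[sel])
    cent <- cent / as.integer(table(temperature[sel]))
    d <- stats::dist(cent)
    data.frame(class = g, mean_displacement = mean(d))
  })
  do.call(rbind, rows)
}
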