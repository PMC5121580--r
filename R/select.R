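# Validation protocol: (1) stratified 20% test split; (2) PCA on the
# training set only, test samples reprojected; (3) forward-stepwise LDA on
# the training scores, ranking candidate PCs by NER% in bootstrap
# cross-validation (repeated stratified 20% holdout); (4) test-set NER.
# Steps (1)-(4) are repeated with fresh random splits and the overall best
# model is the one closest to the ideal (100, 100, 100) NER point.

.round_half_up <- function(x) floor(x + 0.5)

# per-class holdout counts under the nearest-integer (half-up) rule
.split_counts <- function(class_sizes, fraction) {
  .round_half_up(fraction * class_sizes)
}

# draw a stratified holdout given a list of per-class index vectors;
# consumes the current RNG stream.
.strat_pick <- function(idx_by_class, k_per_class) {
  unlist(lapply(seq_along(idx_by_class), function(i) {
    idx <- idx_by_class[[i]]
    k <- k_per_class[i]
    if (k == 0) integer(0) else idx[sample.int(length(idx), k)]
  }), use.names = FALSE)
}

#' Stratified train/test split
#'
#' From each class, `round(fraction * n_g)` samples (nearest integer, halves
#' up) are drawn uniformly at random into the test set; with the study's
#' class sizes 19/28/21 and `fraction = 0.2` this gives the 4/6/4 test
#' composition. Train and test are disjoint and exhaustive.
#'
#' @param labels class labels.
#' @param fraction test fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, fraction = 0.2, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  labels <- as.character(labels)
  idx_by_class <- split(seq_along(labels), labels)
  sizes <- lengths(idx_by_class)
  k <- .split_counts(sizes, fraction)
  if (any(sizes - k < 2))
    stop("class '", names(idx_by_class)[which(sizes - k < 2)[1]],
         "' would keep fewer than 2 training samples")
  test <- withr::with_seed(as.integer(seed), .strat_pick(idx_by_class, k))
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Bootstrap cross-validated NER
#'
#' Repeats a stratified holdout `n_iterations` times: each iteration
#' excludes `holdout_fraction` of every class from the training set (drawn
#' without replacement), fits the discriminant model on the remainder and
#' scores the excluded samples. Returns the mean of the per-iteration NER%.
#' The same seed always reproduces the same holdout sequence, so candidate
#' feature sets evaluated under one seed see identical splits.
#'
#' @param scores training score matrix (samples x components).
#' @param labels training labels.
#' @param feature_indices components included in the model.
#' @param n_iterations number of holdout iterations.
#' @param holdout_fraction fraction of each class excluded per iteration.
#' @param seed integer seed.
#' @return mean cross-validated NER on the 0-100 scale.
#' @export
bootstrap_cv_ner <- function(scores, labels, feature_indices,
                             n_iterations = 1000, holdout_fraction = 0.2,
                             seed = 1L) {
  stopifnot(n_iterations >= 1)
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  y <- match(labels, lv)
  g <- length(lv)
  idx_by_class <- split(seq_along(labels), labels)
  sizes <- lengths(idx_by_class)
  k <- .split_counts(sizes, holdout_fraction)
  if (any(sizes - k < 2)) stop("holdout leaves a class with < 2 training samples")
  X <- scores[, feature_indices, drop = FALSE]
  all_idx <- seq_along(labels)
  ner <- numeric(n_iterations)
  withr::with_seed(as.integer(seed), {
    for (it in seq_len(n_iterations)) {
      hold <- .strat_pick(idx_by_class, k)
      keep <- all_idx[-hold]
      core <- .lda_core(X[keep, , drop = FALSE], y[keep], g)
      pred <- .lda_predict(core, X[hold, , drop = FALSE])
      ner[it] <- 100 * mean(pred == y[hold])
    }
  })
  mean(ner)
}

#' Forward-stepwise selection of principal components
#'
#' Greedy forward search over `candidate_pcs`: at each step every unused
#' candidate is appended to the current set and scored by
#' [bootstrap_cv_ner()]; the candidate with the highest cross-validated NER
#' joins the model (ties to the lower PC index). Selection stops when no
#' candidate strictly increases the CV NER. The first step always adds one
#' component.
#'
#' @inheritParams bootstrap_cv_ner
#' @param candidate_pcs candidate component indices (default first 20).
#' @return list with `selected` (ordered indices) and `cv_path`
#'   (nondecreasing CV NER after each addition).
#' @export
forward_select <- function(scores, labels, candidate_pcs = 1:20,
                           n_iterations = 1000, holdout_fraction = 0.2,
                           seed = 1L) {
  if (!length(candidate_pcs)) stop("empty candidate pool")
  scores <- as.matrix(scores)
  candidate_pcs <- sort(unique(as.integer(candidate_pcs)))
  if (max(candidate_pcs) > ncol(scores))
    stop("candidate index beyond score columns")
  step_seeds <- expand_seeds(seed, length(candidate_pcs))
  selected <- integer(0)
  cv_path <- numeric(0)
  best_cv <- -Inf
  for (step in seq_along(candidate_pcs)) {
    pool <- setdiff(candidate_pcs, selected)
    if (!length(pool)) break
    cv <- vapply(pool, function(p)
      bootstrap_cv_ner(scores, labels, c(selected, p), n_iterations,
                       holdout_fraction, step_seeds[step]),
      numeric(1))
    j <- which.max(cv)   # ties: first = lowest index (pool is sorted)
    if (cv[j] > best_cv || step == 1L) {
      selected <- c(selected, pool[j])
      best_cv <- cv[j]
      cv_path <- c(cv_path, best_cv)
    } else break
  }
  list(selected = selected, cv_path = cv_path)
}

#' Expand one seed into a reproducible sequence of sub-seeds
#'
#' @param seed master seed.
#' @param n number of sub-seeds.
#' @return integer vector of seeds below 2^31.
#' @export
expand_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

#' Repeated split-train-test validation
#'
#' Runs the full protocol `n_repeats` times. Each repeat draws a fresh
#' stratified split, fits the column scaling and PCA on the training rows
#' only, reprojects the test rows, selects components by forward-stepwise
#' search with bootstrap cross-validation, and records the training,
#' cross-validation and test NER of the resulting model. Row scaling is
#' per-sample (self-contained) and therefore applied once to all samples.
#'
#' @param m a raw `aligned_matrix` with labels.
#' @param n_repeats number of outer repeats.
#' @param n_iterations bootstrap iterations per CV evaluation.
#' @param holdout_fraction test (and CV holdout) fraction per class.
#' @param n_pcs number of candidate components.
#' @param seed master seed; per-repeat split and CV seeds derive from it.
#' @param row_range,col_range target intervals for row / column range
#'   scaling.
#' @return data frame of class `validation_records`: `repeat_index`,
#'   `split_seed`, `cv_seed`, `n_selected`, `selected_pcs` (list column),
#'   `ner_train`, `ner_cv`, `ner_test`.
#' @export
repeated_validation <- function(m, n_repeats = 100, n_iterations = 1000,
                                holdout_fraction = 0.2, n_pcs = 20,
                                seed = 1L, row_range = c(0, 1),
                                col_range = c(0, 1)) {
  stopifnot(inherits(m, "aligned_matrix"), n_repeats >= 1)
  seeds <- matrix(expand_seeds(seed, 2L * n_repeats), ncol = 2)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    fit <- .fit_one_split(m, split_seed = seeds[r, 1], cv_seed = seeds[r, 2],
                          n_iterations = n_iterations,
                          holdout_fraction = holdout_fraction, n_pcs = n_pcs,
                          row_range = row_range, col_range = col_range)
    rows[[r]] <- data.frame(repeat_index = r, split_seed = seeds[r, 1],
                            cv_seed = seeds[r, 2],
                            n_selected = length(fit$selected),
                            selected_pcs = I(list(fit$selected)),
                            ner_train = fit$ner_train, ner_cv = fit$ner_cv,
                            ner_test = fit$ner_test)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("validation_records", class(out))
  out
}

# One split-scale-PCA-select-test cycle; also the refit path for the best
# model, so the pipeline can reconstruct its artifacts from the seeds alone.
.fit_one_split <- function(m, split_seed, cv_seed, n_iterations,
                           holdout_fraction, n_pcs, row_range, col_range,
                           keep_models = FALSE) {
  mr <- range_scale_rows(m, row_range[1], row_range[2])
  sp <- stratified_split(mr$labels, holdout_fraction, split_seed)
  train <- mr; train$X <- mr$X[sp$train, , drop = FALSE]
  train$sample_ids <- mr$sample_ids[sp$train]
  train$labels <- mr$labels[sp$train]
  train$temperature <- mr$temperature[sp$train]
  train <- range_scale_columns(train, col_range[1], col_range[2])
  k <- min(n_pcs, length(sp$train) - 1L, ncol(mr$X))
  pca <- fit_pca(train, k)
  test_X <- .apply_col_scale(mr$X[sp$test, , drop = FALSE],
                             train$scaling_params$column)
  test_scores <- project(pca, test_X)
  fs <- forward_select(pca$training_scores, train$labels,
                       candidate_pcs = seq_len(k),
                       n_iterations = n_iterations,
                       holdout_fraction = holdout_fraction, seed = cv_seed)
  model <- fit_lda(pca$training_scores, train$labels, fs$selected)
  pred_tr <- classify(model, pca$training_scores[, fs$selected, drop = FALSE])
  pred_te <- classify(model, test_scores[, fs$selected, drop = FALSE])
  out <- list(selected = fs$selected,
              ner_train = ner_percent(train$labels, pred_tr),
              ner_cv = fs$cv_path[length(fs$cv_path)],
              ner_test = ner_percent(mr$labels[sp$test], pred_te))
  if (keep_models) {
    out$split <- sp
    out$pca <- pca
    out$lda <- model
    out$train_labels <- train$labels
    out$test_labels <- mr$labels[sp$test]
    out$train_scores <- pca$training_scores
    out$test_scores <- test_scores
    out$column_params <- train$scaling_params$column
    out$pred_train <- pred_tr
    out$pred_test <- pred_te
  }
  out
}

#' Pick the overall best model
#'
#' The best repeat is the one whose `(NER_train, NER_cv, NER_test)` triple
#' lies closest (Euclidean distance) to the ideal model at
#' `(100, 100, 100)`; ties go to the earlier repeat.
#'
#' @param records a `validation_records` data frame.
#' @return one-row record with an added `distance_to_ideal` column.
#' @export
pick_best_model <- function(records) {
  if (!nrow(records)) stop("no validation records")
  d <- sqrt((100 - records$ner_train)^2 + (100 - records$ner_cv)^2 +
            (100 - records$ner_test)^2)
  best <- records[which.min(d), , drop = FALSE]   # which.min: earliest tie
  best$distance_to_ideal <- min(d)
  best
}

#' Refit the model of one validation record
#'
#' Reconstructs the full artifact set (scaling parameters, PCA, selected
#' components, LDA model, train/test scores) of a recorded repeat from its
#' stored seeds — used to materialise the best model for canonical analysis
#' and marker extraction.
#'
#' @param m the raw `aligned_matrix` the records were computed on.
#' @param record one row of a `validation_records` data frame.
#' @inheritParams repeated_validation
#' @export
refit_record <- function(m, record, n_iterations = 1000,
                         holdout_fraction = 0.2, n_pcs = 20,
                         row_range = c(0, 1), col_range = c(0, 1)) {
  .fit_one_split(m, split_seed = record$split_seed, cv_seed = record$cv_seed,
                 n_iterations = n_iterations,
                 holdout_fraction = holdout_fraction, n_pcs = n_pcs,
                 row_range = row_range, col_range = col_range,
                 keep_models = TRUE)
}

#' Table-1-style summary of a validation run
#'
#' @param records a `validation_records` data frame.
#' @return data frame with model-size range and min/max NER per set.
#' @export
summarize_records <- function(records) {
  data.frame(
    n_pcs_min = min(records$n_selected), n_pcs_max = max(records$n_selected),
    ner_train_min = min(records$ner_train), ner_train_max = max(records$ner_train),
    ner_cv_min = min(records$ner_cv), ner_cv_max = max(records$ner_cv),
    ner_test_min = min(records$ner_test), ner_test_max = max(records$ner_test))
}
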