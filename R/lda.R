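# Bayesian linear discriminant analysis on PCA scores.
#
# Each class g is a Gaussian with its own centroid c_g and a covariance
# shared across classes (the pooled within-class covariance S_p). A sample x
# is assigned to the class minimising the discriminant score
#
#   D(g|x) = (x - c_g)' S_p^{-1} (x - c_g) + ln|S_p| - 2 ln P_g
#
# i.e. squared Mahalanobis distance plus a log-determinant term and a prior
# penalty. Priors default to equal.

# ---- fast core (no validation; used by CV loops) --------------------------

# X: n x k numeric, y: integer class codes 1..g. Returns centroids, the
# Cholesky factor of S_p (after a ridge escalation if needed), ln|S_p| and
# priors. Ridge: eps * trace(S_p)/k * I with eps growing by decades.
.lda_core <- function(X, y, nclass, priors = NULL) {
  k <- ncol(X)
  n <- nrow(X)
  counts <- tabulate(y, nclass)
  cent <- rowsum(X, y, reorder = TRUE) / counts
  Xc <- X - cent[y, , drop = FALSE]
  Sp <- crossprod(Xc) / (n - nclass)
  R <- tryCatch(chol(Sp), error = function(e) NULL)
  if (is.null(R)) {
    base_ridge <- max(sum(diag(Sp)) / k, .Machine$double.eps)
    eps <- 1e-8
    while (is.null(R) && eps <= 1) {
      R <- tryCatch(chol(Sp + diag(eps * base_ridge, k)), error = function(e) NULL)
      eps <- eps * 10
    }
    if (is.null(R)) stop("pooled covariance not repairable by ridge")
  }
  if (is.null(priors)) priors <- rep(1 / nclass, nclass)
  list(centroids = cent, chol = R, log_det = 2 * sum(log(diag(R))),
       priors = priors, counts = counts)
}

# Discriminant scores D(g|x) for rows of X; returns n x g matrix.
.lda_scores <- function(core, X) {
  g <- nrow(core$centroids)
  n <- nrow(X)
  D <- matrix(0, n, g)
  for (j in seq_len(g)) {
    Z <- backsolve(core$chol, t(X) - core$centroids[j, ], transpose = TRUE)
    D[, j] <- colSums(Z^2)
  }
  sweep(D, 2, core$log_det - 2 * log(core$priors), `+`)
}

.lda_predict <- function(core, X) {
  max.col(-.lda_scores(core, X), ties.method = "first")
}

# ---- public surface -------------------------------------------------------

#' Fit a linear discriminant model on selected components
#'
#' Class centroids are the per-class means; the shared covariance is the
#' pooled within-class covariance `S_p = sum_g (n_g - 1) cov_g / (N - G)`.
#' A singular `S_p` (possible in small bootstrap resamples) is repaired by
#' adding a ridge `eps * trace(S_p)/K * I`, with `eps` starting at 1e-8 and
#' escalating by decades until the Cholesky factorisation succeeds.
#'
#' @param scores numeric matrix of PCA scores (samples x components).
#' @param labels class labels, one per row.
#' @param feature_indices column indices to use (default: all columns).
#' @param priors prior class probabilities, in `sort(unique(labels))` order;
#'   default equal for all classes.
#' @return an `lda_model` with `feature_indices`, `class_labels`,
#'   `centroids`, `pooled_covariance`, `log_det` and `priors`.
#' @export
fit_lda <- function(scores, labels, feature_indices = NULL, priors = NULL) {
  scores <- as.matrix(scores)
  if (is.null(feature_indices)) feature_indices <- seq_len(ncol(scores))
  X <- scores[, feature_indices, drop = FALSE]
  lv <- sort(unique(as.character(labels)))
  if (length(lv) < 2) stop("need at least 2 classes")
  y <- match(as.character(labels), lv)
  if (any(tabulate(y, length(lv)) < 2))
    stop("every class needs at least 2 samples")
  if (!is.null(priors)) {
    if (length(priors) != length(lv) || any(priors <= 0))
      stop("priors must be positive, one per class")
    priors <- priors / sum(priors)
  }
  core <- .lda_core(X, y, length(lv), priors)
  structure(list(feature_indices = feature_indices, class_labels = lv,
                 centroids = core$centroids,
                 pooled_covariance = crossprod(core$chol),
                 log_det = core$log_det, priors = core$priors,
                 chol = core$chol),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes on %d features (PCs %s)\n",
              length(x$class_labels), length(x$feature_indices),
              paste(x$feature_indices, collapse = ", ")))
  invisible(x)
}

#' Per-class discriminant scores
#'
#' Evaluates `D(g|x)` for each class; classification picks the minimum.
#'
#' @param model an `lda_model`.
#' @param x numeric vector (one sample) or matrix of samples on the model's
#'   selected features.
#' @return matrix (samples x classes) of discriminant scores.
#' @export
discriminant_scores <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != ncol(model$centroids))
    stop("feature dimension mismatch")
  D <- .lda_scores(model, X)
  colnames(D) <- model$class_labels
  D
}

#' Classify samples by minimum discriminant score
#'
#' Ties are broken in favour of the first class in `model$class_labels`.
#'
#' @inheritParams discriminant_scores
#' @return character vector of predicted labels.
#' @export
classify <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != ncol(model$centroids))
    stop("feature dimension mismatch")
  model$class_labels[.lda_predict(model, X)]
}

#' Non-error rate
#'
#' Percentage of samples assigned to their true class.
#'
#' @param true_labels,predicted_labels equal-length nonempty label vectors.
#' @return NER on the 0-100 scale.
#' @export
ner_percent <- function(true_labels, predicted_labels) {
  if (!length(true_labels)) stop("empty input")
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  100 * mean(as.character(true_labels) == as.character(predicted_labels))
}

#' Per-class specificity and selectivity
#'
#' Specificity of class g is `TN / (TN + FP) * 100`: how well samples of
#' other classes avoid being assigned to g. Selectivity is class precision,
#' `TP / (TP + FP) * 100`, defined as 100 when nothing is assigned to g.
#'
#' @inheritParams ner_percent
#' @return list with `per_class` (data frame: class, specificity,
#'   selectivity) and `ner`.
#' @export
class_metrics <- function(true_labels, predicted_labels) {
  truth <- as.character(true_labels); pred <- as.character(predicted_labels)
  if (!length(truth)) stop("empty input")
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  classes <- sort(unique(truth))
  if (!all(pred %in% classes)) stop("prediction contains unknown label")
  rows <- lapply(classes, function(g) {
    tp <- sum(truth == g & pred == g)
    fp <- sum(truth != g & pred == g)
    tn <- sum(truth != g & pred != g)
    data.frame(class = g,
               specificity = 100 * tn / (tn + fp),
               selectivity = if (tp + fp == 0) 100 else 100 * tp / (tp + fp))
  })
  list(per_class = do.call(rbind, rows), ner = ner_percent(truth, pred))
}
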