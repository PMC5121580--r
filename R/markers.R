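# Canonical discriminant analysis of the final model and back-projection of
# the root coefficients through the PCA loadings to per-m/z marker weights.

#' Canonical discriminant analysis on selected components
#'
#' Solves the generalised eigenproblem of the between-class scatter against
#' the within-class scatter on the (mean-centred) selected-component scores.
#' With G classes at most G-1 roots exist; they are ordered by decreasing
#' between/within variance ratio (the canonical eigenvalues). Coefficients
#' are raw (unstandardised) and normalised so each root has unit pooled
#' within-class variance; an option standardises them by the component
#' standard deviations instead. The sign convention makes the
#' largest-magnitude coefficient of each root positive. A singular
#' within-class scatter is repaired by the same escalating ridge as the
#' discriminant model.
#'
#' @param scores matrix of training scores on the selected components.
#' @param labels training class labels.
#' @param standardized if `TRUE`, coefficients are multiplied by the pooled
#'   within-class standard deviation of each component.
#' @return a `canonical_model`: `root_coefficients` (components x roots),
#'   `root_scores` (samples x roots), `eigenvalues`, `center`, `labels`.
#' @export
canonical_analysis <- function(scores, labels, standardized = FALSE) {
  X <- as.matrix(scores)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  g <- length(lv)
  if (g < 2) stop("need at least 2 classes")
  y <- match(labels, lv)
  n <- nrow(X); k <- ncol(X)
  counts <- tabulate(y, g)
  if (any(counts < 2)) stop("every class needs at least 2 samples")
  grand <- colMeans(X)
  cent <- rowsum(X, y, reorder = TRUE) / counts
  Xw <- X - cent[y, , drop = FALSE]
  W <- crossprod(Xw)                                   # within-class scatter
  Cb <- sweep(cent, 2, grand)
  B <- crossprod(Cb * sqrt(counts))                    # between-class scatter
  Sp <- W / (n - g)
  R <- tryCatch(chol(Sp), error = function(e) NULL)
  if (is.null(R)) {
    base_ridge <- max(sum(diag(Sp)) / k, .Machine$double.eps)
    eps <- 1e-8
    while (is.null(R) && eps <= 1) {
      R <- tryCatch(chol(Sp + diag(eps * base_ridge, k)), error = function(e) NULL)
      eps <- eps * 10
    }
    if (is.null(R)) stop("within-class scatter not repairable by ridge")
  }
  # symmetrise: eigen of R^-T B R^-1 / (n - g) has the eigenvalues of W^-1 B
  M <- backsolve(R, t(backsolve(R, t(B), transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2 / (n - g)
  ev <- eigen(M, symmetric = TRUE)
  n_roots <- min(g - 1L, k)
  vals <- pmax(ev$values[seq_len(n_roots)], 0)
  A <- backsolve(R, ev$vectors[, seq_len(n_roots), drop = FALSE])
  # backsolve(R, u) gives a with R a = u, hence a' Sp a = u'u = 1: raw
  # coefficients on the unit pooled within-class variance scale
  for (r in seq_len(ncol(A))) {
    j <- which.max(abs(A[, r]))
    if (A[j, r] < 0) A[, r] <- -A[, r]
  }
  if (standardized) A <- A * sqrt(diag(Sp))
  rownames(A) <- colnames(X)
  colnames(A) <- paste0("root", seq_len(ncol(A)))
  root_scores <- sweep(X, 2, grand) %*% A
  structure(list(root_coefficients = A, root_scores = root_scores,
                 eigenvalues = vals, center = grand, labels = labels,
                 class_labels = lv),
            class = "canonical_model")
}

#' @export
print.canonical_model <- function(x, ...) {
  cat(sprintf("<canonical_model> %d roots, eigenvalues %s\n",
              ncol(x$root_coefficients),
              paste(sprintf("%.3f", x$eigenvalues), collapse = ", ")))
  invisible(x)
}

#' Back-project root coefficients to per-m/z variable weights
#'
#' Principal components are linear combinations of the original m/z
#' variables, so the weight of variable j on root r is the loading-weighted
#' sum of the root coefficients over the selected components:
#' `w[j, r] = sum_k loading[j, k] * coefficient[k, r]`.
#'
#' @param pca_loadings loadings restricted to the selected components
#'   (variables x components).
#' @param root_coefficients coefficients from [canonical_analysis()]
#'   (components x roots).
#' @param mz optional m/z axis for the output table.
#' @return data frame of class `marker_table`: `mz` plus one
#'   `weight_root<r>` column per root.
#' @export
variable_weights <- function(pca_loadings, root_coefficients, mz = NULL) {
  L <- as.matrix(pca_loadings)
  A <- as.matrix(root_coefficients)
  if (ncol(L) != nrow(A))
    stop("loadings (", ncol(L), " components) do not match coefficients (",
         nrow(A), ")")
  W <- L %*% A
  if (is.null(mz)) {
    mz <- suppressWarnings(as.numeric(rownames(L)))
    if (is.null(rownames(L)) || anyNA(mz)) mz <- seq_len(nrow(L))
  }
  out <- data.frame(mz = mz)
  for (r in seq_len(ncol(W))) out[[paste0("weight_root", r)]] <- W[, r]
  class(out) <- c("marker_table", class(out))
  out
}

#' Flag significant marker weights
#'
#' Two modes. `"fixed"` flags weights whose absolute value exceeds a
#' per-root threshold (defaults 0.1 on root 1 and 0.05 on root 2, the
#' convention of the study's supplementary list). `"normal_probability"`
#' operationalises the normal-probability-plot reading: the ordered weights
#' of each root are fitted by a robust straight line against normal
#' quantiles (median/IQR line), and a weight is flagged when its residual
#' exceeds `multiplier` times the sampling standard error of its order
#' statistic under that line — weights on the line (a single normal
#' population) are never flagged, departures in the tails are.
#'
#' @param weights a `marker_table` from [variable_weights()].
#' @param method `"fixed"` or `"normal_probability"`.
#' @param thresholds per-root absolute thresholds for the fixed mode;
#'   recycled if shorter than the number of roots.
#' @param multiplier residual multiple for the normal-probability mode.
#' @return the table with one logical `flag_root<r>` column per root, plus
#'   a `threshold` attribute recording the rule used.
#' @export
significant_weights <- function(weights, method = c("fixed", "normal_probability"),
                                thresholds = c(0.1, 0.05), multiplier = 4) {
  method <- match.arg(method)
  wcols <- grep("^weight_root", names(weights), value = TRUE)
  n_roots <- length(wcols)
  thr <- rep_len(thresholds, n_roots)
  for (r in seq_len(n_roots)) {
    w <- weights[[wcols[r]]]
    flag <- if (method == "fixed") {
      abs(w) > thr[r]
    } else {
      .qq_outliers(w, multiplier)
    }
    weights[[paste0("flag_root", r)]] <- flag
  }
  attr(weights, "threshold") <- if (method == "fixed")
    list(method = "fixed", thresholds = thr)
  else list(method = "normal_probability", multiplier = multiplier)
  weights
}

# Normal-probability-plot outliers: residuals of the ordered sample from a
# median/IQR reference line, compared to the asymptotic standard error of
# each order statistic, sd(x_(i)) ~ slope * sqrt(p(1-p)/n) / phi(q_p).
.qq_outliers <- function(w, multiplier) {
  n <- length(w)
  if (n < 4) return(rep(FALSE, n))
  o <- order(w)
  ws <- w[o]
  p <- stats::ppoints(n)
  q <- stats::qnorm(p)
  slope <- stats::IQR(ws) / (stats::qnorm(0.75) - stats::qnorm(0.25))
  if (slope == 0) slope <- stats::mad(ws)
  if (slope == 0) slope <- .Machine$double.eps
  intercept <- stats::median(ws)
  resid <- ws - (intercept + slope * q)
  se <- slope * sqrt(p * (1 - p) / n) / stats::dnorm(q)
  flag_sorted <- abs(resid) > multiplier * se
  flag <- logical(n)
  flag[o] <- flag_sorted
  flag
}

#' Summarise class positions along canonical roots
#'
#' For each root, reports the class mean scores, their signs and the class
#' ordering — the textual counterpart of a canonical score plot (e.g. "root
#' 1 separates glycerol-treated samples at negative values from the other
#' classes at positive values").
#'
#' @param root_scores sample-by-root score matrix (or a `canonical_model`).
#' @param labels class labels (ignored when a model is given).
#' @return list with one data frame per root (`class`, `mean_score`,
#'   `sign`), classes ordered by mean score; empty with a warning for a
#'   single class.
#' @export
interpret_roots <- function(root_scores, labels = NULL) {
  if (inherits(root_scores, "canonical_model")) {
    labels <- root_scores$labels
    root_scores <- root_scores$root_scores
  }
  S <- as.matrix(root_scores)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    warning("fewer than two classes: nothing to separate")
    return(list())
  }
  out <- lapply(seq_len(ncol(S)), function(r) {
    mm <- tapply(S[, r], labels, mean)
    df <- data.frame(class = names(mm), mean_score = as.numeric(mm),
                     sign = ifelse(mm >= 0, "+", "-"))
    df[order(df$mean_score), ]
  })
  names(out) <- colnames(S) %||% paste0("root", seq_len(ncol(S)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Which root isolates a given class
#'
#' Picks the root with the largest standardised gap between the class mean
#' and the nearest other-class mean — a helper for marker reporting on the
#' class-separating root.
#'
#' @param model a `canonical_model`.
#' @param class_name class to isolate.
#' @return integer root index.
#' @export
separating_root <- function(model, class_name) {
  S <- model$root_scores
  labels <- model$labels
  if (!class_name %in% labels) stop("unknown class '", class_name, "'")
  gaps <- vapply(seq_len(ncol(S)), function(r) {
    mm <- tapply(S[, r], labels, mean)
    spread <- stats::sd(S[, r])
    min(abs(mm[class_name] - mm[names(mm) != class_name])) / max(spread, 1e-12)
  }, numeric(1))
  which.max(gaps)
}

#' Plot canonical root scores by class
#'
#' @param x a `canonical_model`.
#' @param roots which two roots to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.canonical_model <- function(x, roots = c(1, 2), ...) {
  S <- x$root_scores
  if (ncol(S) < 2) stop("need at least two roots to plot")
  cls <- factor(x$labels)
  graphics::plot(S[, roots[1]], S[, roots[2]], col = as.integer(cls),
                 pch = 19, xlab = paste("Root", roots[1]),
                 ylab = paste("Root", roots[2]), ...)
  graphics::legend("topright", legend = levels(cls), col = seq_along(levels(cls)),
                   pch = 19, cex = 0.8)
  invisible(x)
}
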