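# ---- PCA ------------------------------------------------------------------

#' Principal component analysis with held-out-sample reprojection
#'
#' Mean-centred singular value decomposition of the (already range-scaled)
#' sample-by-m/z matrix. Loadings carry a deterministic sign convention —
#' the largest-magnitude entry of each loading vector is positive — so
#' repeated fits and downstream marker back-projection are reproducible.
#' Explained variance percentages are computed over the full decomposition
#' (all `min(N-1, P)` components), then truncated to the requested number.
#'
#' @param m an `aligned_matrix` or plain numeric matrix (samples x
#'   variables).
#' @param n_components number of components to keep, between 1 and
#'   `min(N-1, P)`.
#' @return a `pca_model`: `column_means`, `loadings` (P x K, orthonormal
#'   columns), `explained_variance_pct` (length K), `training_scores`
#'   (N x K), `full_variance_pct` (all components) and `mz` when available.
#' @export
fit_pca <- function(m, n_components = 20) {
  X <- if (inherits(m, "aligned_matrix")) m$X else as.matrix(m)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 samples")
  kmax <- min(n - 1L, p)
  if (n_components < 1 || n_components > kmax)
    stop("n_components must be in 1..", kmax)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = kmax)
  var_all <- sv$d[seq_len(kmax)]^2 / (n - 1)
  pct_all <- 100 * var_all / sum(var_all)
  V <- sv$v[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude loading entry positive
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  scores <- Xc %*% V
  structure(list(column_means = mu, loadings = V,
                 explained_variance_pct = pct_all[seq_len(n_components)],
                 full_variance_pct = pct_all,
                 training_scores = scores,
                 mz = if (inherits(m, "aligned_matrix")) m$mz else NULL),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("<pca_model> %d components over %d variables\n",
              k, nrow(x$loadings)))
  show <- utils::head(x$explained_variance_pct, 5)
  cat("  explained variance %:",
      paste(sprintf("PC%d=%.2f", seq_along(show), show), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project samples into a fitted PCA space
#'
#' Held-out samples must already be on the training scale (per-sample row
#' scaling plus the training column min/max via [apply_column_scaling()]);
#' the model's stored column means and loadings are then applied.
#'
#' @param model a `pca_model`.
#' @param m an `aligned_matrix` or matrix with the model's column set.
#' @return score matrix (rows x components).
#' @export
project <- function(model, m) {
  X <- if (inherits(m, "aligned_matrix")) m$X else as.matrix(m)
  if (ncol(X) != length(model$column_means))
    stop("column mismatch: model has ", length(model$column_means),
         " variables, data has ", ncol(X))
  sweep(X, 2, model$column_means) %*% model$loadings
}

#' Explained-variance table
#'
#' @param model a `pca_model`.
#' @return data frame with `pc` and `pct` (0-100 scale, nonincreasing).
#' @export
explained_variance_report <- function(model) {
  data.frame(pc = seq_along(model$explained_variance_pct),
             pct = model$explained_variance_pct)
}
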