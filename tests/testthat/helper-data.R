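# Shared fixture builders. Everything is generated in code; no files.

# quick spectrum from bare vectors
spec <- function(id, mz, intensity, class = NA_character_, temp = NA_real_) {
  peak_spectrum(id, mz, intensity, class_label = class, temperature = temp)
}

# small labelled score matrix: g well-separated Gaussian classes in k dims
make_separated_scores <- function(n_per_class = 8, g = 3, k = 2, sep = 10,
                                  sd = 1, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(g), function(ci) {
      center <- rep(0, k)
      center[((ci - 1) %% k) + 1] <- sep * ci
      matrix(stats::rnorm(n_per_class * k, sd = sd), ncol = k) +
        matrix(center, n_per_class, k, byrow = TRUE)
    }))
    list(scores = X, labels = rep(paste0("c", seq_len(g)), each = n_per_class))
  })
}

# hand-buildable discriminant model (documented lda_model fields)
manual_lda_model <- function(centroids, Sp, priors = NULL,
                             labels = paste0("c", seq_len(nrow(centroids)))) {
  if (is.null(priors)) priors <- rep(1 / nrow(centroids), nrow(centroids))
  R <- chol(Sp)
  structure(list(feature_indices = seq_len(ncol(centroids)),
                 class_labels = labels, centroids = centroids,
                 pooled_covariance = Sp, log_det = 2 * sum(log(diag(R))),
                 priors = priors, chol = R),
            class = "lda_model")
}

# independent evaluation of the discriminant score with an explicit inverse
brute_force_discriminant <- function(X, centroids, Sp, priors) {
  Sinv <- solve(Sp)
  ld <- determinant(Sp, logarithm = TRUE)$modulus[1]
  t(apply(X, 1, function(x) {
    vapply(seq_len(nrow(centroids)), function(gidx) {
      d <- x - centroids[gidx, ]
      drop(t(d) %*% Sinv %*% d) + ld - 2 * log(priors[gidx])
    }, numeric(1))
  }))
}

# brute-force clustering oracle for alignment on well-separated peak groups:
# cut the pooled sorted m/z wherever adjacent gaps exceed the tolerance.
gap_clusters <- function(mz, tolerance) {
  o <- order(mz)
  cl <- as.integer(cumsum(c(1, diff(mz[o]) > tolerance)))
  out <- integer(length(mz))
  out[o] <- cl
  out
}
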