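# ---- spectrum container ---------------------------------------------------

#' One centroided mass spectrum with sample metadata
#'
#' Peaks are stored sorted by ascending m/z with unique positions and
#' nonnegative intensities; duplicate m/z entries are summed.
#'
#' @param sample_id sample identifier.
#' @param mz peak positions in Da (> 0).
#' @param intensity peak intensities in counts (>= 0), same length as `mz`.
#' @param class_label class label, or `NA`.
#' @param temperature ion-source temperature in deg C, or `NA`.
#' @return an object of class `peak_spectrum`.
#' @export
peak_spectrum <- function(sample_id, mz, intensity, class_label = NA_character_,
                          temperature = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) && any(mz <= 0)) stop("m/z values must be positive")
  if (length(intensity) && any(intensity < 0))
    stop("intensities must be nonnegative")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(sample_id = as.character(sample_id),
                 class_label = as.character(class_label),
                 temperature = as.numeric(temperature),
                 peaks = data.frame(mz = mz, intensity = intensity)),
            class = "peak_spectrum")
}

#' @export
print.peak_spectrum <- function(x, ...) {
  cat(sprintf("<peak_spectrum> %s  class=%s  %d peaks, m/z %.3f-%.3f\n",
              x$sample_id, x$class_label, nrow(x$peaks),
              if (nrow(x$peaks)) min(x$peaks$mz) else NA,
              if (nrow(x$peaks)) max(x$peaks$mz) else NA))
  invisible(x)
}

# ---- alignment ------------------------------------------------------------

#' Align spectra onto a common m/z grid
#'
#' All peaks from all spectra are pooled, sorted by m/z and clustered
#' greedily: a peak joins the current cluster when its m/z lies within
#' `tolerance` of the cluster's running intensity-weighted centroid,
#' otherwise it opens a new cluster. Each cluster becomes one column of the
#' sample-by-m/z matrix, placed at the final intensity-weighted mean m/z;
#' samples without a peak in a cluster get intensity 0, and several peaks of
#' one sample falling into the same cluster are summed.
#'
#' @param spectra nonempty list of [peak_spectrum()] objects.
#' @param tolerance maximum distance (Da) from a cluster centroid.
#' @return an `aligned_matrix`: list with `mz` (ascending grid), `X`
#'   (samples x m/z intensities), `sample_ids`, `labels`, `temperature`,
#'   `scaling_state` and `scaling_params`.
#' @export
align_spectra <- function(spectra, tolerance = 0.01) {
  if (!length(spectra)) stop("no spectra to align")
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be positive")
  n <- length(spectra)
  sizes <- vapply(spectra, function(s) nrow(s$peaks), integer(1))
  mz <- unlist(lapply(spectra, function(s) s$peaks$mz), use.names = FALSE)
  ity <- unlist(lapply(spectra, function(s) s$peaks$intensity), use.names = FALSE)
  samp <- rep.int(seq_len(n), sizes)
  o <- order(mz)
  mz <- mz[o]; ity <- ity[o]; samp <- samp[o]

  m <- length(mz)
  cluster <- integer(m)
  k <- 0L
  centroid <- 0; wsum <- 0; csum <- 0; cn <- 0L
  for (i in seq_len(m)) {
    if (k == 0L || mz[i] - centroid > tolerance) {
      k <- k + 1L
      wsum <- ity[i]; csum <- mz[i] * ity[i]; cn <- 1L
      centroid <- if (wsum > 0) csum / wsum else mz[i]
    } else {
      wsum <- wsum + ity[i]; csum <- csum + mz[i] * ity[i]; cn <- cn + 1L
      # zero-intensity peaks fall back to an unweighted running mean
      centroid <- if (wsum > 0) csum / wsum else centroid + (mz[i] - centroid) / cn
    }
    cluster[i] <- k
  }

  axis <- vapply(split(seq_len(m), cluster), function(ii) {
    w <- ity[ii]
    if (sum(w) > 0) sum(mz[ii] * w) / sum(w) else mean(mz[ii])
  }, numeric(1))
  X <- matrix(0, n, k)
  idx <- cbind(samp, cluster)
  # accumulate (duplicate sample/cluster pairs sum)
  for (i in seq_len(m)) X[samp[i], cluster[i]] <- X[samp[i], cluster[i]] + ity[i]
  o2 <- order(axis)
  X <- X[, o2, drop = FALSE]
  axis <- axis[o2]
  colnames(X) <- sprintf("%.4f", axis)
  ids <- unname(vapply(spectra, `[[`, character(1), "sample_id"))
  rownames(X) <- ids
  structure(list(mz = unname(axis), X = X, sample_ids = ids,
                 labels = unname(vapply(spectra, `[[`, character(1), "class_label")),
                 temperature = unname(vapply(spectra, `[[`, numeric(1), "temperature")),
                 scaling_state = "raw", scaling_params = list()),
            class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("<aligned_matrix> %d samples x %d m/z columns (%s)\n",
              nrow(x$X), ncol(x$X), x$scaling_state))
  if (!all(is.na(x$labels)))
    print(table(x$labels))
  invisible(x)
}

# ---- range scaling --------------------------------------------------------

.range_scale <- function(v, lo, hi) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(lo, length(v)))
  lo + (v - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Range scaling of an aligned matrix
#'
#' `range_scale_rows()` maps each sample's intensities affinely onto
#' `[lo, hi]` using that row's own min and max, removing overall abundance
#' differences between samples. `range_scale_columns()` does the same per
#' m/z column and stores the column min/max so the identical transform can
#' later be applied to held-out samples with [apply_column_scaling()]
#' (held-out values may then fall outside `[lo, hi]`). Constant rows or
#' columns map to `lo`.
#'
#' @param m an `aligned_matrix`.
#' @param lo,hi target interval, `hi > lo`.
#' @return the matrix with scaled `X`, updated `scaling_state` and, for
#'   columns, `scaling_params$column` holding `min`, `max`, `lo`, `hi`.
#' @export
range_scale_rows <- function(m, lo = 0, hi = 1) {
  stopifnot(inherits(m, "aligned_matrix"))
  if (hi <= lo) stop("hi must be > lo")
  rmin <- apply(m$X, 1, min)
  rmax <- apply(m$X, 1, max)
  span <- rmax - rmin
  scaled <- (m$X - rmin) / ifelse(span == 0, 1, span) * (hi - lo) + lo
  scaled[span == 0, ] <- lo
  m$X <- scaled
  m$scaling_params$row <- list(min = rmin, max = rmax, lo = lo, hi = hi)
  m$scaling_state <- if (m$scaling_state == "raw") "row_scaled" else m$scaling_state
  m
}

#' @rdname range_scale_rows
#' @export
range_scale_columns <- function(m, lo = 0, hi = 1) {
  stopifnot(inherits(m, "aligned_matrix"))
  if (hi <= lo) stop("hi must be > lo")
  cmin <- apply(m$X, 2, min)
  cmax <- apply(m$X, 2, max)
  m$scaling_params$column <- list(min = cmin, max = cmax, lo = lo, hi = hi)
  m$X <- .apply_col_scale(m$X, m$scaling_params$column)
  m$scaling_state <- switch(m$scaling_state,
                            raw = "column_scaled",
                            row_scaled = "row_then_column_scaled",
                            m$scaling_state)
  m
}

.apply_col_scale <- function(X, p) {
  span <- p$max - p$min
  fac <- ifelse(span == 0, 0, (p$hi - p$lo) / span)
  out <- sweep(sweep(X, 2, p$min), 2, fac, `*`) + p$lo
  dimnames(out) <- dimnames(X)
  out
}

#' Apply stored column-scaling parameters to new data
#'
#' Used to put held-out samples on the training scale: each column is mapped
#' with the training min/max, so values outside the training range land
#' outside `[lo, hi]`.
#'
#' @param m an `aligned_matrix` (or plain matrix) with the same columns the
#'   parameters were fitted on.
#' @param params the `scaling_params$column` list from a column-scaled
#'   training matrix.
#' @export
apply_column_scaling <- function(m, params) {
  X <- if (inherits(m, "aligned_matrix")) m$X else m
  if (ncol(X) != length(params$min)) stop("column count mismatch")
  out <- .apply_col_scale(X, params)
  if (inherits(m, "aligned_matrix")) {
    m$X <- out
    m$scaling_params$column <- params
    m$scaling_state <- switch(m$scaling_state,
                              raw = "column_scaled",
                              row_scaled = "row_then_column_scaled",
                              m$scaling_state)
    m
  } else out
}

#' Invert column scaling
#'
#' @inheritParams apply_column_scaling
#' @keywords internal
#' @export
invert_column_scaling <- function(m, params) {
  X <- if (inherits(m, "aligned_matrix")) m$X else m
  span <- params$max - params$min
  raw <- sweep((X - params$lo) / (params$hi - params$lo), 2, span, `*`)
  raw <- sweep(raw, 2, params$min, `+`)
  constant <- span == 0
  if (any(constant)) raw[, constant] <- rep(params$min[constant], each = nrow(raw))
  if (inherits(m, "aligned_matrix")) { m$X <- raw; m } else raw
}

# ---- TIC ------------------------------------------------------------------

#' Total ion current of a scan series
#'
#' @param series time-ordered list of [peak_spectrum()] objects (one scan
#'   each).
#' @return data frame with `scan` (acquisition index) and `tic` (summed
#'   intensity of all peaks in the scan).
#' @export
total_ion_current <- function(series) {
  data.frame(scan = seq_along(series),
             tic = vapply(series, function(s) sum(s$peaks$intensity),
                          numeric(1)))
}

# ---- disk round-trip ------------------------------------------------------

#' Write / read an aligned matrix as a delimited table
#'
#' The table carries the m/z grid as the header row and sample ids as the
#' first column; labels and temperatures go to a `<path>.labels.tsv`
#' sidecar. The round trip restores an identical object up to printed
#' precision of the stored numbers.
#'
#' @param m an `aligned_matrix`.
#' @param path output path for the intensity table.
#' @export
write_aligned_matrix <- function(m, path) {
  df <- data.frame(sample_id = m$sample_ids,
                   format(m$X, digits = 15, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("sample_id", format(m$mz, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(sample_id = m$sample_ids, class = m$labels,
                     temperature = m$temperature)
  utils::write.table(side, paste0(path, ".labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aligned_matrix
#' @export
read_aligned_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  side <- utils::read.delim(paste0(path, ".labels.tsv"))
  X <- as.matrix(df[, -1, drop = FALSE])
  mz <- as.numeric(names(df)[-1])
  rownames(X) <- df$sample_id
  colnames(X) <- sprintf("%.4f", mz)
  structure(list(mz = mz, X = X, sample_ids = df$sample_id,
                 labels = side$class, temperature = side$temperature,
                 scaling_state = "raw", scaling_params = list()),
            class = "aligned_matrix")
}
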