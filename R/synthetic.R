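# ---- class / config constructors ------------------------------------------

#' Describe one sample class for the synthetic spectrum generator
#'
#' A class is a named group of samples sharing a mean spectrum: a common
#' "backbone" peak set (referenced by id, so several classes can share one)
#' plus class-specific marker peaks. Within-class variability is controlled
#' by `dispersion`, a multiplicative factor on every peak's intensity
#' standard deviation.
#'
#' @param name class label (unique within a config).
#' @param n_samples number of samples to generate for this class.
#' @param marker_peaks data frame with columns `mz` (Da), `mean_intensity`
#'   and `sd_intensity` (counts); may have zero rows.
#' @param backbone_id id of a shared peak set in the config, or `NA` for
#'   classes with marker peaks only.
#' @param dispersion multiplicative within-class spread factor (>= 0).
#'   Larger values give more heterogeneous spectra.
#' @param mz_jitter_sd standard deviation (Da) of the per-sample mass
#'   perturbation applied to every peak position.
#' @return an object of class `class_spec`.
#' @export
class_spec <- function(name, n_samples, marker_peaks = empty_peak_table(),
                       backbone_id = NA_character_, dispersion = 1,
                       mz_jitter_sd = 0.002) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("n_samples must be >= 1 for class '", name, "'")
  marker_peaks <- as.data.frame(marker_peaks)
  req <- c("mz", "mean_intensity", "sd_intensity")
  if (!all(req %in% names(marker_peaks)))
    stop("marker_peaks needs columns mz, mean_intensity, sd_intensity")
  if (nrow(marker_peaks)) {
    if (any(marker_peaks$mz <= 0)) stop("marker m/z values must be positive")
    if (anyDuplicated(marker_peaks$mz)) stop("marker m/z values must be unique")
    if (any(marker_peaks$mean_intensity < 0) || any(marker_peaks$sd_intensity < 0))
      stop("marker intensities must be nonnegative")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (mz_jitter_sd < 0) stop("mz_jitter_sd must be >= 0")
  structure(list(name = name, n_samples = n_samples,
                 marker_peaks = marker_peaks, backbone_id = backbone_id,
                 dispersion = dispersion, mz_jitter_sd = mz_jitter_sd),
            class = "class_spec")
}

#' @rdname class_spec
#' @export
empty_peak_table <- function() {
  data.frame(mz = numeric(0), mean_intensity = numeric(0),
             sd_intensity = numeric(0))
}

peak_table <- function(mz, mean_intensity, sd_intensity) {
  data.frame(mz = mz, mean_intensity = mean_intensity,
             sd_intensity = sd_intensity)
}

#' Assemble a synthetic-dataset configuration
#'
#' @param classes list of [class_spec()] objects with unique names.
#' @param shared_backbones named list mapping backbone ids to peak tables
#'   (`mz`, `mean_intensity`, `sd_intensity`).
#' @param mz_range acquisition window in Da; peaks outside it are rejected.
#' @param baseline_noise_sd standard deviation (counts) of additive baseline
#'   noise applied to every generated peak intensity.
#' @param temperature_levels data frame with columns `temperature` (deg C),
#'   `n_samples` (samples acquired at that level), `separation` and `spread`
#'   (multipliers applied at that level to the class-specific peak means and
#'   to all intensity standard deviations of temperature-sensitive classes).
#' @param seed default seed attached to the configuration.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(classes, shared_backbones = list(),
                             mz_range = c(50, 800), baseline_noise_sd = 4,
                             temperature_levels = NULL, seed = 1L) {
  stopifnot(is.list(classes), length(classes) >= 1L)
  if (!all(vapply(classes, inherits, logical(1), "class_spec")))
    stop("classes must be a list of class_spec objects")
  nm <- vapply(classes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("class names must be unique")
  names(classes) <- nm
  stopifnot(length(mz_range) == 2L, mz_range[1] > 0, mz_range[2] > mz_range[1])
  for (cl in classes) {
    bid <- cl$backbone_id
    if (!is.na(bid) && is.null(shared_backbones[[bid]]))
      stop("unknown backbone_id '", bid, "' in class '", cl$name, "'")
    all_mz <- c(cl$marker_peaks$mz,
                if (!is.na(bid)) shared_backbones[[bid]]$mz)
    if (length(all_mz) == 0L)
      stop("class '", cl$name, "' has no peaks at all")
    if (any(all_mz < mz_range[1] | all_mz > mz_range[2]))
      stop("class '", cl$name, "' has peaks outside mz_range")
  }
  if (!is.null(temperature_levels)) {
    req <- c("temperature", "n_samples", "separation", "spread")
    if (!all(req %in% names(temperature_levels)))
      stop("temperature_levels needs columns ", paste(req, collapse = ", "))
    if (any(temperature_levels$n_samples < length(classes)))
      stop("each temperature level needs at least one sample per class")
  }
  structure(list(classes = classes, shared_backbones = shared_backbones,
                 mz_range = mz_range, baseline_noise_sd = baseline_noise_sd,
                 temperature_levels = temperature_levels,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic lipid-like backbone shared by the parchment-related classes:
# peak positions and mean intensities are frozen (fixed internal seed), so
# repeated config construction is a pure function.
.backbone_lipid <- function() {
  withr::with_seed(271828L, {
    mz <- sort(round(stats::runif(60, 55, 790), 3))
    mean_int <- round(exp(stats::rnorm(60, log(300), 0.8)))
  })
  peak_table(mz, pmax(mean_int, 20), pmax(0.25 * pmax(mean_int, 20), 5))
}

.backbone_glycerol_matrix <- function() {
  withr::with_seed(314159L, {
    mz <- sort(round(stats::runif(12, 60, 400), 3))
    mean_int <- round(exp(stats::rnorm(12, log(120), 0.6)))
  })
  peak_table(mz, pmax(mean_int, 15), pmax(0.25 * pmax(mean_int, 15), 4))
}

# Marker ions. Glycerol: protonated molecule, water adduct and protonated
# dimer. Castor oil: ricinoleic-acid-related ions. Untreated parchment:
# collagen-derived ions. Values are emulation targets, not assignments.
.markers_glycerol <- function(scale = 1) {
  peak_table(c(93.049, 110.058, 185.063),
             scale * c(900, 350, 650), scale * c(160, 70, 120))
}
.markers_castor <- function(scale = 1) {
  peak_table(c(299.259, 317.270, 617.512),
             scale * c(140, 110, 80), scale * c(35, 28, 20))
}
.markers_parchment <- function() {
  peak_table(c(244.166, 340.200, 528.300), c(160, 120, 90), c(40, 30, 24))
}

#' Default configuration emulating the treated-parchment study
#'
#' Five classes with the study's sample sizes (19 untreated parchment, 28
#' castor-oil parchment, 21 glycerol parchment, 16 castor-oil standard, 22
#' glycerol standard; 106 samples in total). Untreated parchment, both
#' castor-oil classes and glycerol-treated parchment share one lipid-like
#' backbone, which makes untreated and castor-oil-treated parchment nearly
#' indistinguishable by eye; glycerol classes carry marker ions at m/z
#' 93.049, 110.058 and 185.063 and have markedly lower within-class
#' dispersion than the parchment/castor classes. Two calls return identical
#' configurations.
#'
#' @return a [synthetic_config()].
#' @export
default_parchment_config <- function() {
  lipid <- .backbone_lipid()
  classes <- list(
    class_spec("parchment_untreated", 19, .markers_parchment(),
               "lipid", dispersion = 1.4),
    class_spec("parchment_castor", 28,
               rbind(.markers_parchment(), .markers_castor()),
               "lipid", dispersion = 1.4),
    class_spec("parchment_glycerol", 21,
               rbind(.markers_parchment(), .markers_glycerol()),
               "lipid", dispersion = 0.5),
    class_spec("castor_standard", 16, .markers_castor(scale = 3),
               "lipid", dispersion = 1.2),
    class_spec("glycerol_standard", 22, .markers_glycerol(scale = 1.6),
               "glycerol_matrix", dispersion = 0.4)
  )
  synthetic_config(
    classes,
    shared_backbones = list(lipid = lipid,
                            glycerol_matrix = .backbone_glycerol_matrix()),
    mz_range = c(50, 800), baseline_noise_sd = 4,
    temperature_levels = data.frame(
      temperature = c(23, 45, 90),
      n_samples   = c(69, 78, 85),
      separation  = c(1.0, 1.6, 2.6),
      spread      = c(1.0, 1.4, 2.0)),
    seed = 1L)
}

#' Restrict a configuration to the three parchment classes
#'
#' The discriminant-analysis stage of the study works on the 68-sample
#' subset: untreated, castor-oil-treated and glycerol-treated parchment.
#'
#' @param config a [synthetic_config()]; defaults to the study configuration.
#' @export
parchment_only_config <- function(config = default_parchment_config()) {
  keep <- c("parchment_untreated", "parchment_castor", "parchment_glycerol")
  missing <- setdiff(keep, names(config$classes))
  if (length(missing))
    stop("config lacks parchment classes: ", paste(missing, collapse = ", "))
  config$classes <- config$classes[keep]
  config
}

# ---- generation -----------------------------------------------------------

.draw_sample <- function(id, cls, config, temperature = NA_real_,
                         mean_mult = 1, sd_mult = 1) {
  backbone <- if (!is.na(cls$backbone_id))
    config$shared_backbones[[cls$backbone_id]] else empty_peak_table()
  pk <- rbind(backbone, cls$marker_peaks)
  means <- pk$mean_intensity * mean_mult
  sds <- pk$sd_intensity * cls$dispersion * sd_mult
  intensity <- pmax(0, stats::rnorm(nrow(pk), means, sds) +
                       stats::rnorm(nrow(pk), 0, config$baseline_noise_sd))
  mz <- pk$mz + stats::rnorm(nrow(pk), 0, cls$mz_jitter_sd)
  mz <- pmin(pmax(mz, config$mz_range[1]), config$mz_range[2])
  keep <- intensity > 0
  peak_spectrum(id, mz[keep], intensity[keep],
                class_label = cls$name, temperature = temperature)
}

#' Generate a labelled synthetic peak-list dataset
#'
#' Draws one centroided spectrum per sample from the class models in
#' `config`: every peak intensity is a zero-truncated normal draw around the
#' class mean plus baseline noise, and every peak position is jittered.
#' The same `(config, seed)` pair always yields a bit-identical dataset.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list of [peak_spectrum()] objects, one per sample, in class order.
#' @export
generate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (cls in config$classes) {
      for (i in seq_len(cls$n_samples)) {
        id <- sprintf("%s_%02d", cls$name, i)
        out[[id]] <- .draw_sample(id, cls, config)
      }
    }
    out
  })
}

# Largest-remainder allocation of n samples across classes proportional to
# their configured sizes; guarantees the exact per-level total.
.allocate_counts <- function(n, weights) {
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate the ion-source temperature study dataset
#'
#' Emulates the three-temperature design (defaults 69, 78 and 85 samples at
#' 23, 45 and 90 deg C over the three parchment classes, 232 in total).
#' Higher source temperature multiplies the class-specific peak means
#' (pushing class centroids apart) and the intensity spread of the
#' temperature-sensitive classes — untreated and castor-oil-treated
#' parchment — while glycerol-treated parchment is left untouched, so its
#' spectra are approximately temperature-invariant.
#'
#' @inheritParams generate_dataset
#' @param temperature_sensitive class names whose spectra respond to source
#'   temperature.
#' @return list of [peak_spectrum()] objects with temperature metadata.
#' @export
generate_temperature_dataset <- function(config = default_parchment_config(),
                                         seed = config$seed,
                                         temperature_sensitive =
                                           c("parchment_untreated",
                                             "parchment_castor")) {
  stopifnot(inherits(config, "synthetic_config"))
  levels <- config$temperature_levels
  if (is.null(levels) || nrow(levels) == 0L)
    stop("config has no temperature_levels")
  config <- parchment_only_config(config)
  unknown <- setdiff(temperature_sensitive, names(config$classes))
  if (length(unknown))
    stop("unknown temperature-sensitive class: ", paste(unknown, collapse = ", "))
  w <- vapply(config$classes, `[[`, integer(1), "n_samples")
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (li in seq_len(nrow(levels))) {
      lev <- levels[li, ]
      counts <- .allocate_counts(lev$n_samples, w)
      for (ci in seq_along(config$classes)) {
        cls <- config$classes[[ci]]
        sensitive <- cls$name %in% temperature_sensitive
        # separation multiplies only the class-specific markers: the shared
        # backbone stays put, so centroids move apart rather than rescale.
        cls_lev <- cls
        if (sensitive)
          cls_lev$marker_peaks$mean_intensity <-
            cls$marker_peaks$mean_intensity * lev$separation
        for (i in seq_len(counts[ci])) {
          id <- sprintf("%s_T%g_%02d", cls$name, lev$temperature, i)
          out[[id]] <- .draw_sample(
            id, cls_lev, config, temperature = lev$temperature,
            sd_mult = if (sensitive) lev$spread else 1)
        }
      }
    }
    out
  })
}

# ---- disk round-trip ------------------------------------------------------

#' Write and read peak-list datasets as delimited files
#'
#' Each spectrum becomes one two-column tab-separated file (`mz`,
#' `intensity`); a `manifest.tsv` records `sample_id`, `class`,
#' `temperature` and `file`. `read_peak_lists()` restores the dataset from a
#' manifest; the round trip is exact to the printed precision.
#'
#' @param spectra list of [peak_spectrum()] objects.
#' @param dir output directory (created if needed).
#' @param digits number of significant digits written.
#' @return `write_peak_lists()` the manifest path, invisibly;
#'   `read_peak_lists()` a list of [peak_spectrum()] objects.
#' @export
write_peak_lists <- function(spectra, dir, digits = 15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(spectra, function(sp) {
    f <- paste0(sp$sample_id, ".tsv")
    df <- data.frame(mz = format(sp$peaks$mz, digits = digits, trim = TRUE),
                     intensity = format(sp$peaks$intensity, digits = digits,
                                        trim = TRUE))
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    data.frame(sample_id = sp$sample_id, class = sp$class_label,
               temperature = sp$temperature, file = f)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mf)
}

#' @rdname write_peak_lists
#' @param manifest path to a manifest file written by `write_peak_lists()`.
#' @export
read_peak_lists <- function(manifest) {
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    df <- utils::read.delim(file.path(dir, man$file[i]))
    peak_spectrum(man$sample_id[i], df$mz, df$intensity,
                  class_label = man$class[i],
                  temperature = man$temperature[i])
  })
}
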