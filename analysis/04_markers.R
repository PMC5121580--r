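#!/usr/bin/env Rscript
# Stage 4 — canonical roots and m/z markers of the best model.
#
# Rebuilds the best model recorded by stage 3 from its stored seeds,
# computes the two canonical discriminant roots, back-projects the root
# coefficients through the PCA loadings to per-m/z weights, and flags the
# significant ones (|w| > 0.1 on root 1, > 0.05 on root 2). Writes the
# marker table under results/markers/.

library(dartchemo)

spectra <- read_peak_lists("results/data/main/manifest.tsv")
keep <- vapply(spectra, function(s)
  s$class_label %in% c("parchment_untreated", "parchment_castor",
                       "parchment_glycerol"), logical(1))
aligned <- align_spectra(spectra[keep], tolerance = 0.01)

records <- read.csv("results/validation/records.csv")
best <- pick_best_model(records)
fit <- refit_record(aligned, best, n_iterations = 100, n_pcs = 20)
sel <- fit$selected

canon <- canonical_analysis(fit$train_scores[, sel, drop = FALSE],
                            fit$train_labels)
print(canon)
cat("\nclass positions along the roots:\n")
print(interpret_roots(canon))

weights <- variable_weights(fit$pca$loadings[, sel, drop = FALSE],
                            canon$root_coefficients, mz = aligned$mz)
markers <- significant_weights(weights, method = "fixed",
                               thresholds = c(0.1, 0.05))
dir.create("results/markers", showWarnings = FALSE, recursive = TRUE)
write.csv(markers, "results/markers/marker_table.csv", row.names = FALSE)

root <- separating_root(canon, "parchment_glycerol")
ord <- order(-abs(markers[[paste0("weight_root", root)]]))
cat(sprintf("\nstrongest m/z signals on the glycerol-separating root (root %d):\n",
            root))
print(head(markers[ord, c("mz", paste0("weight_root", root),
                          paste0("flag_root", root))], 8), row.names = FALSE)
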