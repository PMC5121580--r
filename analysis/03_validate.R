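#!/usr/bin/env Rscript
# Stage 3 — repeated validation of the three-parchment-class model.
#
# Restricts to the 68 parchment samples, then runs the full protocol 25
# times (stratified 20% split, training-only scaling and PCA, forward
# stepwise PC selection by 100-iteration bootstrap CV) and summarises the
# per-repeat training / CV / test NER%. Writes records and summary under
# results/validation/.

library(dartchemo)

seed <- 20163L
spectra <- read_peak_lists("results/data/main/manifest.tsv")
keep <- vapply(spectra, function(s)
  s$class_label %in% c("parchment_untreated", "parchment_castor",
                       "parchment_glycerol"), logical(1))
aligned <- align_spectra(spectra[keep], tolerance = 0.01)
cat(sprintf("classification set: %d samples x %d m/z columns\n",
            nrow(aligned$X), ncol(aligned$X)))

records <- repeated_validation(aligned, n_repeats = 25, n_iterations = 100,
                               holdout_fraction = 0.2, n_pcs = 20,
                               seed = seed)
best <- pick_best_model(records)

dir.create("results/validation", showWarnings = FALSE, recursive = TRUE)
flat <- records
flat$selected_pcs <- vapply(flat$selected_pcs, paste, character(1),
                            collapse = ";")
write.csv(flat, "results/validation/records.csv", row.names = FALSE)
write.csv(summarize_records(records), "results/validation/summary.csv",
          row.names = FALSE)

cat("\nacross the 25 repeats:\n")
print(summarize_records(records))
cat(sprintf("\nbest model (repeat %d): PCs %s\n  NER train %.2f | cv %.2f | test %.2f (distance to ideal %.3f)\n",
            best$repeat_index, paste(best$selected_pcs[[1]], collapse = ", "),
            best$ner_train, best$ner_cv, best$ner_test,
            best$distance_to_ideal))
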