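#!/usr/bin/env Rscript
# Stage 1 — simulate the study datasets.
#
# Writes the 106-sample five-class dataset (untreated / castor-oil /
# glycerol parchment plus the two neat standards) and the 232-sample
# three-temperature dataset as per-sample peak lists with manifests under
# results/data/. Everything downstream reads only these files.

library(dartchemo)

seed <- 20160L
cfg <- default_parchment_config()

main <- generate_dataset(cfg, seed)
write_peak_lists(main, "results/data/main")
cat(sprintf("main dataset: %d spectra\n", length(main)))
print(table(vapply(main, `[[`, character(1), "class_label")))

temp <- generate_temperature_dataset(cfg, seed + 1L)
write_peak_lists(temp, "results/data/temperature")
cat(sprintf("\ntemperature dataset: %d spectra\n", length(temp)))
print(table(vapply(temp, `[[`, numeric(1), "temperature")))

# TIC-style sanity trace over the first few samples
tic <- total_ion_current(main[1:10])
cat("\nTIC of first 10 samples:\n")
print(tic)
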