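#!/usr/bin/env Rscript
# Amide-I band decomposition of a synthetic FTIR plate (4 sample
# carriers x 9 wells, signal-to-noise 100): preprocessing, per-carrier
# median spectra, Gaussian mixtures for k = 1..13 from 10 seeded random
# starts each, AICc-weighted model averaging of the component count,
# and width statistics of the ~1645 cm^-1 disorder-indicator band.

suppressPackageStartupMessages(library(nanospring))
dir.create("results", showWarnings = FALSE)
seed <- 1L

sim <- gen_amide1_spectra(seed = seed)   # disorder-like 3-band truth
carriers <- split(sim$spectra,
                  vapply(sim$spectra, `[[`, character(1), "carrier_id"))
res <- lapply(seq_along(carriers), function(i)
  analyze_amide1_carrier(carriers[[i]], k_max = 13, n_starts = 10,
                         seed = seed + i))

per_k <- do.call(rbind, lapply(seq_along(res), function(i) {
  tb <- res[[i]]$selection$table
  tb$carrier <- names(carriers)[i]
  tb
}))
write.table(per_k[, c("carrier", "k", "rss", "aicc", "weight")],
            "results/amide1_model_weights.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

comps <- do.call(rbind, lapply(seq_along(res), function(i) {
  cc <- res[[i]]$best_fit$components
  cc$carrier <- names(carriers)[i]
  cc
}))
write.table(round_df <- within(comps, {
  center_cm1 <- round(center_cm1, 2); fwhm_cm1 <- round(fwhm_cm1, 2)
  amplitude <- signif(amplitude, 4); area_fraction <- round(area_fraction, 4)
}), "results/amide1_components.tsv", sep = "\t",
  row.names = FALSE, quote = FALSE)

ks <- vapply(res, function(r) r$selection$weighted_mean_k, numeric(1))
ksd <- vapply(res, function(r) r$selection$weighted_sd_k, numeric(1))
width <- peak_width_analysis(lapply(res, `[[`, "best_fit"),
                             target_cm1 = 1645, window_cm1 = 10,
                             min_area_fraction = 0.01)

for (i in seq_along(ks))
  cat(sprintf("carrier %s: %0.2f +/- %0.2f spectral components\n",
              names(carriers)[i], ks[i], ksd[i]))
cat(sprintf("\nModel-averaged component count over carriers: %.2f\n", mean(ks)))
cat(sprintf("Width of the band nearest 1645 cm^-1: %.2f cm^-1 FWHM\n",
            width$mean_fwhm_cm1))
cat(sprintf("Welch t-test of 1645-band widths vs other bands: p = %.3g\n",
            width$p_value))
cat("\nA low component count together with a broad 1645 cm^-1 band is the\n")
cat("classic amide-I signature of a disordered (non-ordered) backbone.\n")
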