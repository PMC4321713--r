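#!/usr/bin/env Rscript
# Force-quench collapse kinetics: 20 stochastic collapse trajectories
# per peptide started from the stretched state (7 nm), first passage to
# the collapsed state (end-to-end distance <= 1.5 nm), cumulative event
# curves and the exponential lifetime of the extended state. The four
# effective potentials are calibrated (by exact mean-first-passage-time
# quadrature) to the lifetimes of Cnidoin, silk, the vWF domain linker
# and the methionine-free Cnidoin mutant.

suppressPackageStartupMessages(library(nanospring))
dir.create("results", showWarnings = FALSE)
seed <- 1L

targets <- c(cnidoin = 5.7, silk = 3.7, vwf_linker = 10.5,
             cnidoin_no_met = 4.7)
rows <- list()
for (i in seq_along(targets)) {
  nm <- names(targets)[i]
  sim <- gen_collapse_trajectories(n_traj = 20, target_tau_ns = targets[[i]],
                                   threshold_nm = 1.5, seed = seed + i)
  fpt <- first_passage_times(sim$trajectories, threshold_nm = 1.5)
  fit <- fit_lifetime(fpt, n_boot = 1000, boot_seed = seed + 100 + i)
  grid <- seq(0, 10 * targets[[i]], length.out = 120)
  curve <- cumulative_events(fpt, grid[-1])
  write.table(round(curve, 4),
              sprintf("results/collapse_cumulative_%s.tsv", nm), sep = "\t",
              row.names = FALSE, quote = FALSE)
  rows[[nm]] <- data.frame(
    peptide = nm, target_tau_ns = targets[[i]],
    fitted_tau_ns = round(fit$tau_ns, 3),
    ci_low_ns = round(fit$tau_ci_ns[1], 3),
    ci_high_ns = round(fit$tau_ci_ns[2], 3),
    n_events = fit$n_events, n_censored = fit$n_censored)
  cat(sprintf("%-15s tau = %5.2f ns (95%% CI %.2f-%.2f), %d/%d collapsed\n",
              nm, fit$tau_ns, fit$tau_ci_ns[1], fit$tau_ci_ns[2],
              fit$n_events, fit$n_total))
}
tab <- do.call(rbind, rows)
write.table(tab, "results/collapse_lifetimes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("\nThe ordering silk < mutant < Cnidoin < vWF linker places Cnidoin's\n")
cat("collapse speed between the fast elastomeric silk peptides and the\n")
cat("slow non-elastomeric linker, at 20 trajectories per peptide the\n")
cat("confidence intervals span roughly +/- 40% of the lifetime.\n")

# PPII dihedral metric on a toy ensemble: stretched frames carry more
# extended-backbone (PPII) residues than relaxed frames
set.seed(seed)
wrap_deg <- function(a) {
  w <- ((a + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}
frames <- do.call(rbind, lapply(1:20, function(fr) {
  stretched <- fr > 10
  n <- 18
  ppii <- runif(n) < ifelse(stretched, 0.6, 0.3)
  data.frame(frame = fr, residue = 1:n,
             phi_deg = wrap_deg(ifelse(ppii, -75 + rnorm(n, 0, 8),
                                       -150 + rnorm(n, 0, 15))),
             psi_deg = wrap_deg(ifelse(ppii, 145 + rnorm(n, 0, 8),
                                       60 + rnorm(n, 0, 20))))
}))
pf <- ppii_fraction(frames)
pf$stretched <- pf$frame > 10
write.table(round(as.data.frame(pf), 4), "results/ppii_fractions.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("\nPPII fraction: %.2f (relaxed frames) vs %.2f (stretched frames)\n",
            mean(pf$ppii_fraction[!pf$stretched]),
            mean(pf$ppii_fraction[pf$stretched])))
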