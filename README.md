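# nanospring

Quantitative mechanics of elastomeric, intrinsically disordered structural
proteins — built around Cnidoin, the silk-like protein of the cnidarian
nematocyst wall, whose spring-like collapse is thought to power the
organelle's sub-microsecond discharge. The package implements, as one
tested R pipeline, the four quantitative arguments for an elastomer:

* **Worm-like chain (WLC) mechanics** — Marko–Siggia force–extension
  evaluation, inversion, and least-squares fitting:
  `F(x) = (kBT/Lp) · [1/(4(1−x/Lc)²) − 1/4 + x/Lc]`.
* **AFM single-molecule force spectroscopy** — trace parsing, baseline and
  contact-point correction, authentication of specific stretching events by
  the cohesin–dockerin double rupture (8 ± 2 nm apart in contour-length
  space), per-trace WLC fits and population histograms of `Lc` and `Lp`.
* **Umbrella-sampling elasticity** — WHAM reconstruction of the potential
  of mean force along the end-to-end distance (windows every 0.4 nm,
  500 kJ mol⁻¹ nm⁻² umbrellas), mean-force profiling, and WLC fits of the
  simulated repeat units.
* **Force-quench collapse kinetics** — first passage to the collapsed
  state (≤ 1.5 nm), cumulative event curves, exponential lifetime
  `N(t) = n·(1 − exp(−t/τ))` with parametric-bootstrap confidence
  intervals, and a polyproline-II dihedral fraction.
* **Amide-I FTIR decomposition** — vector normalisation, replicate
  medians, Gaussian mixtures for k = 1…13 with AICc weights
  `w_i ∝ exp(−ΔAICc_i/2)`, model-averaged component count, and width
  statistics of the ~1645 cm⁻¹ disorder band.
* **Sequence disorder metrics** — composition, Kyte–Doolittle/Uversky
  charge–hydropathy classification (boundary `R = 2.785·H − 1.151`), and
  `GXGQQ` motif scanning.

Seeded generators (`gen_fd_traces`, `gen_umbrella_samples`,
`gen_collapse_trajectories`, `gen_amide1_spectra`) emulate the instruments
and simulations and return machine-readable ground truth, so the whole
pipeline is testable offline. The methods vignette
(`vignettes/elastomer-pipeline.Rmd`) documents every model, default and
numerical choice.

## Worked example

Analyse a synthetic AFM cohort drawn at the study's conditions
(`Lc ~ N(94, 43) nm` truncated above 20 nm, `Lp = 0.37` nm, 5 pN noise):

```r
library(nanospring)

sim <- gen_fd_traces(500, lc_mean_nm = 94, lc_sd_nm = 43, lp_nm = 0.37,
                     noise_sd_pN = 5, specific_fraction = 0.8, seed = 1)
res <- analyze_afm_cohort(sim$traces, persistence_length_nm = 0.4,
                          expected_separation_nm = 8, tolerance_nm = 2)
res$summary
#> Population of 384 accepted traces (of 500): Lc = 98.8 +/- 38.6 nm,
#>   Lp = 0.360 +/- 0.036 nm
expected_contour_length(283, 0.32, 20)
#> [1] 110.56
```

Of 500 traces (20 % of which carry no specific double rupture), 384 are
accepted; the recovered population mean contour length (98.8 nm) matches
the generator truth for the accepted molecules (101.1 nm) and sits, as in
the experiment, somewhat below the 110.6 nm expected for the full
283-residue construct at 0.32 nm per residue plus a 20 nm linker. The
persistence length (0.360 nm) recovers the generating 0.37 nm.

The remaining stages are driven the same way; the numbered scripts under
`analysis/` run each one end to end and write their tables to `results/`:

```sh
Rscript analysis/01_sequence_disorder.R
Rscript analysis/02_afm_force_spectroscopy.R
Rscript analysis/03_umbrella_elasticity.R     # WHAM + repeat-unit Lp fits
Rscript analysis/04_collapse_kinetics.R       # lifetimes + PPII metric
Rscript analysis/05_amide1_spectroscopy.R     # AICc model averaging
Rscript analysis/06_full_pipeline.R           # orchestrated run
```

For example, `analysis/03_umbrella_elasticity.R` prints

```
repeat_unit_1: WHAM converged in 95117 iterations; fitted Lp = 0.882 nm (true 0.89 nm)
repeat_unit_2: WHAM converged in 95921 iterations; fitted Lp = 0.659 nm (true 0.66 nm)
```

— the two simulated repeat units are recovered as soft entropic springs
with sub-nanometre persistence lengths.

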