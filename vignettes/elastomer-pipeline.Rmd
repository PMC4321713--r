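---
title: "Quantifying elastomeric protein mechanics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying elastomeric protein mechanics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanospring)
```

## The scientific problem

Nematocysts -- the explosive stinging organelles of cnidarians -- discharge
on a sub-microsecond time scale, which requires their wall to store and
release elastic energy like a spring. The silk-like wall protein Cnidoin is
the candidate elastomer: a glycine/glutamine-rich repetitive protein
(repeat units such as `QMQGCGQQMPPMMSGCGG`, carrying the `GXGQQ` motif
shared with spider silk) flanked by cysteine-rich domains that crosslink it
into the minicollagen network. `nanospring` implements the quantitative
analyses by which such an elastomeric character is established:

1. **Sequence disorder metrics** -- composition, charge--hydropathy
   (Uversky) classification, elastic-motif scanning.
2. **Single-molecule AFM force spectroscopy** -- worm-like-chain (WLC)
   fits of retract traces authenticated by the cohesin--dockerin
   double-rupture fingerprint.
3. **Umbrella-sampling elasticity profiling** -- WHAM reconstruction of
   the potential of mean force (PMF) along the end-to-end distance and WLC
   fits of the derived mean forces.
4. **Force-quench collapse kinetics** -- first-passage analysis and
   exponential lifetime of the extended state, plus a polyproline-II
   (PPII) dihedral metric.
5. **Amide-I FTIR decomposition** -- Gaussian band fitting with
   AICc-weighted model averaging and width statistics of the ~1645
   cm^-1^ disorder indicator.

Because no instrument data are distributed with the package, a seeded
synthetic-data module emulates the AFM, the biased and force-quench
molecular-dynamics sampling, and the FTIR plate reader; every analysis
stage is tested against the generators' ground truth.

## The worm-like chain

All elasticity fits use the Marko--Siggia interpolation of the WLC
force--extension relation,

$$F(x) = \frac{k_B T}{L_p}\left[\frac{1}{4\,(1-x/L_c)^2} - \frac14 +
\frac{x}{L_c}\right],$$

with persistence length $L_p$ (nm), contour length $L_c$ (nm), and
$k_B = 0.0138065$ pN nm K^-1^ at a default $T = 300$ K. This is the
standard AFM convention for the 10--300 pN range probed here. The inverse
(`wlc_extension`) is solved by bisection on $[0, L_c(1-10^{-12})]$ to
$10^{-9} L_c$; the fit (`fit_wlc`) is unweighted least squares on force
(no per-point uncertainties exist for these data) via bounded
Levenberg--Marquardt, with standard errors from the local quadratic
approximation at the optimum. The back-of-envelope construct length is
`expected_contour_length(n, 0.32, linker)`: 0.32 nm of contour per
residue, with the PEG linker and anchoring domains absorbed into a fixed
linker length (and therefore into $L_c$ rather than modelled as a
separate elastic element).

## AFM trace analysis

`correct_baseline` subtracts the median force of the detached tail
segment (last 10 % of the trace; a tail with a systematic trend means the
molecule never detached and is rejected) and shifts the distance origin to
a *fitted* contact point: a three-parameter WLC (with distance offset) is
fitted to the segment up to the first rupture. Thresholding alone cannot
locate the contact point because an $L_p \approx 0.4$ nm chain rises by
only ~0.2 pN/nm at small extension, far below the 5 pN instrument noise
-- this is also why fitted persistence lengths scatter strongly (the
zero-force/zero-distance uncertainty), while contour lengths are robust.

Rupture peaks are local maxima of the median-smoothed force whose
**level shift** -- median force just before the peak minus median just
after the drop window -- exceeds both 15 % of the peak force and five
smoothed-noise standard deviations. A sustained shift separates a branch
change from a noise excursion that recovers; a purely relative drop
criterion either misses shallow first ruptures of long molecules or
accepts low-force noise bumps. Candidates are merged when they are
adjacent or sit at the same force level within the merge window (two real
ruptures in quick succession still differ in level).

The final two peaks are mapped to contour-length space by inverting the
WLC in $L_c$ at fixed $L_p = 0.4$ nm (the value conventionally assumed
for unfolded polypeptides); the trace is accepted as a specific
cohesin--dockerin stretching event iff their separation is within
$8 \pm 2$ nm. The 2 nm tolerance covers the transform jitter at 5 pN
noise. Points below 10 pN are excluded from the transform (the inversion
is ill-conditioned near zero force). Accepted traces are fitted from zero
extension to the first peak with both parameters free, and population
statistics use the uncorrected (population) standard deviation, matching
the "standard deviation of a histogram" convention.

The trace generator draws per-molecule contour lengths from a normal
(mean 94, sd 43 nm) truncated above 20 nm, applies white Gaussian force
noise only (distance noise is folded into contact-point uncertainty), and
builds the terminal double rupture so that the second bond sustains at
least the force transferred when the first breaks -- otherwise both bonds
would fail in the same instant and no double peak would exist. What it
does **not** emulate: baseline drift, multiple tethers, unfolding
intermediates, or the discarded-curve taxonomy of real campaigns; passing
recovery tests therefore demonstrates correctness of the analysis, not
instrument-grade robustness.

## WHAM and mean-force profiles

`wham` iterates the standard self-consistent equations on binned samples
(bin width 0.05 nm, below the $\sqrt{k_B T/k} \approx 0.071$ nm spread of
a 500 kJ mol^-1^ nm^-2^ window),

$$P_l = \frac{\sum_i n_{il}}{\sum_i N_i\, e^{(f_i - U_i(z_l))/k_BT}},
\qquad f_i = -k_B T \log \sum_l P_l\, e^{-U_i(z_l)/k_BT},$$

until the largest change in any window shift $f_i$ falls below $10^{-8}$
kJ/mol (up to $10^5$ iterations by default; the drivers allow more).
Windows are sorted internally, so results are bit-identical under input
permutation. Non-overlapping neighbours raise an error naming the gap.

Mean forces are PMF derivatives (the derivative route, not window-mean
constraint forces), converted at 1 kJ mol^-1^ nm^-1^ = 1.6606 pN, with
"resisting extension" positive. For reconstructed profiles the derivative
is a count-weighted local quadratic over ±0.15 nm -- plain central
differences on 0.05 nm bins amplify the per-bin statistical noise by
~10 pN. For analytic profiles plain central differences are used, which
keeps exact identities (a quadratic PMF of curvature 10 gives 16.606 pN
at 1 nm).

Two numerical caveats discovered while validating and worth knowing:

* At the study's window layout (spacing 0.4 nm, $k = 500$) the spacing is
  5.7 window-sd, so adjacent windows overlap only in their far tails. The
  relative shifts $f_i$ are then pinned by few samples and their errors
  random-walk along the window chain, tilting the stitched PMF. The
  effect shrinks as $1/\sqrt{n}$; the repeat-unit profiles are therefore
  sampled at 2×10^4^ samples/window (the MD study's frame counts were an
  order of magnitude larger still), while the quadratic-recovery check
  runs at 5×10^3^.
* WLC fits to mean-force profiles are restricted to the sampled support
  (`pmf_supported_range`): beyond the outermost windows' sample clouds
  the PMF is histogram-tail extrapolation, and including it biases
  $L_p$ by ~15 %. Repeat-unit fits hold $L_c$ fixed at the known
  18-mer contour length (~7.5 nm), as one does for simulated peptides of
  known sequence; both choices matter more than sampling noise.

The umbrella generator draws by inverse-CDF on a fine grid using a
trapezoid CDF -- a running-sum CDF shifts every sample half a grid step,
which WHAM converts into a systematic PMF tilt. An optional subsampling
stride is left to the caller; samples are treated as uncorrelated (the
generator produces i.i.d. draws; real MD time series would require
decorrelation first).

## Collapse kinetics

First passages to the collapsed state (end-to-end distance ≤ 1.5 nm) are
linearly interpolated between frames; trajectories that never cross are
censored at their final time. The lifetime is the least-squares fit of
$N(t) = n_{\rm tot}(1 - e^{-t/\tau})$ to the cumulative event curve with
the plateau constrained to the cohort size (a free-plateau variant is
available), matching how lifetimes are read off cumulative collapse
counts; maximum likelihood on the passage times would weight the data
differently. The 95 % CI is a seeded parametric bootstrap (1,000
resamples, percentile interval); at $n = 20$ its coverage measures
95 ± 2 % in the calibration test, and the estimator's small-sample bias
is below 10 % of $\tau$.

The generator is a 1-D overdamped Langevin walk on an effective
free-energy surface -- not a chain model, since the analysis consumes
only end-to-end distances. The surface has a harmonic extended basin
(minimum 6.3 nm) ending at a barrier (4.8 nm) and a steep downhill side
(15 kJ mol^-1^ nm^-1^); escape over the barrier, not transit, is
rate-limiting, which makes first-passage times near-exponential, as the
single-exponential fits assume. The diffusion coefficient is 2 nm^2^/ns,
the scale of end-to-end diffusion of short disordered peptides; the
barrier height is calibrated by exact mean-first-passage-time quadrature
(`collapse_mfpt`) so that the analytic lifetime equals the target (5.7 ns
for the Cnidoin unit; 3.7, 10.5 and 4.7 ns for the comparison peptides).
Drift mobility defaults to $D/k_BT$ but can be decoupled from the noise
for deterministic checks.

The PPII metric counts residues with $\phi \in [-100, -50]$,
$\psi \in [120, 180]$ degrees (covering the canonical PPII point
(-75, 145)); the window is configurable because no universal dihedral
definition of PPII exists.

## Amide-I decomposition

Preprocessing removes, per spectrum and over the 1600--1715 cm^-1^
region, the least-squares straight line (background and mean in one
orthogonal projection) and scales to unit Euclidean norm. Fitting the
baseline over the whole region rather than through the two boundary
samples was a deliberate design choice: the boundary samples are noisy,
and subtracting a line pinned to them injects a random linear component
carrying ~77σ² of residual structure into every spectrum, which a spare
Gaussian component absorbs and which systematically inflates the
AICc-selected component count. The projection form also makes
preprocessing exactly idempotent.

Mixtures of $k$ Gaussians (FWHM parameterisation; centre within the
region, FWHM in [2, 80] cm^-1^, amplitude ≥ 0) are fitted by bounded
least squares from 10 seeded random starts; start centres are drawn from
the spectrum's intensity-weighted distribution (uniform centres miss the
global optimum at moderate $k$ often enough that the monitored
"RSS non-increasing in k" property fails). For preprocessed (trend-free)
input the model is evaluated under the same linear projection, so model
and data are compared like for like without changing the parameter
count. Model averaging uses
$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2p + 2p(p+1)/(n-p-1)$ with
$p = 3k + 1$ (the +1 for the noise variance) and Akaike weights
$w_i \propto e^{-\Delta_i/2}$; the component count is reported as the
weighted mean ± weighted sd of $k$.

Width statistics drop components below 1 % of the band area, take per
replicate carrier the component nearest 1645 cm^-1^ (±10), and compare
its width against the pooled other widths by a two-sided Welch t-test.
Widths are reported both as FWHM and as Gaussian sd (FWHM/2.355), since
literature "width" values do not always state their convention. The
generator replicates a disorder-like three-band truth (1625/1645/1678
cm^-1^, the 1645 band 17.3 cm^-1^ wide) over 9 wells × 4 carriers at
signal-to-noise 100; nine wells are used per carrier even though plates
may hold more, matching the nine-fold replication the median is taken
over. Even at this noise level the weighted count fluctuates: a single
carrier occasionally averages near 4 because an extra Gaussian can absorb
smooth replicate-median artefacts, and only the across-carrier average is
a stable estimate -- which is exactly why the protocol replicates
carriers.

## Sequence metrics

Hydropathy uses the Kyte--Doolittle scale rescaled to $[0,1]$ via
$(h+4.5)/9$, averaged over 5-residue sliding windows (per-residue
averaging is available; with full-length sequences the two differ only in
edge weighting). Net charge is $|\#K + \#R - \#D - \#E|/L$ at neutral pH
(His neutral). The folded/disordered boundary is
$R = 2.785\,H - 1.151$; points on the boundary classify as ordered.
Motif scanning treats `X` as a wildcard and reports 1-based, possibly
overlapping, start positions. `X` residues are tolerated in input and
excluded from all metrics.

## Orchestration

`run_pipeline` executes the stages over synthetic data (or user files)
with one global seed, collects per-stage summaries plus provenance
(config hash, package version, seed) into a JSON report, and lets
independent stages continue past a failed one. Configs are plain R lists
or YAML files -- YAML because it is flat, diff-friendly, comment-capable
and has a mature R parser. The numbered scripts under `analysis/` are the
narrative drivers; `scripts/acceptance.R` recomputes the headline numbers
from scratch.

## Problem sizes and limitations

The shipped analyses use: 500 AFM traces (population recovery), 17
umbrella windows × 5×10^3^--2×10^4^ samples, 20 collapse trajectories per
peptide (the study's cohort size; at $n=20$ a fitted lifetime has ~22 %
relative sd, visible in the confidence intervals), 200 calibration
cohorts × 1,000 bootstrap resamples, and 4 FTIR carriers × 9 wells.

Beyond the generator idealisations already noted, the package does not
model extensible-WLC or composite (protein + linker spring) elasticity,
does not decorrelate MD time series, has no 2-D reaction coordinates or
MBAR, and draws no secondary-structure percentages from band areas --
the amide-I analysis supports an order/disorder statement only.
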