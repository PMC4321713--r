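# Seeded generators that emulate the study's instruments and simulations:
# the AFM force spectrometer, the biased (umbrella) and force-quench MD
# sampling, and the FTIR plate reader. Each call consumes a single RNG
# stream seeded explicitly and restores the caller's RNG state, and each
# generator returns machine-readable ground truth next to its data.

# truncated normal by rejection (simple, exact, adequate at these scales)
.rtruncnorm_min <- function(n, mean, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw > lower])
  }
  out[seq_len(n)]
}

#' Generate synthetic AFM retract traces
#'
#' Emulates single-molecule pulling of a disordered polypeptide through a
#' cohesin-dockerin anchor: each specific trace follows a WLC branch with
#' a per-trace contour length drawn from a truncated normal (> 20 nm),
#' ends in a terminal double rupture whose branches are separated by
#' `separation_nm` in contour length, and carries additive white Gaussian
#' force noise plus an optional constant force offset. Non-specific
#' traces (the remaining fraction) are single-rupture or pure-noise
#' curves in equal proportion. Ground truth is returned alongside.
#'
#' @param n_traces Number of traces.
#' @param lc_mean_nm,lc_sd_nm Contour-length population (normal,
#'   truncated above `lc_min_nm`). Defaults 94 and 43 nm.
#' @param lc_min_nm Truncation bound (default 20 nm).
#' @param lp_nm True persistence length (default 0.37 nm).
#' @param noise_sd_pN Force noise standard deviation (default 5 pN).
#' @param linker_nm Extra contour length added to every molecule
#'   (linker absorbed into Lc; default 0).
#' @param specific_fraction Fraction of traces carrying the specific
#'   double rupture (default 1).
#' @param separation_nm Contour-length separation of the double rupture
#'   (default 8 nm).
#' @param rupture_force_range_pN Uniform range for rupture forces
#'   (default 100-250 pN).
#' @param contact_nm Contact-point offset of the distance axis; scalar or
#'   range to draw from uniformly (default `c(2, 12)`).
#' @param baseline_offset_pN Constant force offset (default 0).
#' @param step_nm Distance sampling step (default 0.25 nm).
#' @param tail_nm Detached-baseline tail length past the final rupture
#'   (default 25 nm).
#' @param temperature_K Temperature in kelvin.
#' @param seed RNG seed; identical seeds give identical output.
#' @return List with `traces` (list of [fd_trace()]) and `truth`
#'   (data frame: `trace_id`, `specific`, `kind`, `lc_nm`, `lp_nm`,
#'   `contact_nm`, `rupture1_pN`, `rupture2_pN`).
#' @export
gen_fd_traces <- function(n_traces, lc_mean_nm = 94, lc_sd_nm = 43,
                          lc_min_nm = 20, lp_nm = 0.37, noise_sd_pN = 5,
                          linker_nm = 0, specific_fraction = 1,
                          separation_nm = 8,
                          rupture_force_range_pN = c(100, 250),
                          contact_nm = c(2, 12), baseline_offset_pN = 0,
                          step_nm = 0.25, tail_nm = 25,
                          temperature_K = 300, seed = 1L) {
  if (specific_fraction < 0 || specific_fraction > 1)
    stop("'specific_fraction' must lie in [0, 1]", call. = FALSE)
  if (noise_sd_pN < 0 || lc_sd_nm < 0 || linker_nm < 0)
    stop("scales must be non-negative", call. = FALSE)
  .assert_scalar_pos(lp_nm, "lp_nm")
  with_seed(seed, {
    truth <- vector("list", n_traces)
    traces <- vector("list", n_traces)
    for (i in seq_len(n_traces)) {
      id <- sprintf("trace_%04d", i)
      lc <- .rtruncnorm_min(1, lc_mean_nm, lc_sd_nm, lc_min_nm) + linker_nm
      contact <- if (length(contact_nm) == 2L)
        stats::runif(1, contact_nm[1], contact_nm[2]) else contact_nm
      specific <- stats::runif(1) < specific_fraction
      kind <- if (specific) "specific"
              else if (stats::runif(1) < 0.5) "single" else "noise"
      p1 <- wlc_params(lp_nm, lc, temperature_K)
      f1 <- stats::runif(1, rupture_force_range_pN[1], rupture_force_range_pN[2])
      x1 <- wlc_extension(p1, f1)
      if (kind == "specific") {
        p2 <- wlc_params(lp_nm, lc + separation_nm, temperature_K)
        # when the first bond breaks the load drops onto the longer
        # branch at its entry force; the second bond must sustain at
        # least that, else it would have ruptured in the same instant
        f_entry <- wlc_force(p2, x1)
        f2_lo <- max(rupture_force_range_pN[1], 1.05 * f_entry)
        f2 <- stats::runif(1, f2_lo, max(rupture_force_range_pN[2], f2_lo))
        x2 <- wlc_extension(p2, f2)
      } else { f2 <- NA_real_; x2 <- x1 }
      d_end <- contact + (if (kind == "noise") 60 else x2 + tail_nm)
      d <- seq(0, d_end, by = step_nm)
      x <- d - contact
      f <- numeric(length(d))
      if (kind != "noise") {
        on1 <- x > 0 & x <= x1
        f[on1] <- wlc_force(p1, x[on1])
        if (kind == "specific") {
          on2 <- x > x1 & x <= x2
          f[on2] <- wlc_force(p2, x[on2])
        }
      }
      f <- f + baseline_offset_pN + stats::rnorm(length(f), 0, noise_sd_pN)
      traces[[i]] <- fd_trace(id, d, f)
      truth[[i]] <- data.frame(
        trace_id = id, specific = (kind == "specific"), kind = kind,
        lc_nm = if (kind == "noise") NA_real_ else lc, lp_nm = lp_nm,
        contact_nm = contact,
        rupture1_pN = if (kind == "noise") NA_real_ else f1,
        rupture2_pN = f2)
    }
    list(traces = traces, truth = do.call(rbind, truth))
  })
}

#' Generate umbrella-sampling windows on a known PMF
#'
#' Draws reaction-coordinate samples from the normalised biased Boltzmann
#' density `p(z) ~ exp(-(U(z) + k/2 (z - c)^2) / kBT)` of each harmonic
#' window by inverse-CDF sampling on a fine grid, emulating the
#' umbrella-sampling layout used for the repeat-unit elasticity profiling
#' (windows every 0.4 nm between 0.4 and 7.0 nm, force constant 500
#' kJ mol^-1 nm^-2). The true PMF is returned alongside.
#'
#' @param pmf_fun Function `U(z)` in kJ/mol (vectorised).
#' @param window_centers_nm Bias centres (default `seq(0.4, 7, 0.4)`).
#' @param spring_kJ_mol_nm2 Umbrella force constant (default 500).
#' @param n_samples_per_window Samples per window; scalar or vector
#'   recycled over windows (asymmetric sampling times are represented as
#'   per-window sample counts).
#' @param temperature_K Temperature in kelvin.
#' @param grid_nm Fine grid for inverse-CDF sampling; default spans the
#'   window centres with a 1 nm margin at 4001 points.
#' @param seed RNG seed.
#' @return List with `windows` (list of [umbrella_window()]) and `truth`
#'   (data frame `z_nm`, `free_energy_kJ_mol`, minimum pinned to 0).
#' @export
gen_umbrella_samples <- function(pmf_fun,
                                 window_centers_nm = seq(0.4, 7, by = 0.4),
                                 spring_kJ_mol_nm2 = 500,
                                 n_samples_per_window = 5000,
                                 temperature_K = 300, grid_nm = NULL,
                                 seed = 1L) {
  stopifnot(is.function(pmf_fun))
  .assert_scalar_pos(spring_kJ_mol_nm2, "spring_kJ_mol_nm2")
  kBT <- .kB_kJ_mol * temperature_K
  if (is.null(grid_nm))
    grid_nm <- seq(min(window_centers_nm) - 1, max(window_centers_nm) + 1,
                   length.out = 4001L)
  U <- pmf_fun(grid_nm)
  ns <- rep_len(n_samples_per_window, length(window_centers_nm))
  with_seed(seed, {
    windows <- lapply(seq_along(window_centers_nm), function(i) {
      c0 <- window_centers_nm[i]
      Ub <- U + 0.5 * spring_kJ_mol_nm2 * (grid_nm - c0)^2
      if (!any(is.finite(Ub)))
        stop("biased density numerically zero across the grid", call. = FALSE)
      w <- exp(-(Ub - min(Ub, na.rm = TRUE)) / kBT)
      w[!is.finite(w)] <- 0
      if (!any(w > 1e-300))
        stop("biased density numerically zero across the grid", call. = FALSE)
      # trapezoid CDF: midpoint-exact, avoids the half-step shift a
      # running sum would imprint on every sample
      ng <- length(grid_nm)
      cdf <- c(0, cumsum((w[-1] + w[-ng]) / 2 * diff(grid_nm)))
      cdf <- cdf / cdf[ng]
      u <- stats::runif(ns[i])
      samples <- stats::approx(cdf, grid_nm, xout = u, ties = "ordered",
                               yleft = grid_nm[1],
                               yright = grid_nm[ng])$y
      umbrella_window(c0, spring_kJ_mol_nm2, samples)
    })
    list(windows = windows,
         truth = data.frame(z_nm = grid_nm,
                            free_energy_kJ_mol = U - min(U)))
  })
}

#' Effective collapse potential with a metastable extended state
#'
#' One-dimensional effective free-energy surface along the end-to-end
#' distance used to emulate force-quench collapse: a harmonic basin
#' around the extended state ending at a barrier top, from which the
#' chain slides downhill into the collapsed state. Escape over the
#' barrier makes the first-passage times of the extended state
#' near-exponential.
#'
#' @param barrier_kJ_mol Barrier height at `z_barrier_nm` (kJ/mol).
#' @param z_extended_nm Extended-basin minimum (default 6.3 nm).
#' @param z_barrier_nm Barrier position (default 4.8 nm).
#' @param downhill_slope_kJ_mol_nm Slope of the collapse side (default 15).
#' @return List with vectorised functions `U(z)` and `dU(z)` (kJ/mol and
#'   kJ/mol/nm) plus the shape parameters.
#' @export
collapse_potential <- function(barrier_kJ_mol, z_extended_nm = 6.3,
                               z_barrier_nm = 4.8,
                               downhill_slope_kJ_mol_nm = 15) {
  .assert_scalar_pos(barrier_kJ_mol, "barrier_kJ_mol")
  ke <- 2 * barrier_kJ_mol / (z_extended_nm - z_barrier_nm)^2
  U <- function(z) ifelse(z >= z_barrier_nm,
                          0.5 * ke * (z - z_extended_nm)^2,
                          barrier_kJ_mol -
                            downhill_slope_kJ_mol_nm * (z_barrier_nm - z))
  dU <- function(z) ifelse(z >= z_barrier_nm,
                           ke * (z - z_extended_nm),
                           downhill_slope_kJ_mol_nm)
  list(U = U, dU = dU, barrier_kJ_mol = barrier_kJ_mol,
       z_extended_nm = z_extended_nm, z_barrier_nm = z_barrier_nm,
       spring_kJ_mol_nm2 = ke,
       downhill_slope_kJ_mol_nm = downhill_slope_kJ_mol_nm)
}

#' Analytic mean first-passage time of an overdamped walker
#'
#' Double-integral expression for the mean first-passage time from
#' `z_start` down to an absorbing threshold, with a reflecting boundary
#' at the maximal extension:
#' `MFPT = 1/D int_a^{z0} e^{U(y)/kBT} int_y^{B} e^{-U(z)/kBT} dz dy`,
#' evaluated by trapezoidal quadrature on a fine grid. Used to calibrate
#' the collapse generator and as an independent check on its output.
#'
#' @param potential A [collapse_potential()]-style list with `U`.
#' @param diffusion_nm2_ns Diffusion coefficient (nm^2/ns).
#' @param z_start_nm Starting extension.
#' @param threshold_nm Absorbing (collapsed-state) threshold.
#' @param z_max_nm Reflecting boundary (maximal chain extension).
#' @param temperature_K Temperature in kelvin.
#' @param n_grid Quadrature resolution.
#' @return Mean first-passage time in ns.
#' @export
collapse_mfpt <- function(potential, diffusion_nm2_ns, z_start_nm = 7,
                          threshold_nm = 1.5, z_max_nm = 7.5,
                          temperature_K = 300, n_grid = 4001L) {
  kBT <- .kB_kJ_mol * temperature_K
  z <- seq(threshold_nm, z_max_nm, length.out = n_grid)
  dz <- z[2] - z[1]
  u <- potential$U(z) / kBT
  u <- u - min(u)
  em <- exp(-u)
  # inner integral from y to the reflecting boundary
  inner <- rev(cumsum(rev(em))) * dz - 0.5 * dz * (em + em[n_grid])
  ep <- exp(u)
  integrand <- ep * inner
  sel <- z <= z_start_nm
  zi <- z[sel]
  fi <- integrand[sel]
  (sum(fi) - 0.5 * (fi[1] + fi[length(fi)])) * dz / diffusion_nm2_ns
}

#' Calibrate the collapse potential to a target lifetime
#'
#' Solves for the barrier height at which the analytic mean
#' first-passage time ([collapse_mfpt()]) equals the target lifetime.
#'
#' @param target_tau_ns Target mean lifetime of the extended state (ns).
#' @param diffusion_nm2_ns Diffusion coefficient (default 2 nm^2/ns, the
#'   scale of end-to-end diffusion of short disordered peptides).
#' @param z_start_nm,threshold_nm,z_max_nm Geometry as in
#'   [collapse_mfpt()].
#' @param temperature_K Temperature in kelvin.
#' @param ... Shape arguments forwarded to [collapse_potential()].
#' @return A [collapse_potential()] list whose MFPT matches the target.
#' @export
calibrate_collapse_potential <- function(target_tau_ns,
                                         diffusion_nm2_ns = 2,
                                         z_start_nm = 7, threshold_nm = 1.5,
                                         z_max_nm = 7.5,
                                         temperature_K = 300, ...) {
  .assert_scalar_pos(target_tau_ns, "target_tau_ns")
  obj <- function(h)
    collapse_mfpt(collapse_potential(h, ...), diffusion_nm2_ns, z_start_nm,
                  threshold_nm, z_max_nm, temperature_K) - target_tau_ns
  root <- stats::uniroot(obj, lower = 0.1, upper = 60, tol = 1e-10)
  collapse_potential(root$root, ...)
}

#' Generate force-quench collapse trajectories
#'
#' Overdamped Langevin dynamics of the effective end-to-end coordinate,
#' `z <- z + mobility * (-U'(z)) dt + sqrt(2 D dt) * xi`, started from
#' the stretched state, with a reflecting boundary at the maximal
#' extension and absorption at the collapsed-state threshold. By default
#' the potential is calibrated so the analytic mean first-passage time
#' equals `target_tau_ns`.
#'
#' @param n_traj Number of trajectories (default 20).
#' @param z_start_nm Starting extension (default 7 nm; must exceed the
#'   threshold).
#' @param potential Optional [collapse_potential()]; default calibrated
#'   to `target_tau_ns`.
#' @param target_tau_ns Target extended-state lifetime used when
#'   `potential` is `NULL` (default 5.7 ns).
#' @param diffusion_nm2_ns Diffusion coefficient of the noise
#'   (default 2).
#' @param mobility_nm2_kJ_mol_ns Drift mobility; defaults to
#'   `diffusion / kBT` (fluctuation-dissipation). Passing it explicitly
#'   decouples drift from noise (e.g. a noise-free deterministic run
#'   with `diffusion_nm2_ns = 0`).
#' @param dt_ns Integration step (default 1e-3 ns); rejected if too
#'   large for the potential stiffness.
#' @param t_max_ns Maximum simulated time; default `10 * target_tau_ns`
#'   (or 50 ns with a user potential).
#' @param threshold_nm Collapsed-state threshold (default 1.5 nm).
#' @param z_max_nm Reflecting boundary (default 7.5 nm).
#' @param record_dt_ns Recording interval (default 0.01 ns).
#' @param seed RNG seed.
#' @return List with `trajectories` (list of [end_to_end_trajectory()]),
#'   `truth` (data frame `trajectory_id`, `passage_time_ns`, `censored`
#'   from the un-recorded full-resolution dynamics), and `potential`.
#' @export
gen_collapse_trajectories <- function(n_traj = 20L, z_start_nm = 7,
                                      potential = NULL, target_tau_ns = 5.7,
                                      diffusion_nm2_ns = 2,
                                      mobility_nm2_kJ_mol_ns = NULL,
                                      dt_ns = 1e-3, t_max_ns = NULL,
                                      threshold_nm = 1.5, z_max_nm = 7.5,
                                      record_dt_ns = 0.01, seed = 1L) {
  if (z_start_nm <= threshold_nm)
    stop("'z_start_nm' must lie above the collapse threshold", call. = FALSE)
  if (diffusion_nm2_ns < 0) stop("diffusion must be >= 0", call. = FALSE)
  kBT <- .kB_kJ_mol * 300
  if (is.null(potential)) {
    potential <- calibrate_collapse_potential(target_tau_ns,
                                              diffusion_nm2_ns,
                                              z_start_nm, threshold_nm,
                                              z_max_nm)
    if (is.null(t_max_ns)) t_max_ns <- 10 * target_tau_ns
  }
  if (is.null(t_max_ns)) t_max_ns <- 50
  mob <- mobility_nm2_kJ_mol_ns %||% (diffusion_nm2_ns / kBT)
  # stability: the drift update must not overshoot. Curvature is taken as
  # an upper quantile of the numerical |U''| so an isolated kink in the
  # potential (bounded force jump) does not masquerade as stiffness.
  zz <- seq(threshold_nm, z_max_nm, length.out = 2001L)
  dU_grid <- potential$dU(zz)
  curv <- stats::quantile(abs(diff(dU_grid) / diff(zz)), 0.95, names = FALSE)
  step_nm <- mob * max(abs(dU_grid)) * dt_ns
  if ((is.finite(curv) && mob * curv * dt_ns > 0.25) || step_nm > 0.1)
    stop("'dt_ns' too large for the potential stiffness", call. = FALSE)

  n_steps <- ceiling(t_max_ns / dt_ns)
  stride <- max(1L, round(record_dt_ns / dt_ns))
  n_rec <- n_steps %/% stride + 1L
  with_seed(seed, {
    z <- rep(z_start_nm, n_traj)
    alive <- rep(TRUE, n_traj)
    passage <- rep(NA_real_, n_traj)
    rec <- matrix(NA_real_, nrow = n_rec, ncol = n_traj)
    rec[1, ] <- z
    sqn <- sqrt(2 * diffusion_nm2_ns * dt_ns)
    for (s in seq_len(n_steps)) {
      if (any(alive)) {
        ia <- which(alive)
        zi <- z[ia] - mob * potential$dU(z[ia]) * dt_ns
        if (sqn > 0) zi <- zi + sqn * stats::rnorm(length(ia))
        over <- zi > z_max_nm
        zi[over] <- 2 * z_max_nm - zi[over]
        zi[zi < 0] <- -zi[zi < 0]
        z[ia] <- zi
        hit <- ia[zi <= threshold_nm]
        passage[hit] <- s * dt_ns
        alive[hit] <- FALSE
      }
      if (s %% stride == 0L) rec[s %/% stride + 1L, ] <- z
    }
    t_rec <- (0:(n_rec - 1L)) * stride * dt_ns
    trajectories <- lapply(seq_len(n_traj), function(j) {
      zj <- rec[, j]
      last <- if (is.na(passage[j])) n_rec
              else min(n_rec, which(zj <= threshold_nm)[1], na.rm = TRUE)
      if (is.na(last) || !is.finite(last)) last <- n_rec
      end_to_end_trajectory(t_rec[1:last], pmax(zj[1:last], 0),
                            sprintf("traj_%03d", j))
    })
    list(trajectories = trajectories,
         truth = data.frame(trajectory_id = sprintf("traj_%03d", seq_len(n_traj)),
                            passage_time_ns = ifelse(is.na(passage),
                                                     t_max_ns, passage),
                            censored = is.na(passage)),
         potential = potential)
  })
}

#' Generate a synthetic amide-I plate
#'
#' Multi-well replicate spectra on a 1 cm^-1 grid: a sum of Gaussian
#' components plus a linear baseline and white Gaussian noise,
#' replicated over wells and sample carriers the way dried protein films
#' are measured on silicon 96-well carriers.
#'
#' @param components Data frame with columns `center_cm1`, `fwhm_cm1`,
#'   `area` (relative band areas). Default: a three-band disordered
#'   amide-I profile with a dominant broad component at 1645 cm^-1
#'   of 17.3 cm^-1 width.
#' @param baseline_offset,baseline_slope Linear baseline parameters
#'   (absorbance units and per cm^-1).
#' @param noise_sd Noise standard deviation; default `peak / 100`
#'   (signal-to-noise 100).
#' @param n_wells Wells per carrier (default 9).
#' @param n_carriers Sample carriers (default 4).
#' @param region Wavenumber region, default `c(1600, 1715)`.
#' @param step_cm1 Grid step (default 1).
#' @param seed RNG seed.
#' @return List with `plate` (long data frame `carrier_id`, `well_id`,
#'   `wavenumber_cm1`, `absorbance`), `spectra` (list of
#'   [ir_spectrum()]), and `truth` (the component table with
#'   amplitudes).
#' @export
gen_amide1_spectra <- function(components = NULL, baseline_offset = 0.05,
                               baseline_slope = 2e-4, noise_sd = NULL,
                               n_wells = 9L, n_carriers = 4L,
                               region = c(1600, 1715), step_cm1 = 1,
                               seed = 1L) {
  if (is.null(components))
    components <- data.frame(center_cm1 = c(1625, 1645, 1678),
                             fwhm_cm1 = c(12, 17.3, 12),
                             area = c(0.25, 0.5, 0.25))
  stopifnot(all(c("center_cm1", "fwhm_cm1", "area") %in% names(components)))
  if (any(components$center_cm1 < region[1] |
          components$center_cm1 > region[2]))
    stop("component centres must lie within the region", call. = FALSE)
  x <- seq(region[1], region[2], by = step_cm1)
  amp <- components$area /
    (components$fwhm_cm1 * sqrt(pi / (4 * log(2))))
  clean <- numeric(length(x))
  for (j in seq_len(nrow(components)))
    clean <- clean + .gauss(x, components$center_cm1[j],
                            components$fwhm_cm1[j], amp[j])
  if (is.null(noise_sd)) noise_sd <- max(clean) / 100
  base <- baseline_offset + baseline_slope * (x - region[1])
  with_seed(seed, {
    rows <- list()
    spectra <- list()
    for (ci in seq_len(n_carriers)) {
      for (wi in seq_len(n_wells)) {
        a <- clean + base + stats::rnorm(length(x), 0, noise_sd)
        sp <- ir_spectrum(x, a, well_id = sprintf("W%02d", wi),
                          carrier_id = sprintf("C%d", ci))
        spectra[[length(spectra) + 1L]] <- sp
        rows[[length(rows) + 1L]] <- data.frame(
          carrier_id = sp$carrier_id, well_id = sp$well_id,
          wavenumber_cm1 = x, absorbance = a)
      }
    }
    truth <- components
    truth$amplitude <- amp
    list(plate = do.call(rbind, rows), spectra = spectra, truth = truth)
  })
}
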