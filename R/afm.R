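#' Construct a force-distance trace
#'
#' Container for one AFM retract curve: tip-sample distance (nm, monotone
#' non-decreasing) against measured force (pN), plus optional instrument
#' metadata.
#'
#' @param trace_id Identifier string.
#' @param distance_nm Numeric vector, monotone non-decreasing.
#' @param force_pN Numeric vector of the same length.
#' @param pulling_speed_nm_s,spring_constant_N_m Optional scalars.
#' @return An object of class `fd_trace`.
#' @export
fd_trace <- function(trace_id, distance_nm, force_pN,
                     pulling_speed_nm_s = NULL, spring_constant_N_m = NULL) {
  distance_nm <- as.numeric(distance_nm)
  force_pN <- as.numeric(force_pN)
  if (length(distance_nm) != length(force_pN))
    stop("distance and force must have equal length", call. = FALSE)
  if (any(!is.finite(distance_nm)) || any(!is.finite(force_pN)))
    stop("trace values must be finite", call. = FALSE)
  if (is.unsorted(distance_nm))
    stop("distance must be monotone non-decreasing", call. = FALSE)
  structure(list(trace_id = as.character(trace_id),
                 distance_nm = distance_nm, force_pN = force_pN,
                 pulling_speed_nm_s = pulling_speed_nm_s,
                 spring_constant_N_m = spring_constant_N_m),
            class = "fd_trace")
}

#' @export
print.fd_trace <- function(x, ...) {
  cat(sprintf("Force-distance trace '%s': %d points, %.1f-%.1f nm\n",
              x$trace_id, length(x$distance_nm), min(x$distance_nm),
              max(x$distance_nm)))
  invisible(x)
}

#' Read force-distance traces from file or directory
#'
#' Each trace is a two-column numeric table (`distance_nm`, `force_pN`),
#' tab/comma/space separated. Lines starting with `#` are metadata of the
#' form `#key value`; recognised keys are `trace_id`,
#' `pulling_speed_nm_s` and `spring_constant_N_m`. The trace id defaults
#' to the file name without extension.
#'
#' @param source Path to one trace file, or a directory of
#'   `.tsv`/`.csv`/`.txt` files.
#' @return A list of [fd_trace()] objects.
#' @export
read_traces <- function(source) {
  if (dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.(tsv|csv|txt)$",
                             full.names = TRUE))
    if (!length(files))
      stop("no trace files (*.tsv, *.csv, *.txt) found in ", source,
           call. = FALSE)
  } else if (file.exists(source)) {
    files <- source
  } else stop("no such file or directory: ", source, call. = FALSE)
  lapply(files, .read_trace_file)
}

.read_trace_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    parts <- strsplit(sub("^\\s*#\\s*", "", ln), "\\s+")[[1]]
    if (length(parts) >= 2) meta[[parts[1]]] <- parts[2]
  }
  data_idx <- which(!is_meta & nzchar(trimws(lines)))
  if (!length(data_idx))
    stop("parse error in ", path, ": no data rows", call. = FALSE)
  fields <- strsplit(trimws(lines[data_idx]), "[,\t ]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- data_idx[which(nf != 2L)[1]]
    stop(sprintf("parse error in %s, line %d: expected 2 columns, found %d",
                 path, bad, nf[which(nf != 2L)[1]]), call. = FALSE)
  }
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(2)))
  if (any(!is.finite(vals))) {
    bad <- data_idx[which(colSums(!is.finite(vals)) > 0)[1]]
    stop(sprintf("parse error in %s, line %d: non-numeric value", path, bad),
         call. = FALSE)
  }
  num <- function(key) if (is.null(meta[[key]])) NULL else as.numeric(meta[[key]])
  fd_trace(trace_id = meta$trace_id %||%
             sub("\\.[^.]*$", "", basename(path)),
           distance_nm = vals[1, ], force_pN = vals[2, ],
           pulling_speed_nm_s = num("pulling_speed_nm_s"),
           spring_constant_N_m = num("spring_constant_N_m"))
}

#' Write traces to a directory
#'
#' Inverse of [read_traces()]: one two-column TSV per trace with `#key
#' value` metadata headers.
#'
#' @param traces List of [fd_trace()] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_traces <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(traces, function(tr) {
    path <- file.path(dir, paste0(tr$trace_id, ".tsv"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#trace_id %s", tr$trace_id), con)
    if (!is.null(tr$pulling_speed_nm_s))
      writeLines(sprintf("#pulling_speed_nm_s %g", tr$pulling_speed_nm_s), con)
    if (!is.null(tr$spring_constant_N_m))
      writeLines(sprintf("#spring_constant_N_m %g", tr$spring_constant_N_m), con)
    writeLines(sprintf("%.6f\t%.6f", tr$distance_nm, tr$force_pN), con)
    path
  }, character(1))
  invisible(paths)
}

#' Baseline-correct a force-distance trace
#'
#' Removes the force offset (median of the detached tail segment) and
#' shifts the distance axis so the fitted contact point sits at zero. The
#' contact point is estimated by fitting a three-parameter WLC (Lp, Lc and
#' a distance offset) to the segment up to the global force maximum; when
#' no force signal rises above the baseline noise the distance axis is
#' left untouched. The input trace is not modified.
#'
#' Attributes `baseline_offset_pN`, `contact_shift_nm` and `noise_sd_pN`
#' on the returned trace record what was removed; downstream peak
#' detection uses the noise estimate.
#'
#' @param trace An [fd_trace()] with at least 50 points.
#' @param tail_fraction Fraction of the trace (from the far end) treated
#'   as the detached baseline segment (default 0.1).
#' @return A corrected [fd_trace()].
#' @export
correct_baseline <- function(trace, tail_fraction = 0.1) {
  stopifnot(inherits(trace, "fd_trace"))
  n <- length(trace$force_pN)
  if (n < 50L)
    stop("baseline correction needs at least 50 points", call. = FALSE)
  n_tail <- max(10L, ceiling(tail_fraction * n))
  tail_idx <- (n - n_tail + 1L):n
  tail_f <- trace$force_pN[tail_idx]
  tail_d <- trace$distance_nm[tail_idx]
  # A baseline segment must be trend-free: a detached tail is flat noise,
  # a still-attached molecule leaves a systematic rise.
  slope <- stats::cov(tail_d, tail_f) / stats::var(tail_d)
  resid <- tail_f - slope * (tail_d - mean(tail_d)) - mean(tail_f)
  r_mad <- stats::mad(resid)
  if (abs(slope) * diff(range(tail_d)) > 6 * r_mad + 1e-9)
    stop("no identifiable baseline segment at the trace tail", call. = FALSE)
  offset <- stats::median(tail_f)
  f <- trace$force_pN - offset
  noise <- stats::mad(tail_f)
  if (!is.finite(noise) || noise == 0) noise <- 1e-9

  d <- trace$distance_nm
  shift <- 0
  # the contact fit must stop before the first rupture: a single WLC
  # cannot span two contour-length branches
  peaks <- .find_rupture_peaks(f, max(5 * noise, 10), noise_sd = noise)
  seg_end <- if (length(peaks)) peaks[1] else which.max(f)
  sm <- stats::runmed(f, k = min(21L, 2L * (n %/% 2L) - 1L))
  above <- which(sm > max(3 * noise, 1e-6) & seq_len(n) <= seg_end)
  if (length(above) >= 10L && f[seg_end] > 5 * noise) {
    rough <- d[above[1]]
    fitseg <- seq_len(seg_end)
    shift <- .fit_contact_point(d[fitseg], f[fitseg], rough)
    step <- stats::median(diff(d))
    if (!is.finite(shift) || abs(shift) < 0.5 * step) shift <- 0
  }
  out <- fd_trace(trace$trace_id, d - shift, f,
                  trace$pulling_speed_nm_s, trace$spring_constant_N_m)
  attr(out, "baseline_offset_pN") <- offset
  attr(out, "contact_shift_nm") <- shift
  attr(out, "noise_sd_pN") <- noise
  out
}

# Fit force = WLC(distance - x0) with free (Lp, Lc, x0); several starting
# contact points guard against local minima. Returns the fitted x0.
.fit_contact_point <- function(d, f, rough, temperature_K = 300) {
  kBT <- .kB_pN_nm * temperature_K
  model <- function(par) {
    x <- pmax(d - par[3], 0)
    u <- pmin(x / par[2], 1 - 1e-9)
    (kBT / par[1]) * .ms_factor(u)
  }
  dmax <- max(d)
  best <- NULL
  for (x0 in unique(pmax(c(rough, rough - 5, rough - 15, 0), 0))) {
    fit <- try(minpack.lm::nls.lm(
      par = c(0.4, (dmax - x0) * 1.1 + 1, x0),
      lower = c(1e-3, 1e-2, 0), upper = c(50, 1e5, dmax),
      fn = function(par) f - model(par),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(NA_real_)
  best$par[3]
}

#' Transform a trace into contour-length space
#'
#' Maps every point with force above `min_force_pN` to the contour length
#' of the WLC (at fixed persistence length) passing through it. Rupture
#' branches of constant contour length become peaks of the resulting
#' density, which is the fingerprint used to authenticate specific
#' cohesin-dockerin stretching events.
#'
#' @param trace A baseline-corrected [fd_trace()].
#' @param persistence_length_nm Fixed Lp for the inversion (default 0.4 nm,
#'   the value conventionally assumed for unfolded polypeptides).
#' @param temperature_K Temperature in kelvin.
#' @param min_force_pN Points below this force are ignored (default 10 pN;
#'   the inversion is ill-conditioned near zero force).
#' @param bin_width_nm Histogram bin width for the returned density.
#' @return An object of class `lc_transform`: `lc_nm` (transformed sample
#'   values), `histogram` (breaks/counts/density), `n_points`, and
#'   `empty` (`TRUE` when no point exceeded the force threshold).
#' @export
contour_length_transform <- function(trace, persistence_length_nm = 0.4,
                                     temperature_K = 300, min_force_pN = 10,
                                     bin_width_nm = 1) {
  stopifnot(inherits(trace, "fd_trace"))
  .assert_scalar_pos(persistence_length_nm, "persistence_length_nm")
  .assert_scalar_pos(min_force_pN, "min_force_pN")
  sel <- trace$force_pN >= min_force_pN & trace$distance_nm > 0
  if (!any(sel))
    return(structure(list(lc_nm = numeric(0), histogram = NULL,
                          n_points = 0L, empty = TRUE),
                     class = "lc_transform"))
  lc <- .wlc_contour_from_point(trace$distance_nm[sel], trace$force_pN[sel],
                                persistence_length_nm, temperature_K)
  breaks <- seq(0, max(lc) + bin_width_nm,
                by = bin_width_nm)
  h <- graphics::hist(lc, breaks = breaks, plot = FALSE)
  structure(list(lc_nm = lc,
                 histogram = list(breaks = h$breaks, counts = h$counts,
                                  density = h$density),
                 n_points = length(lc), empty = FALSE),
            class = "lc_transform")
}

# Rupture peaks: local maxima of the (median-smoothed) force followed by
# a sustained level shift. A rupture moves the force to a lower branch
# and it stays there; a noise excursion recovers. The candidate is kept
# when the median force just after the drop window sits below the median
# just before the peak by at least `drop_fraction` of the peak force and
# several smoothed-noise standard deviations. The returned index is the
# raw-force maximum near the smoothed candidate, so the peak point
# itself is not smoothed.
.find_rupture_peaks <- function(force, min_peak_force, drop_fraction = 0.15,
                                drop_window = 5L, noise_sd = NULL) {
  n <- length(force)
  if (n < 3L * drop_window + 5L) return(integer(0))
  sm <- stats::runmed(force, 5L)
  noise_sm <- (noise_sd %||% stats::mad(diff(force)) / sqrt(2)) / sqrt(5)
  cand <- which(force >= min_peak_force & sm >= min_peak_force)
  cand <- cand[cand > drop_window + 2L & cand <= n - 2L * drop_window]
  keep <- cand[vapply(cand, function(i) {
    if (sm[i] != max(sm[max(1L, i - 2L):min(n, i + 2L)])) return(FALSE)
    before <- stats::median(sm[max(1L, i - drop_window):(i - 1L)])
    after <- stats::median(sm[(i + drop_window - 1L):(i + 2L * drop_window)])
    before - after >= max(drop_fraction * sm[i], 5 * noise_sm)
  }, logical(1))]
  if (!length(keep)) return(integer(0))
  # merge candidates that are one rupture seen twice: adjacent, or close
  # together at the same smoothed force level (two genuine ruptures in
  # quick succession still differ in level)
  groups <- integer(length(keep))
  groups[1] <- 1L
  if (length(keep) > 1L) for (t in 2:length(keep)) {
    gap <- keep[t] - keep[t - 1L]
    same <- gap <= 2L ||
      (gap <= drop_window + 1L &&
         abs(sm[keep[t]] - sm[keep[t - 1L]]) < 5 * noise_sm)
    groups[t] <- groups[t - 1L] + !same
  }
  peaks <- as.integer(vapply(split(keep, groups),
                             function(ix) ix[which.max(force[ix])],
                             numeric(1)))
  # snap to the raw local maximum around each smoothed candidate
  vapply(peaks, function(i) {
    w <- max(1L, i - 2L):min(n, i + 2L)
    w[which.max(force[w])]
  }, integer(1))
}

#' Detect the cohesin-dockerin double-rupture fingerprint
#'
#' Forced dissociation of the type I cohesin-dockerin pair produces a
#' characteristic terminal double rupture whose two branches are separated
#' by 8 nm in contour-length space; that separation authenticates a
#' specific stretching event. The detector finds rupture peaks (local
#' force maxima with a >= 30 % force drop within 5 samples), takes the
#' final two, transforms each peak point to its contour length at the
#' given persistence length, and accepts the trace when the separation
#' falls within the tolerance window.
#'
#' A rupture peak is a local maximum of the median-smoothed force whose
#' level shift -- the drop from the median force just before the peak to
#' the median just after the drop window -- exceeds both a fraction of
#' the peak force and five smoothed-noise standard deviations; the
#' sustained-shift requirement separates true branch changes from noise
#' excursions that recover.
#'
#' @param trace A baseline-corrected [fd_trace()].
#' @param persistence_length_nm Lp for the contour-length inversion.
#' @param expected_separation_nm Expected branch separation (default 8 nm).
#' @param tolerance_nm Acceptance window half-width (default 2 nm).
#' @param drop_fraction,drop_window Peak criterion (see above).
#' @param min_peak_force_pN Minimum peak force; defaults to
#'   `max(5 * noise sd, 10)` using the noise estimate stored by
#'   [correct_baseline()].
#' @param temperature_K Temperature in kelvin.
#' @return An object of class `stretch_event`: `specific` flag,
#'   `first_peak_index`, `second_peak_index`, `delta_Lc_nm`,
#'   `rupture_forces_pN`, `lc_at_peaks_nm` and a `reason` code for
#'   rejected traces.
#' @export
detect_specific_event <- function(trace, persistence_length_nm = 0.4,
                                  expected_separation_nm = 8,
                                  tolerance_nm = 2, drop_fraction = 0.15,
                                  drop_window = 5L,
                                  min_peak_force_pN = NULL,
                                  temperature_K = 300) {
  stopifnot(inherits(trace, "fd_trace"))
  noise <- attr(trace, "noise_sd_pN") %||% stats::mad(utils::tail(
    trace$force_pN, max(10L, length(trace$force_pN) %/% 10L)))
  min_peak <- min_peak_force_pN %||% max(5 * noise, 10)
  nonspecific <- function(reason)
    structure(list(specific = FALSE, first_peak_index = NULL,
                   second_peak_index = NULL, delta_Lc_nm = NULL,
                   rupture_forces_pN = NULL, lc_at_peaks_nm = NULL,
                   reason = reason), class = "stretch_event")
  peaks <- .find_rupture_peaks(trace$force_pN, min_peak, drop_fraction,
                               drop_window, noise_sd = noise)
  peaks <- peaks[trace$distance_nm[peaks] > 0]
  if (length(peaks) == 0L) return(nonspecific("no peaks"))
  if (length(peaks) == 1L) return(nonspecific("single peak"))
  i1 <- peaks[length(peaks) - 1L]
  i2 <- peaks[length(peaks)]
  lc <- .wlc_contour_from_point(trace$distance_nm[c(i1, i2)],
                                trace$force_pN[c(i1, i2)],
                                persistence_length_nm, temperature_K)
  delta <- lc[2] - lc[1]
  if (abs(delta - expected_separation_nm) > tolerance_nm) {
    ev <- nonspecific("separation outside window")
    ev$delta_Lc_nm <- delta
    return(ev)
  }
  structure(list(specific = TRUE, first_peak_index = i1,
                 second_peak_index = i2, delta_Lc_nm = delta,
                 rupture_forces_pN = trace$force_pN[c(i1, i2)],
                 lc_at_peaks_nm = lc, reason = "specific"),
            class = "stretch_event")
}

#' @export
print.stretch_event <- function(x, ...) {
  if (x$specific)
    cat(sprintf("Specific stretch event: dLc = %.2f nm, ruptures %.0f / %.0f pN\n",
                x$delta_Lc_nm, x$rupture_forces_pN[1], x$rupture_forces_pN[2]))
  else cat(sprintf("Non-specific trace (%s)\n", x$reason))
  invisible(x)
}

#' Fit the WLC to an accepted trace
#'
#' Fits both persistence and contour length on the segment from zero
#' extension to the first peak of the double rupture, i.e. the stretch of
#' the molecule itself before the complex dissociates. Points with
#' negative extension or negative force are clipped out of the fit.
#'
#' @param trace A baseline-corrected [fd_trace()].
#' @param event The [detect_specific_event()] result; must be specific.
#' @param fixed_temperature_K Temperature in kelvin (fixed).
#' @return A `wlc_fit` (see [fit_wlc()]) with `fit_window` set to the
#'   index range used.
#' @export
analyze_trace <- function(trace, event, fixed_temperature_K = 300) {
  stopifnot(inherits(trace, "fd_trace"), inherits(event, "stretch_event"))
  if (!isTRUE(event$specific))
    stop("trace rejected: event is not a specific stretching event",
         call. = FALSE)
  i1 <- event$first_peak_index
  idx <- seq_len(i1)
  idx <- idx[trace$distance_nm[idx] > 0 & trace$force_pN[idx] > 0]
  pts <- data.frame(extension_nm = trace$distance_nm[idx],
                    force_pN = trace$force_pN[idx])
  attr(pts, "fit_window") <- c(min(idx), i1)
  init <- if (!is.null(event$lc_at_peaks_nm))
    list(contour_length_nm = max(event$lc_at_peaks_nm[1],
                                 max(pts$extension_nm) * 1.01))
  fit_wlc(pts, initial = init, temperature_K = fixed_temperature_K)
}

#' Population statistics of WLC fits
#'
#' Arithmetic means and population (uncorrected) standard deviations of
#' the fitted contour and persistence lengths, plus histograms at the
#' stated bin widths.
#'
#' @param fits Non-empty list of `wlc_fit` objects.
#' @param lc_bin_nm Contour-length histogram bin width (default 10 nm).
#' @param lp_bin_nm Persistence-length histogram bin width (default 0.05 nm).
#' @param n_total Total number of traces examined (accepted plus
#'   rejected); defaults to `length(fits)`.
#' @return An object of class `population_summary`.
#' @export
summarize_population <- function(fits, lc_bin_nm = 10, lp_bin_nm = 0.05,
                                 n_total = length(fits)) {
  if (!length(fits)) stop("no fits to summarise", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "wlc_fit")))
  lc <- vapply(fits, function(f) f$params$contour_length_nm, numeric(1))
  lp <- vapply(fits, function(f) f$params$persistence_length_nm, numeric(1))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  mk_hist <- function(x, bw) {
    lo <- floor(min(x) / bw) * bw
    hi <- ceiling(max(x) / bw) * bw
    if (hi <= lo) hi <- lo + bw
    h <- graphics::hist(x, breaks = seq(lo, hi, by = bw), plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  }
  structure(list(
    n_total = as.integer(n_total), n_accepted = length(fits),
    contour_mean_nm = mean(lc), contour_sd_nm = pop_sd(lc),
    persistence_mean_nm = mean(lp), persistence_sd_nm = pop_sd(lp),
    contour_lengths_nm = lc, persistence_lengths_nm = lp,
    lc_histogram = mk_hist(lc, lc_bin_nm),
    lp_histogram = mk_hist(lp, lp_bin_nm)
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "Population of %d accepted traces (of %d): Lc = %.1f +/- %.1f nm, Lp = %.3f +/- %.3f nm\n",
    x$n_accepted, x$n_total, x$contour_mean_nm, x$contour_sd_nm,
    x$persistence_mean_nm, x$persistence_sd_nm))
  invisible(x)
}

#' Run the full AFM analysis over a set of traces
#'
#' Convenience wrapper: baseline-correct each trace, detect the specific
#' double-rupture fingerprint, fit accepted traces and summarise the
#' population.
#'
#' @param traces List of [fd_trace()] objects.
#' @param persistence_length_nm Lp for the contour-length transform.
#' @param expected_separation_nm,tolerance_nm Fingerprint window.
#' @param temperature_K Temperature in kelvin.
#' @return List with `events`, `fits`, `summary` and `accepted` (logical
#'   vector over the input traces).
#' @export
analyze_afm_cohort <- function(traces, persistence_length_nm = 0.4,
                               expected_separation_nm = 8, tolerance_nm = 2,
                               temperature_K = 300) {
  events <- vector("list", length(traces))
  fits <- list()
  accepted <- logical(length(traces))
  for (i in seq_along(traces)) {
    tr <- try(correct_baseline(traces[[i]]), silent = TRUE)
    if (inherits(tr, "try-error")) {
      events[[i]] <- structure(list(specific = FALSE, reason = "baseline failure"),
                               class = "stretch_event")
      next
    }
    ev <- detect_specific_event(tr, persistence_length_nm,
                                expected_separation_nm, tolerance_nm,
                                temperature_K = temperature_K)
    events[[i]] <- ev
    if (isTRUE(ev$specific)) {
      fit <- try(analyze_trace(tr, ev, temperature_K), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        fits[[length(fits) + 1L]] <- fit
        accepted[i] <- TRUE
      }
    }
  }
  summary <- if (length(fits))
    summarize_population(fits, n_total = length(traces))
  list(events = events, fits = fits, summary = summary, accepted = accepted)
}
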