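#' Construct an umbrella-sampling window
#'
#' One harmonically biased window along the end-to-end distance: the bias
#' centre, the harmonic force constant of the umbrella potential and the
#' reaction-coordinate samples recorded under that bias.
#'
#' @param center_nm Bias centre in nm.
#' @param spring_constant_kJ_mol_nm2 Harmonic force constant (> 0),
#'   kJ mol^-1 nm^-2.
#' @param samples_nm Numeric vector of recorded coordinates.
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center_nm, spring_constant_kJ_mol_nm2,
                            samples_nm) {
  if (!is.numeric(center_nm) || length(center_nm) != 1L || !is.finite(center_nm))
    stop("'center_nm' must be a finite scalar", call. = FALSE)
  .assert_scalar_pos(spring_constant_kJ_mol_nm2, "spring_constant_kJ_mol_nm2")
  samples_nm <- as.numeric(samples_nm)
  if (!length(samples_nm) || any(!is.finite(samples_nm)))
    stop("samples must be finite numbers", call. = FALSE)
  structure(list(center_nm = center_nm,
                 spring_constant_kJ_mol_nm2 = spring_constant_kJ_mol_nm2,
                 samples_nm = samples_nm),
            class = "umbrella_window")
}

#' Read umbrella windows from files
#'
#' Each window file has two whitespace-separated columns (time, coordinate
#' in nm); lines starting with `#` or `@` (xvg dialect) are skipped.
#' Window metadata comes either from `#center_nm` /
#' `#spring_constant_kJ_mol_nm2` header lines or from a manifest TSV with
#' columns `file`, `center_nm`, `spring_constant_kJ_mol_nm2`.
#'
#' @param source Directory of window files (or a single file).
#' @param manifest Optional path to a manifest TSV.
#' @return List of [umbrella_window()] objects.
#' @export
read_umbrella_windows <- function(source, manifest = NULL) {
  man <- NULL
  if (!is.null(manifest)) {
    man <- utils::read.table(manifest, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    files <- file.path(if (dir.exists(source)) source else dirname(source),
                       man$file)
  } else if (dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.(xvg|tsv|txt|dat)$",
                             full.names = TRUE))
    if (!length(files)) stop("no window files found in ", source, call. = FALSE)
  } else files <- source
  lapply(seq_along(files), function(i) {
    lines <- readLines(files[i], warn = FALSE)
    meta_lines <- lines[grepl("^\\s*#", lines)]
    meta <- list()
    for (ln in meta_lines) {
      parts <- strsplit(sub("^\\s*#\\s*", "", ln), "\\s+")[[1]]
      if (length(parts) >= 2) meta[[parts[1]]] <- suppressWarnings(as.numeric(parts[2]))
    }
    keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
    vals <- do.call(rbind, lapply(strsplit(trimws(lines[keep]), "[\t ]+"),
                                  function(x) as.numeric(x[1:2])))
    if (any(!is.finite(vals)))
      stop("parse error in ", files[i], ": non-numeric data", call. = FALSE)
    center <- if (!is.null(man)) man$center_nm[i] else meta$center_nm
    k <- if (!is.null(man)) man$spring_constant_kJ_mol_nm2[i]
         else meta$spring_constant_kJ_mol_nm2
    if (is.null(center) || is.null(k) || !is.finite(center) || !is.finite(k))
      stop("window metadata (center, spring constant) missing for ",
           files[i], call. = FALSE)
    umbrella_window(center, k, vals[, 2])
  })
}

#' Reconstruct a PMF by the weighted histogram analysis method
#'
#' Self-consistent iteration of the standard WHAM equations over binned
#' umbrella-window samples: unbiased bin probabilities
#' `P_l = sum_i n_il / sum_i N_i exp((f_i - U_i(z_l)) / kBT)` and window
#' free-energy shifts `f_i = -kBT log sum_l P_l exp(-U_i(z_l)/kBT)`,
#' iterated until the largest change of any shift falls below
#' `tol_kJ_mol`. The free energy is reported at bin centres with its
#' minimum pinned to zero. Windows are processed in order of increasing
#' centre internally, so the result is invariant (bit-identical) under
#' permutation of the input.
#'
#' @param windows List of [umbrella_window()] objects; neighbouring
#'   windows' sample ranges must overlap.
#' @param grid_nm Optional bin edges; default covers all samples at
#'   `bin_width_nm` spacing.
#' @param temperature_K Temperature in kelvin.
#' @param tol_kJ_mol Convergence tolerance on the shifts (default 1e-8).
#' @param max_iter Maximum iterations (default 100000).
#' @param bin_width_nm Default bin width, 0.05 nm (below the positional
#'   spread `sqrt(kBT/k)` of the stiffest window used here).
#' @param min_samples Minimum samples required per window (default 100).
#' @return An object of class `pmf_profile`: `grid_nm` (bin centres),
#'   `free_energy_kJ_mol` (minimum 0; `NA` in unvisited bins),
#'   `mean_force_pN` (central-difference derivative, pN; `NA` at the
#'   edges), `converged`, `n_iterations`, `window_shifts_kJ_mol`,
#'   `counts`.
#' @export
wham <- function(windows, grid_nm = NULL, temperature_K = 300,
                 tol_kJ_mol = 1e-8, max_iter = 100000L,
                 bin_width_nm = 0.05, min_samples = 100L) {
  stopifnot(length(windows) >= 1L,
            all(vapply(windows, inherits, logical(1), "umbrella_window")))
  ns <- vapply(windows, function(w) length(w$samples_nm), integer(1))
  if (any(ns < min_samples))
    stop(sprintf("every window needs at least %d samples for reconstruction",
                 min_samples), call. = FALSE)
  centers_in <- vapply(windows, `[[`, numeric(1), "center_nm")
  windows <- windows[order(centers_in)]

  # connectivity: consecutive windows must share sampled territory
  if (length(windows) > 1L) {
    for (i in seq_len(length(windows) - 1L)) {
      r1 <- range(windows[[i]]$samples_nm)
      r2 <- range(windows[[i + 1L]]$samples_nm)
      if (r1[2] < r2[1] || r2[2] < r1[1])
        stop(sprintf(
          "windows centred at %.3g and %.3g nm do not overlap (gap %.3g-%.3g nm)",
          windows[[i]]$center_nm, windows[[i + 1L]]$center_nm,
          min(r1[2], r2[2]), max(r1[1], r2[1])), call. = FALSE)
    }
  }

  all_s <- unlist(lapply(windows, `[[`, "samples_nm"))
  if (is.null(grid_nm)) {
    lo <- floor(min(all_s) / bin_width_nm) * bin_width_nm - bin_width_nm
    hi <- ceiling(max(all_s) / bin_width_nm) * bin_width_nm + bin_width_nm
    grid_nm <- seq(lo, hi, by = bin_width_nm)
  }
  grid_nm <- sort(as.numeric(grid_nm))
  if (min(all_s) < grid_nm[1] || max(all_s) > grid_nm[length(grid_nm)])
    stop("samples fall outside the supplied grid span", call. = FALSE)
  z <- 0.5 * (grid_nm[-1] + grid_nm[-length(grid_nm)])
  L <- length(z)
  W <- length(windows)
  kBT <- .kB_kJ_mol * temperature_K

  counts <- vapply(windows, function(w) {
    ix <- findInterval(w$samples_nm, grid_nm, rightmost.closed = TRUE,
                       all.inside = TRUE)
    tabulate(ix, nbins = L)
  }, numeric(L))                      # L x W
  M <- rowSums(counts)
  N <- colSums(counts)
  bias <- vapply(windows, function(w)
    0.5 * w$spring_constant_kJ_mol_nm2 * (z - w$center_nm)^2,
    numeric(L))                       # L x W
  A <- exp(-bias / kBT)

  f <- numeric(W)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    g <- exp(f / kBT)
    denom <- A %*% (N * g)            # L x 1
    P <- ifelse(denom > 0, M / denom, 0)
    zi <- crossprod(A, P)             # W x 1
    f_new <- -kBT * log(as.numeric(zi))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol_kJ_mol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  P <- as.numeric(P)
  P <- P / sum(P)
  G <- ifelse(P > 0, -kBT * log(P), NA_real_)
  G <- G - min(G, na.rm = TRUE)
  Fz <- .central_gradient(z, G) * .pN_per_kJ_mol_nm
  structure(list(grid_nm = z, free_energy_kJ_mol = G, mean_force_pN = Fz,
                 probability = P, counts = counts, converged = converged,
                 n_iterations = iter, window_shifts_kJ_mol = f,
                 temperature_K = temperature_K),
            class = "pmf_profile")
}

# central differences in the interior, NA at the boundary / beside NAs
.central_gradient <- function(z, G) {
  n <- length(G)
  out <- rep(NA_real_, n)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    out[i] <- (G[i + 1L] - G[i - 1L]) / (z[i + 1L] - z[i - 1L])
  }
  out
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: %d bins over %.2f-%.2f nm, %s after %d iterations\n",
              length(x$grid_nm), min(x$grid_nm), max(x$grid_nm),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Mean-force profile of a PMF
#'
#' Derivative of the free energy along the reaction coordinate,
#' converted to pN (1 kJ mol^-1 nm^-1 = 1.6606 pN). The sign convention
#' is that a force resisting extension is positive.
#'
#' For a reconstructed profile carrying bin counts (a [wham()] result)
#' the derivative is estimated by a count-weighted local quadratic fit
#' over a `window_nm` neighbourhood of each evaluation point, which
#' suppresses the bin-level noise of sparsely visited bins; for an
#' analytic profile (plain `grid_nm`/`free_energy_kJ_mol` list, or
#' `window_nm = 0`) the plain central difference is used.
#'
#' @param pmf A converged `pmf_profile` (from [wham()]) or a list with
#'   `grid_nm` and `free_energy_kJ_mol`.
#' @param at Evaluation points; default: the profile's grid.
#' @param window_nm Half-width of the local-fit neighbourhood (default
#'   0.15 nm for [wham()] profiles, 0 otherwise).
#' @return Data frame with columns `z_nm` and `force_pN` (points with a
#'   defined estimate only).
#' @export
mean_force_profile <- function(pmf, at = NULL, window_nm = NULL) {
  is_wham <- inherits(pmf, "pmf_profile") && !is.null(pmf$counts)
  if (inherits(pmf, "pmf_profile") && !isTRUE(pmf$converged))
    stop("PMF did not converge; refusing to differentiate", call. = FALSE)
  z <- pmf$grid_nm
  G <- pmf$free_energy_kJ_mol
  if (length(z) < 3L)
    stop("need at least 3 grid points to differentiate", call. = FALSE)
  window_nm <- window_nm %||% (if (is_wham) 0.15 else 0)
  if (window_nm <= 0) {
    Fz <- .central_gradient(z, G) * .pN_per_kJ_mol_nm
    ok <- is.finite(Fz)
    return(data.frame(z_nm = z[ok], force_pN = Fz[ok]))
  }
  at <- at %||% z
  wts <- if (is_wham) rowSums(pmf$counts) else rep(1, length(z))
  ok <- is.finite(G) & wts > 0
  est <- vapply(at, function(z0) {
    sel <- ok & abs(z - z0) <= window_nm
    if (sum(sel) < 4L) return(NA_real_)
    dz <- z[sel] - z0
    fit <- stats::lm.wfit(cbind(1, dz, dz^2), G[sel], wts[sel])
    fit$coefficients[2]
  }, numeric(1))
  keep <- is.finite(est)
  data.frame(z_nm = at[keep], force_pN = est[keep] * .pN_per_kJ_mol_nm)
}

#' Well-sampled range of a reconstructed PMF
#'
#' Range of the reaction coordinate over which a [wham()] profile is
#' supported by actual sampling. Beyond the outermost windows' sample
#' clouds the free energy is extrapolated from histogram tails and its
#' derivative is unreliable; downstream fits (e.g. a WLC to the
#' mean-force profile) should be restricted to this range.
#'
#' @param pmf A [wham()] result.
#' @param min_count Minimum total bin count for a bin to be considered
#'   sampled (default 20).
#' @param margin_nm Additional shrink at both ends, e.g. the derivative
#'   estimator's window (default 0.15 nm).
#' @return `c(lower, upper)` in nm.
#' @export
pmf_supported_range <- function(pmf, min_count = 20, margin_nm = 0.15) {
  stopifnot(inherits(pmf, "pmf_profile"), !is.null(pmf$counts))
  z <- pmf$grid_nm[rowSums(pmf$counts) >= min_count]
  if (!length(z)) stop("no bins reach 'min_count' samples", call. = FALSE)
  c(min(z) + margin_nm, max(z) - margin_nm)
}
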