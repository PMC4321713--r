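#' Construct an end-to-end distance trajectory
#'
#' @param time_ns Strictly increasing time stamps in ns.
#' @param distance_nm Non-negative end-to-end distances, same length.
#' @param trajectory_id Identifier string.
#' @return An object of class `ee_trajectory`.
#' @export
end_to_end_trajectory <- function(time_ns, distance_nm, trajectory_id = "traj") {
  time_ns <- as.numeric(time_ns)
  distance_nm <- as.numeric(distance_nm)
  if (!length(time_ns) || length(time_ns) != length(distance_nm))
    stop("time and distance must be non-empty and of equal length",
         call. = FALSE)
  if (any(!is.finite(time_ns)) || any(!is.finite(distance_nm)))
    stop("trajectory values must be finite", call. = FALSE)
  if (any(diff(time_ns) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(distance_nm < 0))
    stop("distances must be non-negative", call. = FALSE)
  structure(list(time_ns = time_ns, distance_nm = distance_nm,
                 trajectory_id = as.character(trajectory_id)),
            class = "ee_trajectory")
}

#' First-passage times to the collapsed state
#'
#' For each trajectory, the first time the end-to-end distance reaches
#' the collapsed-state threshold (1.5 nm by default), linearly
#' interpolated between samples. Trajectories that never cross are
#' censored at their final recorded time.
#'
#' @param trajectories List of [end_to_end_trajectory()] objects.
#' @param threshold_nm Collapsed-state threshold (default 1.5 nm).
#' @return Data frame with columns `trajectory_id`, `time_ns`,
#'   `censored`.
#' @export
first_passage_times <- function(trajectories, threshold_nm = 1.5) {
  stopifnot(length(trajectories) >= 1L,
            all(vapply(trajectories, inherits, logical(1), "ee_trajectory")))
  rows <- lapply(trajectories, function(tr) {
    d <- tr$distance_nm
    t <- tr$time_ns
    i <- which(d <= threshold_nm)[1]
    if (is.na(i))
      return(data.frame(trajectory_id = tr$trajectory_id,
                        time_ns = t[length(t)], censored = TRUE))
    tt <- if (i == 1L) t[1]
          else t[i - 1L] + (t[i] - t[i - 1L]) *
                 (d[i - 1L] - threshold_nm) / (d[i - 1L] - d[i])
    data.frame(trajectory_id = tr$trajectory_id, time_ns = tt,
               censored = FALSE)
  })
  do.call(rbind, rows)
}

#' Cumulative collapse events over time
#'
#' `N(t)`: the number of uncensored first-passage events with passage
#' time at or below `t`, evaluated on a grid. Non-decreasing, reaching
#' the total number of events.
#'
#' @param times Data frame as returned by [first_passage_times()].
#' @param grid_ns Increasing evaluation grid in ns.
#' @return Data frame with columns `time_ns` and `count`.
#' @export
cumulative_events <- function(times, grid_ns) {
  grid_ns <- as.numeric(grid_ns)
  if (any(diff(grid_ns) <= 0))
    stop("grid must be strictly increasing", call. = FALSE)
  ev <- sort(times$time_ns[!times$censored])
  data.frame(time_ns = grid_ns,
             count = findInterval(grid_ns, ev))
}

# Sum of squared residuals of the cumulative-exponential model on a grid.
.cum_exp_sse <- function(tau, grid, counts, n_total)
  sum((counts - n_total * (1 - exp(-grid / tau)))^2)

#' Fit the cumulative-exponential model to a collapse curve
#'
#' Least-squares fit of `N(t) = n_total * (1 - exp(-t / tau))` to a
#' cumulative event curve, with the plateau constrained to `n_total`
#' (or free, as a two-parameter variant).
#'
#' @param grid_ns Time grid.
#' @param counts Cumulative counts on the grid.
#' @param n_total Plateau (total number of trajectories).
#' @param free_plateau If `TRUE`, also fit the plateau.
#' @return List with `tau_ns`, `plateau`, `sse` and `at_bounds` (flag set
#'   when the optimum hit the search bounds).
#' @export
fit_cumulative_exponential <- function(grid_ns, counts, n_total,
                                       free_plateau = FALSE) {
  grid_ns <- as.numeric(grid_ns)
  counts <- as.numeric(counts)
  stopifnot(length(grid_ns) == length(counts), length(grid_ns) >= 3L)
  pos <- grid_ns > 0
  tau0 <- stats::median(grid_ns[pos & counts >= 0.5 * max(counts)])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(grid_ns) / 2
  lo <- tau0 * 1e-3
  hi <- max(grid_ns) * 1e3
  if (!free_plateau) {
    opt <- stats::optimize(function(lt)
      .cum_exp_sse(exp(lt), grid_ns, counts, n_total),
      interval = log(c(lo, hi)), tol = 1e-12)
    tau <- exp(opt$minimum)
    at_bounds <- tau <= lo * 1.01 || tau >= hi * 0.99
    list(tau_ns = tau, plateau = n_total, sse = opt$objective,
         at_bounds = at_bounds)
  } else {
    fit <- minpack.lm::nls.lm(
      par = c(log_tau = log(tau0), plateau = n_total),
      lower = c(log(lo), 0), upper = c(log(hi), 10 * n_total),
      fn = function(p) counts - p[2] * (1 - exp(-grid_ns / exp(p[1]))),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    tau <- exp(fit$par[[1]])
    list(tau_ns = tau, plateau = fit$par[[2]], sse = fit$deviance,
         at_bounds = tau <= lo * 1.01 || tau >= hi * 0.99)
  }
}

# Vectorised grid fit of tau for a matrix of bootstrap cumulative curves
# (grid points x replicates): coarse log-spaced tau grid + parabolic
# refinement of the SSE minimum in log tau.
.batch_fit_tau <- function(C, grid, n_total, tau_center) {
  lt <- seq(log(tau_center) - log(8), log(tau_center) + log(8),
            length.out = 81L)
  M <- outer(grid, exp(lt), function(g, tau) n_total * (1 - exp(-g / tau)))
  # SSE_{b,t} = ||C_b||^2 - 2 C_b . M_t + ||M_t||^2
  cross <- crossprod(C, M)                       # B x T
  sse <- sweep(-2 * cross, 2, colSums(M^2), `+`) # row minima match SSE minima
  ix <- max.col(-sse, ties.method = "first")
  ix <- pmin(pmax(ix, 2L), length(lt) - 1L)
  b <- seq_len(nrow(sse))
  s0 <- sse[cbind(b, ix - 1L)]
  s1 <- sse[cbind(b, ix)]
  s2 <- sse[cbind(b, ix + 1L)]
  denom <- s0 - 2 * s1 + s2
  shift <- ifelse(abs(denom) > 0, 0.5 * (s0 - s2) / denom, 0)
  shift <- pmin(pmax(shift, -1), 1)
  exp(lt[ix] + shift * (lt[2] - lt[1]))
}

#' Exponential lifetime of the extended state
#'
#' Fits `N(t) = n_total * (1 - exp(-t / tau))` to the cumulative collapse
#' curve by least squares (the plateau constrained to the number of
#' trajectories), mirroring the exponential fit used to extract the
#' extended-state lifetime from cumulative collapse events. The 95 %
#' confidence interval comes from a seeded parametric bootstrap
#' (percentile interval over refits of resampled exponential passage
#' times, censored at the longest censoring time when censoring is
#' present).
#'
#' @param times Data frame from [first_passage_times()].
#' @param n_total Total trajectory count (default `nrow(times)`).
#' @param grid_ns Optional evaluation grid; default 200 points from 0 to
#'   the latest recorded time.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param boot_seed Seed for the bootstrap stream.
#' @param free_plateau Fit the plateau as a free parameter instead of
#'   constraining it to `n_total`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `collapse_fit`: `tau_ns`, `tau_ci_ns`,
#'   `n_events`, `n_censored`, `n_total`, `plateau`, `at_bounds`.
#' @export
fit_lifetime <- function(times, n_total = nrow(times), grid_ns = NULL,
                         n_boot = 1000L, boot_seed = 1L,
                         free_plateau = FALSE, conf_level = 0.95) {
  ev <- times$time_ns[!times$censored]
  n_cens <- sum(times$censored)
  if (length(ev) < 3L)
    stop("need at least 3 uncensored collapse events", call. = FALSE)
  if (n_total < length(ev) + n_cens)
    stop("'n_total' smaller than the number of records", call. = FALSE)
  if (is.null(grid_ns))
    grid_ns <- seq(0, max(times$time_ns), length.out = 200L)
  counts <- cumulative_events(times, grid_ns[grid_ns > 0])$count
  grid <- grid_ns[grid_ns > 0]
  fit <- fit_cumulative_exponential(grid, counts, n_total, free_plateau)
  tau <- fit$tau_ns

  t_cens <- if (n_cens > 0) max(times$time_ns[times$censored]) else Inf
  boot_tau <- with_seed(boot_seed, {
    draws <- matrix(stats::rexp(n_total * n_boot, rate = 1 / tau),
                    nrow = n_total)
    C <- apply(draws, 2, function(tb) {
      tb <- tb[tb <= t_cens]
      findInterval(grid, sort(tb))
    })
    .batch_fit_tau(C, grid, n_total, tau)
  })
  ci <- stats::quantile(boot_tau, c((1 - conf_level) / 2,
                                    1 - (1 - conf_level) / 2), names = FALSE)
  structure(list(tau_ns = tau, tau_ci_ns = ci, n_events = length(ev),
                 n_censored = n_cens, n_total = as.integer(n_total),
                 plateau = fit$plateau, at_bounds = fit$at_bounds,
                 boot_tau_ns = boot_tau),
            class = "collapse_fit")
}

#' @export
print.collapse_fit <- function(x, ...) {
  cat(sprintf(
    "Extended-state lifetime: tau = %.3g ns (95%% CI %.3g-%.3g), %d events, %d censored of %d\n",
    x$tau_ns, x$tau_ci_ns[1], x$tau_ci_ns[2], x$n_events, x$n_censored,
    x$n_total))
  invisible(x)
}

#' Polyproline-II dihedral fraction per frame
#'
#' Fraction of residues whose backbone dihedrals fall inside the
#' polyproline-II (PPII) region of the Ramachandran map, per frame. The
#' default window (phi in \[-100, -50\], psi in \[120, 180\] degrees)
#' covers the canonical PPII point near (-75, 145).
#'
#' @param dihedrals Data frame with columns `frame`, `residue`,
#'   `phi_deg`, `psi_deg`; angles in (-180, 180].
#' @param phi_range,psi_range PPII window bounds in degrees.
#' @return Data frame with columns `frame` and `ppii_fraction` in
#'   \[0, 1\].
#' @export
ppii_fraction <- function(dihedrals, phi_range = c(-100, -50),
                          psi_range = c(120, 180)) {
  req <- c("frame", "residue", "phi_deg", "psi_deg")
  if (!all(req %in% names(dihedrals)))
    stop("dihedral table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!nrow(dihedrals)) stop("empty dihedral table", call. = FALSE)
  ang <- c(dihedrals$phi_deg, dihedrals$psi_deg)
  if (any(!is.finite(ang)) || any(ang <= -180) || any(ang > 180))
    stop("angles must lie in (-180, 180]", call. = FALSE)
  inside <- dihedrals$phi_deg >= phi_range[1] &
    dihedrals$phi_deg <= phi_range[2] &
    dihedrals$psi_deg >= psi_range[1] &
    dihedrals$psi_deg <= psi_range[2]
  agg <- stats::aggregate(inside,
                          by = list(frame = dihedrals$frame), FUN = mean)
  data.frame(frame = agg$frame, ppii_fraction = agg$x)
}
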