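#' Worm-like chain parameters
#'
#' Bundles the two mechanical parameters of the worm-like chain (WLC) model
#' of entropic polymer elasticity -- the persistence length `Lp` (bending
#' stiffness length scale) and the contour length `Lc` (fully extended
#' length) -- together with the absolute temperature.
#'
#' @param persistence_length_nm Persistence length in nm (> 0).
#' @param contour_length_nm Contour length in nm (> 0).
#' @param temperature_K Absolute temperature in kelvin (> 0). Default 300 K,
#'   the temperature of the simulations the pipeline emulates.
#' @return An object of class `wlc_params`.
#' @examples
#' wlc_params(0.37, 94)
#' @export
wlc_params <- function(persistence_length_nm, contour_length_nm,
                       temperature_K = 300) {
  structure(list(
    persistence_length_nm = .assert_scalar_pos(persistence_length_nm,
                                               "persistence_length_nm"),
    contour_length_nm = .assert_scalar_pos(contour_length_nm,
                                           "contour_length_nm"),
    temperature_K = .assert_scalar_pos(temperature_K, "temperature_K")
  ), class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("WLC parameters: Lp = %.4g nm, Lc = %.4g nm, T = %g K\n",
              x$persistence_length_nm, x$contour_length_nm, x$temperature_K))
  invisible(x)
}

# Marko-Siggia interpolation factor g(u) = 1/(4(1-u)^2) - 1/4 + u for
# relative extension u = x/Lc. Strictly increasing and convex on [0, 1).
.ms_factor <- function(u) 0.25 / (1 - u)^2 - 0.25 + u

#' WLC force at a given extension
#'
#' Evaluates the Marko-Siggia interpolation formula
#' `F = (kB T / Lp) * (1/(4 (1 - x/Lc)^2) - 1/4 + x/Lc)`,
#' the standard AFM convention for entropic force-extension curves at the
#' force ranges probed in single-molecule pulling experiments. The force is
#' zero at zero extension, strictly increasing, and diverges as the
#' extension approaches the contour length.
#'
#' @param params A [wlc_params()] object.
#' @param extension_nm Extension(s) in nm; must satisfy
#'   `0 <= extension_nm < contour_length_nm`.
#' @return Force(s) in pN.
#' @examples
#' wlc_force(wlc_params(0.4, 100), 50)
#' @export
wlc_force <- function(params, extension_nm) {
  stopifnot(inherits(params, "wlc_params"))
  x <- as.numeric(extension_nm)
  if (length(x) == 0L || any(!is.finite(x)))
    stop("extensions must be finite numbers", call. = FALSE)
  if (any(x < 0))
    stop("extension must be non-negative", call. = FALSE)
  if (any(x >= params$contour_length_nm))
    stop("extension must be smaller than the contour length", call. = FALSE)
  kBT <- .kB_pN_nm * params$temperature_K
  (kBT / params$persistence_length_nm) * .ms_factor(x / params$contour_length_nm)
}

# Vectorised bisection for the unique root of f(mid) = target on [lo, hi],
# with f strictly increasing. Used for both inversions below.
.bisect <- function(f, target, lo, hi, n_iter) {
  lo <- rep_len(lo, length(target))
  hi <- rep_len(hi, length(target))
  for (i in seq_len(n_iter)) {
    mid <- 0.5 * (lo + hi)
    below <- f(mid) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  0.5 * (lo + hi)
}

#' Extension of a WLC at a given force
#'
#' Inverts [wlc_force()] by bracketed bisection on
#' `[0, Lc (1 - 1e-12)]` to an absolute tolerance of `1e-9 * Lc`.
#'
#' @param params A [wlc_params()] object.
#' @param force_pN Non-negative force(s) in pN.
#' @return Extension(s) in nm in `[0, Lc)`.
#' @export
wlc_extension <- function(params, force_pN) {
  stopifnot(inherits(params, "wlc_params"))
  f <- as.numeric(force_pN)
  if (length(f) == 0L || any(!is.finite(f)))
    stop("forces must be finite numbers", call. = FALSE)
  if (any(f < 0))
    stop("force must be non-negative", call. = FALSE)
  Lc <- params$contour_length_nm
  kBT <- .kB_pN_nm * params$temperature_K
  target <- f * params$persistence_length_nm / kBT
  # 52 halvings of the bracket reach well below the 1e-9 * Lc tolerance.
  out <- .bisect(.ms_factor, target, 0, Lc * (1 - 1e-12) / Lc, 52L) * Lc
  out[f == 0] <- 0
  out
}

# Invert the WLC in the contour length: given points (x, F) and a fixed Lp,
# find the Lc for which the curve passes through each point. Solves
# g(u) = F Lp / kBT for the relative extension u, then Lc = x / u.
.wlc_contour_from_point <- function(extension_nm, force_pN,
                                    persistence_length_nm,
                                    temperature_K = 300) {
  kBT <- .kB_pN_nm * temperature_K
  target <- force_pN * persistence_length_nm / kBT
  if (any(target <= 0))
    stop("contour-length inversion requires strictly positive forces",
         call. = FALSE)
  u <- .bisect(.ms_factor, target, 1e-15, 1 - 1e-12, 60L)
  extension_nm / u
}

#' Fit a worm-like chain to force-extension data
#'
#' Unweighted least squares of the Marko-Siggia force on extension, with
#' either or both of `Lp` and `Lc` free. Standard errors come from the
#' local quadratic approximation of the objective at the optimum
#' (Jacobian-based, `s^2 (J'J)^-1`). The fit is deterministic given its
#' inputs.
#'
#' @param points A two-column object (`extension_nm`, `force_pN`): a
#'   data.frame, matrix or list with those names.
#' @param fixed Optional named list holding parameters to keep fixed
#'   (`persistence_length_nm` and/or `contour_length_nm`).
#' @param initial Optional [wlc_params()] (or named list) of starting
#'   values.
#' @param temperature_K Temperature in kelvin (fixed, never fitted).
#' @return An object of class `wlc_fit`: fields `params` ([wlc_params()]),
#'   `param_uncertainties` (named standard errors, `NA` for fixed
#'   parameters), `residual_norm` (L2 norm of force residuals, pN),
#'   `n_points`, `fit_window` (index range used), `fixed_mask`.
#' @examples
#' p <- wlc_params(0.37, 94)
#' x <- seq(1, 80, by = 1)
#' fit_wlc(data.frame(extension_nm = x, force_pN = wlc_force(p, x)))
#' @export
fit_wlc <- function(points, fixed = NULL, initial = NULL,
                    temperature_K = 300) {
  pts <- .as_fe_points(points)
  x <- pts$extension_nm
  y <- pts$force_pN
  if (any(x < 0)) stop("extensions must be non-negative", call. = FALSE)
  fixed <- fixed %||% list()
  bad <- setdiff(names(fixed), c("persistence_length_nm", "contour_length_nm"))
  if (length(bad))
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  free <- setdiff(c("persistence_length_nm", "contour_length_nm"),
                  names(fixed))
  n_free <- length(free)
  if (n_free == 0L)
    stop("at least one of Lp and Lc must be free", call. = FALSE)
  if (length(x) < n_free + 1L)
    stop(sprintf("need at least %d points to fit %d free parameter(s)",
                 n_free + 1L, n_free), call. = FALSE)
  if (all(y == 0))
    stop("degenerate fit: all forces are zero", call. = FALSE)

  kBT <- .kB_pN_nm * temperature_K
  xmax <- max(x)
  if (is.null(initial)) initial <- list()
  start <- c(
    persistence_length_nm = initial$persistence_length_nm %||% 0.4,
    contour_length_nm = initial$contour_length_nm %||% (xmax * 1.1 + 1e-6)
  )
  full <- function(par) {
    p <- c(par, unlist(fixed))
    lp <- p[["persistence_length_nm"]]
    lc <- p[["contour_length_nm"]]
    u <- pmin(x / lc, 1 - 1e-12)
    (kBT / lp) * .ms_factor(u)
  }
  lower <- c(persistence_length_nm = 1e-4,
             contour_length_nm = xmax * (1 + 1e-9))
  upper <- c(persistence_length_nm = 1e3, contour_length_nm = 1e6)
  if ("contour_length_nm" %in% names(fixed) &&
      fixed$contour_length_nm <= xmax)
    stop("fixed contour length must exceed the largest extension",
         call. = FALSE)
  start <- pmin(pmax(start[free], lower[free]), upper[free])
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = lower[free], upper = upper[free],
    fn = function(par) y - full(par),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  est <- fit$par
  rss <- sum(fit$fvec^2)
  n <- length(x)
  se <- rep(NA_real_, n_free)
  names(se) <- free
  if (n > n_free) {
    jtj <- fit$hessian  # Gauss-Newton approximation 2 J'J from nls.lm
    cv <- try(solve(jtj) * 2 * rss / (n - n_free), silent = TRUE)
    if (!inherits(cv, "try-error")) se[] <- sqrt(pmax(diag(cv), 0))
  }
  all_par <- c(as.list(est), fixed)
  unc <- c(persistence_length_nm = NA_real_, contour_length_nm = NA_real_)
  unc[free] <- se
  structure(list(
    params = wlc_params(all_par$persistence_length_nm,
                        all_par$contour_length_nm, temperature_K),
    param_uncertainties = unc,
    residual_norm = sqrt(rss),
    n_points = n,
    fit_window = attr(points, "fit_window") %||% c(1L, n),
    fixed_mask = c(persistence_length_nm = "persistence_length_nm" %in% names(fixed),
                   contour_length_nm = "contour_length_nm" %in% names(fixed)),
    convergence = fit$info
  ), class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf(
    "WLC fit (%d points): Lp = %.4g +/- %.2g nm, Lc = %.4g +/- %.2g nm, |r| = %.3g pN\n",
    x$n_points, x$params$persistence_length_nm,
    x$param_uncertainties[["persistence_length_nm"]],
    x$params$contour_length_nm,
    x$param_uncertainties[["contour_length_nm"]], x$residual_norm))
  invisible(x)
}

.as_fe_points <- function(points) {
  if (is.matrix(points)) points <- as.data.frame(points)
  if (is.list(points) && !is.data.frame(points))
    points <- as.data.frame(points)
  if (!is.data.frame(points))
    stop("points must be a data.frame, matrix or list", call. = FALSE)
  nm <- names(points)
  if (all(c("extension_nm", "force_pN") %in% nm)) {
    out <- points[c("extension_nm", "force_pN")]
  } else if (ncol(points) >= 2L) {
    out <- points[1:2]
    names(out) <- c("extension_nm", "force_pN")
  } else stop("points must have two columns (extension_nm, force_pN)",
              call. = FALSE)
  if (!all(vapply(out, is.numeric, logical(1))) ||
      any(!is.finite(unlist(out))))
    stop("points must be finite numeric values", call. = FALSE)
  out
}

#' Back-of-envelope contour-length estimate
#'
#' Expected contour length of a polypeptide construct:
#' `n_residues * rise_per_residue_nm + linker_nm`, with the conventional
#' 0.32 nm extension per amino acid and an optional fixed linker
#' contribution (e.g. PEG linker plus anchoring domains).
#'
#' @param n_residues Number of residues (>= 0).
#' @param rise_per_residue_nm Contour rise per residue in nm (default 0.32).
#' @param linker_nm Additional linker length in nm (default 0).
#' @return Expected contour length in nm.
#' @examples
#' expected_contour_length(283, 0.32, 20)
#' @export
expected_contour_length <- function(n_residues, rise_per_residue_nm = 0.32,
                                    linker_nm = 0) {
  if (!is.numeric(n_residues) || length(n_residues) != 1L ||
      !is.finite(n_residues) || n_residues < 0 ||
      n_residues != round(n_residues))
    stop("'n_residues' must be a single non-negative integer", call. = FALSE)
  if (!is.numeric(rise_per_residue_nm) || rise_per_residue_nm < 0)
    stop("'rise_per_residue_nm' must be non-negative", call. = FALSE)
  if (!is.numeric(linker_nm) || linker_nm < 0)
    stop("'linker_nm' must be non-negative", call. = FALSE)
  n_residues * rise_per_residue_nm + linker_nm
}
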