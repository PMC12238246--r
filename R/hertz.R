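#' Hertzian sphere-on-half-space contact force
#'
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)` for indentation
#' depth `delta >= 0`, zero otherwise.
#'
#' @param delta_um indentation depth(s) in micrometres.
#' @param E_pa Young's modulus in Pa.
#' @param probe_radius_um spherical probe radius in micrometres.
#' @param poisson Poisson ratio of the sample.
#' @return force in Newtons.
#' @export
hertz_force <- function(delta_um, E_pa, probe_radius_um, poisson) {
  d <- pmax(delta_um, 0) * 1e-6
  (4 / 3) * E_pa / (1 - poisson^2) * sqrt(probe_radius_um * 1e-6) * d^1.5
}

#' Construct a force-indentation curve
#'
#' Approach curves are stored far-from-surface first, deepest indentation
#' last, with `z` the piezo/displacement axis in micrometres and `F` in
#' Newtons.
#'
#' @param z_um strictly monotone displacement axis (um), length >= 20.
#' @param F_N force values (N).
#' @param probe_radius_um spherical probe radius (um).
#' @param poisson sample Poisson ratio.
#' @param meta free-text metadata.
#' @return object of class `force_curve`.
#' @export
force_curve <- function(z_um, F_N, probe_radius_um, poisson, meta = "") {
  if (length(z_um) != length(F_N)) stop("z and F must have equal length")
  if (length(z_um) < 20L) stop("force curve needs at least 20 points")
  dz <- diff(z_um)
  if (!(all(dz > 0) || all(dz < 0))) stop("z must be strictly monotone")
  stop_if_not_scalar_number(probe_radius_um, "probe_radius_um", lo = 1e-9)
  stop_if_not_scalar_number(poisson, "poisson", lo = 0, hi = 0.5)
  structure(list(z_um = as.numeric(z_um), F_N = as.numeric(F_N),
                 probe_radius_um = probe_radius_um, poisson = poisson,
                 meta = meta),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d points, z in [%.3g, %.3g] um, R = %g um, nu = %g\n",
              length(x$z_um), min(x$z_um), max(x$z_um), x$probe_radius_um,
              x$poisson))
  invisible(x)
}

#' Specification for a synthetic force-indentation curve
#'
#' @param E_true true Young's modulus (Pa).
#' @param contact_point contact point along z (um).
#' @param probe_radius spherical probe radius (um).
#' @param poisson sample Poisson ratio (0 to 0.5).
#' @param background_slope linear instrumental background (N per um of z).
#' @param noise_sd additive Gaussian force noise (N).
#' @param n_points number of samples along z.
#' @param z_range total z travel (um), starting at 0.
#' @param seed RNG seed.
#' @return a `force_curve_spec` list.
#' @export
force_curve_spec <- function(E_true, contact_point = 1, probe_radius = 3.31,
                             poisson = 0.3, background_slope = 0,
                             noise_sd = 0, n_points = 200, z_range = 2,
                             seed = 1L) {
  stop_if_not_scalar_number(E_true, "E_true", lo = 1e-12)
  stop_if_not_scalar_number(probe_radius, "probe_radius", lo = 1e-9)
  stop_if_not_scalar_number(poisson, "poisson", lo = 0, hi = 0.5)
  stop_if_not_scalar_number(n_points, "n_points", lo = 20)
  stop_if_not_scalar_number(z_range, "z_range", lo = 1e-9)
  structure(list(E_true = E_true, contact_point = contact_point,
                 probe_radius = probe_radius, poisson = poisson,
                 background_slope = background_slope, noise_sd = noise_sd,
                 n_points = as.integer(n_points), z_range = z_range,
                 seed = as.integer(seed)),
            class = "force_curve_spec")
}

#' Generate a synthetic force-indentation curve
#'
#' Noiseless force is zero before the contact point and Hertzian beyond it
#' (monotone non-decreasing); a linear background and additive Gaussian
#' noise are superimposed when requested.
#'
#' @param spec a [force_curve_spec()].
#' @return a [force_curve()].
#' @export
generate_force_curve <- function(spec) {
  stopifnot(inherits(spec, "force_curve_spec"))
  z <- seq(0, spec$z_range, length.out = spec$n_points)
  F <- hertz_force(z - spec$contact_point, spec$E_true, spec$probe_radius,
                   spec$poisson)
  F <- F + spec$background_slope * z
  if (spec$noise_sd > 0)
    F <- F + with_seed(spec$seed, stats::rnorm(length(z), 0, spec$noise_sd))
  force_curve(z, F, spec$probe_radius, spec$poisson,
              meta = sprintf("synthetic E=%g Pa seed=%d", spec$E_true, spec$seed))
}

#' Subtract a linear instrumental background
#'
#' Fits a straight line to the non-contact (baseline) fraction of the
#' approach curve and subtracts it from all points. With curves stored
#' far-from-surface first (this package's convention) the baseline is the
#' head of the record; instrument exports that store the deepest point first
#' carry it in the tail.
#'
#' @param curve a `force_curve`.
#' @param tail_fraction fraction of points used for the line fit
#'   (default 0.45, i.e., the conventional 40-50% of the record).
#' @param baseline `"head"` (default) or `"tail"`: which end of the record
#'   holds the non-contact region.
#' @return the background-subtracted `force_curve`, with the fitted
#'   `background` line `c(slope, intercept)` attached as an attribute.
#' @export
subtract_background <- function(curve, tail_fraction = 0.45,
                                baseline = c("head", "tail")) {
  stopifnot(inherits(curve, "force_curve"))
  baseline <- match.arg(baseline)
  stop_if_not_scalar_number(tail_fraction, "tail_fraction", lo = 0.01, hi = 0.9)
  n <- length(curve$z_um)
  k <- round(tail_fraction * n)
  if (k < 5L) stop("baseline region shorter than 5 points")
  sel <- if (baseline == "head") seq_len(k) else (n - k + 1L):n
  fit <- stats::lm.fit(cbind(1, curve$z_um[sel]), curve$F_N[sel])
  coefs <- fit$coefficients
  curve$F_N <- curve$F_N - (coefs[1] + coefs[2] * curve$z_um)
  attr(curve, "background") <- c(slope = unname(coefs[2]),
                                 intercept = unname(coefs[1]))
  curve
}

new_hertz_fit <- function(E_pa = NA_real_, contact_point_um = NA_real_,
                          r_squared = NA_real_, background = c(NA, NA),
                          depth_window_um = c(0, Inf), converged = FALSE,
                          accepted = NA) {
  structure(list(E_pa = E_pa, contact_point_um = contact_point_um,
                 r_squared = r_squared, background = background,
                 depth_window_um = depth_window_um, converged = converged,
                 accepted = accepted),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hertz_fit> not converged\n")
  } else {
    cat(sprintf("<hertz_fit> E = %.4g Pa, contact point = %.4g um, R2 = %.4f%s\n",
                x$E_pa, x$contact_point_um, x$r_squared,
                if (isFALSE(x$accepted)) " (rejected)" else ""))
  }
  invisible(x)
}

hertz_model_fit <- function(z, F, R_um, nu, cp_lower, cp_upper) {
  prefac <- (4 / 3) / (1 - nu^2) * sqrt(R_um * 1e-6)
  # initial values: linearize F^(2/3) = (prefac*E)^(2/3) * (z - d0) * 1e-6^(...)
  Fmax <- max(F)
  if (!is.finite(Fmax) || Fmax <= 0) return(NULL)
  top <- F > 0.2 * Fmax
  if (sum(top) < 3L) return(NULL)
  y23 <- F[top]^(2 / 3)
  lin <- stats::lm.fit(cbind(1, z[top]), y23)
  slope <- unname(lin$coefficients[2])
  if (!is.finite(slope) || slope <= 0) return(NULL)
  cp0 <- unname(-lin$coefficients[1] / slope)
  cp0 <- min(max(cp0, cp_lower), cp_upper)
  E0 <- slope^1.5 / (prefac * (1e-6)^1.5)
  if (!is.finite(E0) || E0 <= 0) E0 <- 1e3
  dat <- data.frame(z = z, F = F)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      F ~ prefac * E * (pmax(z - cp, 0) * 1e-6)^1.5,
      data = dat, start = list(E = E0, cp = cp0),
      lower = c(E = 1e-6, cp = cp_lower),
      upper = c(E = Inf, cp = cp_upper),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  list(E = unname(co["E"]), cp = unname(co["cp"]))
}

r_squared_of <- function(F, Fhat) {
  ss_tot <- sum((F - mean(F))^2)
  if (ss_tot <= 0) return(NA_real_)
  max(0, min(1, 1 - sum((F - Fhat)^2) / ss_tot))
}

#' Fit the Hertz model to a whole approach curve
#'
#' Nonlinear least squares over Young's modulus and the contact point, with
#' the model force zero before contact. Intended for background-subtracted
#' curves on stiff extracellular matrix (Poisson ratio 0.3, colloidal
#' probe); the whole curve participates in the fit.
#'
#' @param curve a `force_curve` (background already subtracted).
#' @param depth_cap_um optionally restrict the fit to indentations at most
#'   this deep past the contact point (one refit pass).
#' @return a `hertz_fit` (with `converged = FALSE` and no modulus on
#'   degenerate input or optimizer failure).
#' @export
fit_hertz <- function(curve, depth_cap_um = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z_um; F <- curve$F_N
  if (all(F == 0) || !all(is.finite(F))) return(new_hertz_fit())
  res <- hertz_model_fit(z, F, curve$probe_radius_um, curve$poisson,
                         cp_lower = min(z), cp_upper = max(z))
  if (is.null(res)) return(new_hertz_fit())
  if (!is.null(depth_cap_um)) {
    sel <- z <= res$cp + depth_cap_um
    if (sum(sel) >= 10L) {
      res2 <- hertz_model_fit(z[sel], F[sel], curve$probe_radius_um,
                              curve$poisson, min(z), max(z))
      if (!is.null(res2)) res <- res2
    }
  }
  Fhat <- hertz_force(z - res$cp, res$E, curve$probe_radius_um, curve$poisson)
  bg <- attr(curve, "background")
  new_hertz_fit(E_pa = res$E, contact_point_um = res$cp,
                r_squared = r_squared_of(F, Fhat),
                background = if (is.null(bg)) c(NA, NA) else bg,
                depth_window_um = c(0, if (is.null(depth_cap_um)) Inf
                                    else depth_cap_um),
                converged = TRUE, accepted = TRUE)
}

#' Fit the Hertz model under the monolayer nanoindentation protocol
#'
#' Cell-monolayer protocol: incompressible sample (Poisson ratio 0.5 by
#' default), contact point admissible only where the load does not exceed
#' `max_load_fraction` of the maximum load, fit restricted to indentation
#' depths within `depth_window` past contact, and the result only accepted
#' when R-squared exceeds `r2_min`.
#'
#' @param curve a `force_curve`.
#' @param depth_window_um `c(lo, hi)` indentation window in um past contact
#'   (default 0 to 3).
#' @param poisson Poisson ratio used for the fit (default 0.5).
#' @param max_load_fraction contact point must lie where the load is at most
#'   this fraction of the maximum (default 0.3).
#' @param r2_min acceptance gate on R-squared (default 0.95).
#' @return a `hertz_fit`; `accepted` is FALSE when the gate fails,
#'   `converged` FALSE when no admissible contact point exists.
#' @export
fit_hertz_nanoindentation <- function(curve, depth_window_um = c(0, 3),
                                      poisson = 0.5, max_load_fraction = 0.3,
                                      r2_min = 0.95) {
  stopifnot(inherits(curve, "force_curve"))
  if (length(depth_window_um) != 2L || depth_window_um[2] <= depth_window_um[1])
    stop("degenerate depth window")
  z <- curve$z_um; F <- curve$F_N
  if (all(F == 0) || !all(is.finite(F))) return(new_hertz_fit())
  Fmax <- max(F)
  adm <- which(F <= max_load_fraction * Fmax)
  if (!length(adm)) return(new_hertz_fit())
  cp_lower <- min(z[adm]); cp_upper <- max(z[adm])
  res <- hertz_model_fit(z, F, curve$probe_radius_um, poisson,
                         cp_lower, cp_upper)
  if (is.null(res)) return(new_hertz_fit())
  for (pass in 1:2) {
    sel <- z - res$cp >= depth_window_um[1] & z - res$cp <= depth_window_um[2]
    if (sum(sel) < 10L) break
    res2 <- hertz_model_fit(z[sel], F[sel], curve$probe_radius_um, poisson,
                            cp_lower, cp_upper)
    if (is.null(res2)) break
    res <- res2
  }
  sel <- z - res$cp >= depth_window_um[1] & z - res$cp <= depth_window_um[2]
  Fhat <- (4 / 3) * res$E / (1 - poisson^2) *
    sqrt(curve$probe_radius_um * 1e-6) * (pmax(z - res$cp, 0) * 1e-6)^1.5
  r2 <- r_squared_of(F[sel], Fhat[sel])
  new_hertz_fit(E_pa = res$E, contact_point_um = res$cp, r_squared = r2,
                depth_window_um = depth_window_um, converged = TRUE,
                accepted = is.finite(r2) && r2 > r2_min)
}

#' Most frequent (mode) stiffness of a fitted population
#'
#' Histogram-peak mode with quadratic refinement on log-spaced bins,
#' appropriate for the broad right-skewed stiffness distributions of
#' biological samples.
#'
#' @param values accepted Young's moduli (Pa); at least 10 required.
#' @return mode stiffness in Pa.
#' @export
mode_stiffness <- function(values) {
  values <- values[is.finite(values) & values > 0]
  if (length(values) < 10L)
    stop("fewer than 10 accepted fits; use the median instead")
  density_mode(values, log_bins = TRUE)
}
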