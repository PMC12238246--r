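#' Construct a regular-grid 2-D vector field
#'
#' Shared container for bead displacement fields (um), traction fields (Pa)
#' and stress fields (Pa) on a square grid.
#'
#' @param vx,vy component matrices (rows = y, cols = x).
#' @param spacing_um grid spacing in micrometres.
#' @param role one of `"displacement"`, `"traction"`, `"stress_normal"`.
#' @return object of class `vector_field` with coordinate vectors `x_um`,
#'   `y_um` at pixel-center positions.
#' @export
vector_field <- function(vx, vy, spacing_um, role = c("displacement",
                                                      "traction",
                                                      "stress_normal")) {
  role <- match.arg(role)
  stopifnot(is.matrix(vx), is.matrix(vy), all(dim(vx) == dim(vy)))
  if (!all(is.finite(vx)) || !all(is.finite(vy)))
    stop("vector field contains non-finite values")
  stop_if_not_scalar_number(spacing_um, "spacing_um", lo = 1e-9)
  structure(list(vx = vx, vy = vy, spacing_um = spacing_um, role = role,
                 x_um = (seq_len(ncol(vx)) - 0.5) * spacing_um,
                 y_um = (seq_len(nrow(vx)) - 0.5) * spacing_um),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  mag <- sqrt(x$vx^2 + x$vy^2)
  cat(sprintf("<vector_field:%s> %d x %d, spacing %g um, mean |v| = %.4g, max |v| = %.4g\n",
              x$role, nrow(x$vx), ncol(x$vx), x$spacing_um, mean(mag), max(mag)))
  invisible(x)
}

#' Mean traction magnitude
#'
#' @param field a `vector_field` (traction, Pa).
#' @param mask optional logical matrix selecting grid points.
#' @return mean of `|T|` over the mask (whole field by default), in the
#'   field's units.
#' @export
mean_traction <- function(field, mask = NULL) {
  stopifnot(inherits(field, "vector_field"))
  mag <- sqrt(field$vx^2 + field$vy^2)
  if (is.null(mask)) return(mean(mag))
  stopifnot(is.logical(mask), all(dim(mask) == dim(mag)))
  if (!any(mask)) stop("empty mask")
  mean(mag[mask])
}

#' Specification for a synthetic traction scene
#'
#' Defines a balanced traction pattern on an elastic half-space (the
#' polyacrylamide gel) from which bead displacement is forward-computed.
#'
#' @param pattern `"gaussian_dipole"` (two opposing Gaussian lobes, the
#'   far-field of a contractile cell pair), `"uniform_disc"` (uniform inward
#'   radial traction on an annulus, a contracting colony edge),
#'   `"gaussian_quadrupole"` (a contractile and an extensile dipole, zero
#'   net moment) or `"zero"`.
#' @param peak_traction peak traction magnitude (Pa).
#' @param gel_E gel Young's modulus (Pa).
#' @param gel_poisson gel Poisson ratio (default 0.5, incompressible
#'   polyacrylamide).
#' @param grid_n grid points per side (powers of 2 recommended).
#' @param grid_spacing_um grid spacing (um).
#' @param seed RNG seed (reserved for noise additions downstream).
#' @return a `traction_spec` list.
#' @export
traction_spec <- function(pattern = c("gaussian_dipole", "uniform_disc",
                                      "gaussian_quadrupole", "zero"),
                          peak_traction = 100, gel_E = 4000,
                          gel_poisson = 0.5, grid_n = 64,
                          grid_spacing_um = 4, seed = 1L) {
  pattern <- match.arg(pattern)
  stop_if_not_scalar_number(peak_traction, "peak_traction", lo = 0)
  stop_if_not_scalar_number(gel_E, "gel_E", lo = 1e-9)
  stop_if_not_scalar_number(gel_poisson, "gel_poisson", lo = 0, hi = 0.5)
  stop_if_not_scalar_number(grid_n, "grid_n", lo = 8)
  structure(list(pattern = pattern, peak_traction = peak_traction,
                 gel_E = gel_E, gel_poisson = gel_poisson,
                 grid_n = as.integer(grid_n),
                 grid_spacing_um = grid_spacing_um, seed = as.integer(seed)),
            class = "traction_spec")
}

traction_pattern <- function(spec) {
  n <- spec$grid_n; d <- spec$grid_spacing_um; L <- n * d
  xy <- (seq_len(n) - 0.5) * d
  X <- matrix(rep(xy, each = n), n)   # x varies along columns
  Y <- matrix(rep(xy, times = n), n)
  tx <- ty <- matrix(0, n, n)
  A <- spec$peak_traction
  gauss <- function(x0, y0, s) exp(-((X - x0)^2 + (Y - y0)^2) / (2 * s^2))
  if (spec$pattern == "gaussian_dipole") {
    s <- 0.08 * L
    tx <- A * (gauss(0.35 * L, 0.5 * L, s) - gauss(0.65 * L, 0.5 * L, s))
  } else if (spec$pattern == "gaussian_quadrupole") {
    s <- 0.06 * L
    tx <- A * (gauss(0.30 * L, 0.35 * L, s) - gauss(0.70 * L, 0.35 * L, s)) -
          A * (gauss(0.30 * L, 0.65 * L, s) - gauss(0.70 * L, 0.65 * L, s))
  } else if (spec$pattern == "uniform_disc") {
    r <- sqrt((X - L / 2)^2 + (Y - L / 2)^2)
    sel <- r >= 0.15 * L & r <= 0.30 * L
    tx[sel] <- -A * (X[sel] - L / 2) / r[sel]
    ty[sel] <- -A * (Y[sel] - L / 2) / r[sel]
  }
  # remove any residual net force (discretization of balanced patterns)
  tx <- tx - mean(tx); ty <- ty - mean(ty)
  list(tx = tx, ty = ty)
}

# Fourier-space Boussinesq surface Green tensor on the padded DFT grid.
# G_ij(k) = 2 (1 + nu) / (E k^3) * (k^2 delta_ij - nu k_i k_j)  [m / Pa]
boussinesq_kernel <- function(N, d_m, E, nu) {
  f <- c(0:(N / 2 - 1), -(N / 2):-1) / (N * d_m)
  k_x <- matrix(rep(2 * pi * f, each = N), N)   # x along columns
  k_y <- matrix(rep(2 * pi * f, times = N), N)
  k <- sqrt(k_x^2 + k_y^2)
  k[1, 1] <- 1  # placeholder; the DC entries are zeroed below
  pref <- 2 * (1 + nu) / (E * k^3)
  gxx <- pref * (k^2 - nu * k_x^2)
  gyy <- pref * (k^2 - nu * k_y^2)
  gxy <- pref * (-nu * k_x * k_y)
  gxx[1, 1] <- 0; gyy[1, 1] <- 0; gxy[1, 1] <- 0
  list(gxx = gxx, gyy = gyy, gxy = gxy)
}

pad2 <- function(m) {
  n <- nrow(m)
  out <- matrix(0, 2 * n, 2 * n)
  out[seq_len(n), seq_len(n)] <- m
  out
}

#' Forward-compute bead displacement from a known traction field
#'
#' Convolves a balanced traction field with the Boussinesq half-space
#' surface Green tensor in Fourier space. The convolution is evaluated on
#' an internal grid `fine_factor` times finer than the measurement grid
#' (zero-padded by a factor of two to suppress periodic wrap-around) and
#' the displacement is then sampled at the measurement grid points,
#' emulating a bead field measured at finite resolution from a continuum
#' deformation.
#'
#' @param spec a [traction_spec()].
#' @param fine_factor internal refinement of the forward model (default 4).
#' @return list with `truth_traction` (the pattern sampled at measurement
#'   grid points, Pa) and `displacement` (um), both `vector_field`s on the
#'   measurement grid.
#' @export
generate_traction_scene <- function(spec, fine_factor = 4L) {
  stopifnot(inherits(spec, "traction_spec"))
  f <- as.integer(fine_factor)
  stopifnot(f >= 1L)
  fine <- spec
  fine$grid_n <- spec$grid_n * f
  fine$grid_spacing_um <- spec$grid_spacing_um / f
  tp <- traction_pattern(fine)
  net <- sqrt(sum(tp$tx)^2 + sum(tp$ty)^2)
  scale <- mean(sqrt(tp$tx^2 + tp$ty^2))
  if (scale > 0 && net / (scale * length(tp$tx)) > 1e-6)
    stop("unbalanced traction pattern: net force must vanish")
  nf <- fine$grid_n
  d_m <- fine$grid_spacing_um * 1e-6
  ker <- boussinesq_kernel(2 * nf, d_m, spec$gel_E, spec$gel_poisson)
  Tx <- stats::fft(pad2(tp$tx)); Ty <- stats::fft(pad2(tp$ty))
  Ux <- ker$gxx * Tx + ker$gxy * Ty
  Uy <- ker$gxy * Tx + ker$gyy * Ty
  Ux[1, 1] <- 0; Uy[1, 1] <- 0
  ux <- Re(stats::fft(Ux, inverse = TRUE))[seq_len(nf), seq_len(nf)] / (2 * nf)^2
  uy <- Re(stats::fft(Uy, inverse = TRUE))[seq_len(nf), seq_len(nf)] / (2 * nf)^2
  # sample at measurement grid points (bilinear; the field is smooth)
  n <- spec$grid_n
  coarse <- (seq_len(n) - 0.5) * spec$grid_spacing_um
  finex <- (seq_len(nf) - 0.5) * fine$grid_spacing_um
  ux_c <- bilinear_sample(ux, finex, coarse)
  uy_c <- bilinear_sample(uy, finex, coarse)
  truth <- traction_pattern(spec)
  list(truth_traction = vector_field(truth$tx, truth$ty,
                                     spec$grid_spacing_um, "traction"),
       displacement = vector_field(ux_c * 1e6, uy_c * 1e6,
                                   spec$grid_spacing_um, "displacement"))
}

# Sample matrix m (defined at coordinates src x src) at coordinates dst.
bilinear_sample <- function(m, src, dst) {
  idx <- findInterval(dst, src, all.inside = TRUE)
  w <- (dst - src[idx]) / (src[idx + 1] - src[idx])
  w <- pmin(pmax(w, 0), 1)
  rows <- m[idx, , drop = FALSE] * (1 - w) + m[idx + 1, , drop = FALSE] * w
  rows[, idx, drop = FALSE] %*% diag(1 - w, length(w)) +
    rows[, idx + 1, drop = FALSE] %*% diag(w, length(w))
}

#' Gel and monolayer mechanical parameters
#'
#' @param E_gel gel Young's modulus (Pa).
#' @param poisson_gel gel Poisson ratio (default 0.5; polyacrylamide is
#'   nearly incompressible).
#' @param height_um monolayer height h (um), the thickness over which
#'   traction is balanced by intercellular stress.
#' @return a `gel_spec` list.
#' @export
gel_spec <- function(E_gel = 4000, poisson_gel = 0.5, height_um = 12) {
  stop_if_not_scalar_number(E_gel, "E_gel", lo = 1e-9)
  stop_if_not_scalar_number(poisson_gel, "poisson_gel", lo = 1e-6, hi = 0.5)
  stop_if_not_scalar_number(height_um, "height_um", lo = 1e-9)
  structure(list(E_gel = E_gel, poisson_gel = poisson_gel,
                 height_um = height_um), class = "gel_spec")
}

#' Fourier-transform traction cytometry
#'
#' Inverts a regular-grid displacement field into traction by
#' Tikhonov-regularized inversion of the Boussinesq half-space Green tensor
#' in Fourier space (zero-padding factor two). The zero-frequency component
#' is zero throughout, enforcing a net-force-free traction field.
#'
#' The default `"windowed"` method accounts for the finite field of view:
#' the measured displacement is the restriction of the deformation to the
#' imaging window, so the Tikhonov problem
#' `min || crop(G * T) - u ||^2 + lambda^2 ||T||^2` is solved by conjugate
#' gradients with the Green convolution applied by FFT. The `"direct"`
#' method is the classical per-wavevector algebraic inverse, applied after
#' extending the displacement across the padding band with a raised-cosine
#' taper; it is faster but attributes the window edge to the data, so it
#' needs stronger regularization.
#'
#' @param displacement a `vector_field` (um) on a square grid.
#' @param gel a [gel_spec()].
#' @param lambda Tikhonov regularization parameter (units of the Green
#'   tensor, m/Pa). `0` is appropriate for noiseless synthetic data with
#'   the `"windowed"` method; `"l_curve"` selects the corner of the
#'   L-curve over a log-spaced grid.
#' @param method `"windowed"` (default) or `"direct"`.
#' @param maxit,tol conjugate-gradient iteration controls (windowed method).
#' @return a traction `vector_field` (Pa) with the chosen `lambda` attached
#'   as an attribute.
#' @export
fttc <- function(displacement, gel, lambda = 0,
                 method = c("windowed", "direct"), maxit = 200, tol = 1e-10) {
  stopifnot(inherits(displacement, "vector_field"), inherits(gel, "gel_spec"))
  method <- match.arg(method)
  if (nrow(displacement$vx) != ncol(displacement$vx))
    stop("displacement grid must be square (equal spacing in x and y)")
  if (is.numeric(lambda) && lambda < 0) stop("lambda must be non-negative")
  n <- nrow(displacement$vx)
  d_m <- displacement$spacing_um * 1e-6
  ker <- boussinesq_kernel(2 * n, d_m, gel$E_gel, gel$poisson_gel)
  ux <- displacement$vx * 1e-6; uy <- displacement$vy * 1e-6

  solve_for <- if (method == "windowed") {
    function(lam) fttc_cg(ux, uy, ker, lam, maxit, tol)
  } else {
    function(lam) fttc_direct(ux, uy, ker, lam)
  }
  if (identical(lambda, "l_curve")) {
    gmag <- stats::quantile(abs(ker$gxx[abs(ker$gxx) > 0]), 0.9)
    lams <- unname(gmag * 10^seq(-4, 1, length.out = 15))
    res <- tn <- numeric(length(lams))
    for (i in seq_along(lams)) {
      s <- solve_for(lams[i])
      r <- green_apply(s$tx, s$ty, ker)
      res[i] <- sqrt(sum((r$ux[seq_len(n), seq_len(n)] - ux)^2 +
                         (r$uy[seq_len(n), seq_len(n)] - uy)^2))
      tn[i] <- sqrt(sum(s$tx^2 + s$ty^2))
    }
    lr <- log(pmax(res, .Machine$double.xmin))
    lt <- log(pmax(tn, .Machine$double.xmin))
    curv <- rep(NA_real_, length(lams))
    for (i in 2:(length(lams) - 1)) {
      v1 <- c(lr[i] - lr[i - 1], lt[i] - lt[i - 1])
      v2 <- c(lr[i + 1] - lr[i], lt[i + 1] - lt[i])
      ang <- atan2(v2[2], v2[1]) - atan2(v1[2], v1[1])
      curv[i] <- abs(atan2(sin(ang), cos(ang)))
    }
    lambda <- if (any(is.finite(curv))) lams[which.max(curv)] else lams[1]
  }
  s <- solve_for(lambda)
  # enforce the net-force-free contract on the reported window
  out <- vector_field(s$tx - mean(s$tx), s$ty - mean(s$ty),
                      displacement$spacing_um, "traction")
  attr(out, "lambda") <- lambda
  out
}

# Padded Green convolution of an n-grid traction; returns the full 2n grid.
green_apply <- function(tx, ty, ker) {
  N <- nrow(ker$gxx)
  Tx <- stats::fft(pad2(tx)); Ty <- stats::fft(pad2(ty))
  Ux <- ker$gxx * Tx + ker$gxy * Ty
  Uy <- ker$gxy * Tx + ker$gyy * Ty
  list(ux = Re(stats::fft(Ux, inverse = TRUE)) / N^2,
       uy = Re(stats::fft(Uy, inverse = TRUE)) / N^2)
}

# Windowed Tikhonov inversion by conjugate gradients on the normal
# equations; the adjoint of window restriction is zero-extension and the
# Green tensor is symmetric.
fttc_cg <- function(ux, uy, ker, lambda, maxit, tol) {
  n <- nrow(ux); N <- nrow(ker$gxx)
  crop <- function(m) m[seq_len(n), seq_len(n)]
  AtA <- function(tx, ty) {
    u <- green_apply(tx, ty, ker)
    r <- green_apply(crop(u$ux), crop(u$uy), ker)
    list(tx = crop(r$ux) + lambda^2 * tx, ty = crop(r$uy) + lambda^2 * ty)
  }
  b <- green_apply(ux, uy, ker)
  X <- list(tx = matrix(0, n, n), ty = matrix(0, n, n))
  R <- list(tx = crop(b$ux), ty = crop(b$uy))
  P <- R
  rs <- sum(R$tx^2 + R$ty^2); rs0 <- rs
  if (rs0 == 0) return(X)
  for (it in seq_len(maxit)) {
    Ap <- AtA(P$tx, P$ty)
    alpha <- rs / sum(P$tx * Ap$tx + P$ty * Ap$ty)
    X$tx <- X$tx + alpha * P$tx; X$ty <- X$ty + alpha * P$ty
    R$tx <- R$tx - alpha * Ap$tx; R$ty <- R$ty - alpha * Ap$ty
    rs_new <- sum(R$tx^2 + R$ty^2)
    if (rs_new < tol * rs0) break
    P$tx <- R$tx + (rs_new / rs) * P$tx
    P$ty <- R$ty + (rs_new / rs) * P$ty
    rs <- rs_new
  }
  X
}

# Classical per-wavevector Tikhonov inverse with raised-cosine edge taper.
fttc_direct <- function(ux, uy, ker, lambda) {
  n <- nrow(ux); N <- nrow(ker$gxx)
  pad_taper <- function(m) {
    out <- matrix(0, N, N)
    out[seq_len(n), seq_len(n)] <- m
    out[(n + 1):N, seq_len(n)] <- matrix(m[n, ], n, n, byrow = TRUE)
    out[seq_len(n), (n + 1):N] <- matrix(m[, n], n, n)
    out[(n + 1):N, (n + 1):N] <- m[n, n]
    w1 <- rep(1, N)
    w1[n + seq_len(n)] <- 0.5 * (1 + cos(pi * seq_len(n) / n))
    out * outer(w1, w1, pmin)
  }
  Ux <- stats::fft(pad_taper(ux)); Uy <- stats::fft(pad_taper(uy))
  a <- ker$gxx; b <- ker$gxy; g <- ker$gyy
  m11 <- a * a + b * b + lambda^2
  m12 <- b * (a + g)
  m22 <- g * g + b * b + lambda^2
  det <- m11 * m22 - m12^2
  det[1, 1] <- 1
  rx <- a * Ux + b * Uy; ry <- b * Ux + g * Uy
  Txh <- (m22 * rx - m12 * ry) / det
  Tyh <- (m11 * ry - m12 * rx) / det
  Txh[1, 1] <- 0; Tyh[1, 1] <- 0
  list(tx = Re(stats::fft(Txh, inverse = TRUE))[seq_len(n), seq_len(n)] / N^2,
       ty = Re(stats::fft(Tyh, inverse = TRUE))[seq_len(n), seq_len(n)] / N^2)
}
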