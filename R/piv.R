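#' Render a synthetic bead image
#'
#' Beads are drawn as isotropic Gaussian spots on a dark background, the
#' appearance of fluorescent microbeads embedded in a traction-force gel.
#'
#' @param positions n x 2 matrix of bead centers `(x, y)` in pixels.
#' @param size_px image side length.
#' @param sigma_px Gaussian spot width (default 1.5 px).
#' @param intensity peak intensity per bead.
#' @return numeric matrix (rows = y).
#' @export
render_bead_image <- function(positions, size_px, sigma_px = 1.5,
                              intensity = 1) {
  stopifnot(is.matrix(positions), ncol(positions) == 2)
  img <- matrix(0, size_px, size_px)
  r <- ceiling(4 * sigma_px)
  for (i in seq_len(nrow(positions))) {
    x0 <- positions[i, 1]; y0 <- positions[i, 2]
    cx <- round(x0); cy <- round(y0)
    xs <- max(1, cx - r):min(size_px, cx + r)
    ys <- max(1, cy - r):min(size_px, cy + r)
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - x0)^2 / (2 * sigma_px^2))
    gy <- exp(-(ys - y0)^2 / (2 * sigma_px^2))
    img[ys, xs] <- img[ys, xs] + intensity * outer(gy, gx)
  }
  img
}

#' Displacement field by particle image velocimetry
#'
#' Window-wise FFT cross-correlation between a reference (relaxed gel) and
#' a deformed bead image, with three-point Gaussian sub-pixel peak
#' refinement, peak-ratio validation with neighbor inpainting of invalid
#' vectors, and drift removal by subtracting the median vector.
#'
#' @param img_ref,img_def same-size single-channel images (matrices).
#' @param window_px interrogation window size (default 32).
#' @param overlap window overlap fraction (default 0.5).
#' @param pixel_size_um physical pixel size; output is in um.
#' @param peak_ratio_min smallest admissible ratio of the first to second
#'   correlation peak (default 1.3); windows below it are inpainted from
#'   the median of their valid neighbors.
#' @param remove_drift subtract the median vector (default TRUE).
#' @return a displacement `vector_field` (um) with the number of inpainted
#'   windows attached as attribute `"n_invalid"`.
#' @export
piv_displacement <- function(img_ref, img_def, window_px = 32L,
                             overlap = 0.5, pixel_size_um = 1,
                             peak_ratio_min = 1.3, remove_drift = TRUE) {
  stopifnot(is.matrix(img_ref), all(dim(img_ref) == dim(img_def)))
  w <- as.integer(window_px)
  stride <- max(1L, as.integer(round(w * (1 - overlap))))
  starts_r <- seq(1L, nrow(img_ref) - w + 1L, by = stride)
  starts_c <- seq(1L, ncol(img_ref) - w + 1L, by = stride)
  nr <- length(starts_r); nc <- length(starts_c)
  ux <- uy <- matrix(NA_real_, nr, nc)
  valid <- matrix(TRUE, nr, nc)
  maxshift <- w %/% 3L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a <- img_ref[starts_r[i]:(starts_r[i] + w - 1L),
                 starts_c[j]:(starts_c[j] + w - 1L)]
    b <- img_def[starts_r[i]:(starts_r[i] + w - 1L),
                 starts_c[j]:(starts_c[j] + w - 1L)]
    a <- a - mean(a); b <- b - mean(b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      valid[i, j] <- FALSE
      next
    }
    # linear (zero-padded) cross-correlation to avoid wrap-around bias
    w2 <- 2L * w
    ap <- matrix(0, w2, w2); ap[seq_len(w), seq_len(w)] <- a
    bp <- matrix(0, w2, w2); bp[seq_len(w), seq_len(w)] <- b
    C <- Re(stats::fft(Conj(stats::fft(ap)) * stats::fft(bp),
                       inverse = TRUE)) / w2^2
    sh <- c(0:(w2 / 2 - 1), -(w2 / 2):-1)
    # unbiased estimate: divide by the linear-correlation overlap area
    ov <- pmax(w - abs(sh), 1L)
    C <- C / outer(ov, ov)
    adm <- abs(sh) <= maxshift
    Cadm <- C[adm, adm]
    pk <- which(Cadm == max(Cadm), arr.ind = TRUE)[1, , drop = TRUE]
    shr <- sh[adm][pk[1]]; shc <- sh[adm][pk[2]]
    # peak ratio validation: second peak outside a 3-px exclusion zone
    shm_r <- matrix(sh[adm], nrow = sum(adm), ncol = sum(adm))
    shm_c <- t(shm_r)
    excl <- abs(shm_r - shr) <= 3 & abs(shm_c - shc) <= 3
    second <- suppressWarnings(max(Cadm[!excl]))
    if (!is.finite(second) || second <= 0 ||
        max(Cadm) / second >= peak_ratio_min) {
      # sub-pixel refinement (3-point Gaussian; parabolic fallback)
      idx <- function(s) ((s %% w2) + w2) %% w2 + 1L
      refine <- function(cm, c0, cp) {
        if (cm > 0 && c0 > 0 && cp > 0 && 2 * log(c0) - log(cm) - log(cp) > 0)
          (log(cm) - log(cp)) / (2 * (log(cm) - 2 * log(c0) + log(cp)))
        else if ((cm - 2 * c0 + cp) < 0)
          0.5 * (cm - cp) / (cm - 2 * c0 + cp)
        else 0
      }
      dr <- refine(C[idx(shr - 1), idx(shc)], C[idx(shr), idx(shc)],
                   C[idx(shr + 1), idx(shc)])
      dc <- refine(C[idx(shr), idx(shc - 1)], C[idx(shr), idx(shc)],
                   C[idx(shr), idx(shc + 1)])
      uy[i, j] <- shr + dr
      ux[i, j] <- shc + dc
    } else {
      valid[i, j] <- FALSE
    }
  }
  # inpaint invalid vectors from the median of their valid neighbors
  if (any(!valid)) {
    for (k in which(!valid)) {
      i <- ((k - 1L) %% nr) + 1L; j <- ((k - 1L) %/% nr) + 1L
      ri <- max(1, i - 1):min(nr, i + 1); rj <- max(1, j - 1):min(nc, j + 1)
      nb_u <- ux[ri, rj][valid[ri, rj]]
      nb_v <- uy[ri, rj][valid[ri, rj]]
      ux[i, j] <- if (length(nb_u)) stats::median(nb_u) else 0
      uy[i, j] <- if (length(nb_v)) stats::median(nb_v) else 0
    }
  }
  if (remove_drift) {
    ux <- ux - stats::median(ux)
    uy <- uy - stats::median(uy)
  }
  out <- vector_field(ux * pixel_size_um, uy * pixel_size_um,
                      spacing_um = stride * pixel_size_um, "displacement")
  attr(out, "n_invalid") <- sum(!valid)
  out
}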