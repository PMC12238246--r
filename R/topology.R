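#' Shape-factor summary of a filtered tessellation
#'
#' The shape index of a cell is its perimeter divided by the square root of
#' its area; 3.7224 for a regular hexagon, 4 for a square, larger for
#' elongated cells. Vertex-model theory places the onset of epithelial
#' fluidity near 3.81, so per-image means in the 3.8-4.0 range discriminate
#' mechanical states.
#'
#' @param t a `cell_tessellation` after [filter_cells()].
#' @return list with `mean`, `median` and the vector `values` over the
#'   analysis set.
#' @export
shape_factor_summary <- function(t) {
  cells <- analysis_set(t)
  p <- cells$shape_index
  list(mean = mean(p), median = stats::median(p), values = p)
}

#' Probability density of rescaled cell areas
#'
#' Normalized histogram density of `A_i / <A>` on (0, `max_rescaled`].
#' Pooling across images is done by concatenating per-image-rescaled values
#' before calling this function.
#'
#' @param rescaled either a `cell_tessellation` (analysis set used) or a
#'   numeric vector of rescaled areas.
#' @param bin_width histogram bin width (default 0.1).
#' @param max_rescaled upper edge of the support (default 2).
#' @return list with `bin_centers`, `density` (integrating to 1 over the
#'   support), `bin_width` and `mode` (bin-center of the peak).
#' @export
rescaled_area_pdf <- function(rescaled, bin_width = 0.1, max_rescaled = 2) {
  if (inherits(rescaled, "cell_tessellation"))
    rescaled <- analysis_set(rescaled)$rescaled_area
  x <- rescaled[rescaled > 0 & rescaled <= max_rescaled]
  breaks <- seq(0, max_rescaled, by = bin_width)
  if (max(breaks) < max_rescaled) breaks <- c(breaks, max_rescaled)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  dens <- h$counts / (sum(h$counts) * diff(h$breaks))
  list(bin_centers = h$mids, density = dens, bin_width = bin_width,
       mode = h$mids[which.max(dens)])
}

#' Most probable value of a sample via histogram peak
#'
#' Estimates the mode from a histogram with Freedman-Diaconis bin widths,
#' refined by quadratic interpolation through the peak bin and its two
#' neighbors. Used to define the rescaled perimeter (each perimeter divided
#' by the most probable perimeter of its condition).
#'
#' @param x numeric sample (e.g., cell perimeters in um).
#' @param log_bins use log-spaced bins (appropriate for broad, positive,
#'   right-skewed samples such as stiffness values). Default FALSE.
#' @return scalar mode estimate. With a tie between several equally tall
#'   bins the smallest mode is returned with a warning.
#' @export
density_mode <- function(x, log_bins = FALSE) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values")
  if (log_bins && any(x <= 0)) stop("log-spaced bins require positive values")
  if (length(unique(x)) == 1L) return(x[1])
  # effectively constant samples (spread at floating-point noise level)
  if (diff(range(x)) <= 1e-8 * max(abs(x)))
    return(stats::median(x))
  t <- if (log_bins) log(x) else x
  iqr <- stats::IQR(t)
  bw <- if (iqr > 0) 2 * iqr / length(t)^(1 / 3) else diff(range(t)) / 10
  breaks <- seq(min(t) - bw / 2, max(t) + bw, by = bw)
  h <- graphics::hist(t, breaks = breaks, plot = FALSE)
  # density on the original (linear) measurement scale
  dens <- h$counts / diff(if (log_bins) exp(h$breaks) else h$breaks)
  nb <- length(dens)
  # light moving-average smoothing so sampling noise cannot displace the peak
  w <- min(7L, if (nb %% 2L == 1L) nb else nb - 1L)
  if (w >= 3L) {
    k <- (w - 1L) %/% 2L
    padded <- c(rep(dens[1L], k), dens, rep(dens[nb], k))
    dens <- vapply(seq_len(nb), function(i) mean(padded[i:(i + 2L * k)]), 1.0)
  }
  peak <- which(dens == max(dens))
  if (length(peak) > 1L) {
    warning("multimodal tie in mode estimate; returning the smallest mode")
    peak <- peak[1L]
  }
  m <- h$mids[peak]
  # local quadratic refinement across the peak neighborhood
  lo <- max(1L, peak - 3L); hi <- min(nb, peak + 3L)
  if (hi - lo >= 2L) {
    tt <- h$mids[lo:hi] - m
    co <- stats::lm.fit(cbind(1, tt, tt^2), dens[lo:hi])$coefficients
    if (is.finite(co[3]) && co[3] < 0) {
      off <- -co[2] / (2 * co[3])
      if (abs(off) <= 3 * bw) m <- m + off
    }
  }
  unname(if (log_bins) exp(m) else m)
}

#' Most probable cell perimeter of a condition
#'
#' @param perimeters numeric vector of cell perimeters (um), pooled over the
#'   images of one condition.
#' @return the histogram-peak mode (see [density_mode()]).
#' @export
rescaled_perimeter_mode <- function(perimeters) {
  density_mode(perimeters, log_bins = FALSE)
}

bin_mean_by_n <- function(n, value) {
  spl <- split(value, n)
  data.frame(
    n = as.integer(names(spl)),
    mean = vapply(spl, mean, 1.0),
    sem = vapply(spl, function(v)
      if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_, 1.0),
    count = vapply(spl, length, 1L),
    row.names = NULL)
}

#' Lewis' law: mean rescaled area per neighbor class
#'
#' Cells of the analysis set are separated by their number of neighbors
#' (integer classes) and the rescaled areas averaged per class.
#'
#' @param t a `cell_tessellation` after [filter_cells()].
#' @return data.frame with `n`, `mean`, `sem` (NA for classes with fewer
#'   than two cells) and `count`.
#' @export
lewis_law <- function(t) {
  cells <- analysis_set(t)
  bin_mean_by_n(cells$n_neighbors, cells$rescaled_area)
}

#' Desch's law: mean rescaled perimeter per neighbor class
#'
#' The analogue of Lewis' law for perimeters. Perimeters are rescaled by the
#' most probable perimeter of the sample (histogram-peak mode) by default,
#' or by the mean perimeter.
#'
#' @param t a `cell_tessellation` after [filter_cells()].
#' @param rescale `"mode"` (default) or `"mean"`.
#' @return data.frame with `n`, `mean`, `sem`, `count`.
#' @export
desch_law <- function(t, rescale = c("mode", "mean")) {
  rescale <- match.arg(rescale)
  cells <- analysis_set(t)
  ref <- switch(rescale,
                mode = rescaled_perimeter_mode(cells$perimeter_um),
                mean = mean(cells$perimeter_um))
  bin_mean_by_n(cells$n_neighbors, cells$perimeter_um / ref)
}

#' Aboav-Weaire topology relation
#'
#' For each neighbor class n, `mu_m` is the mean, over all n-sided bulk
#' cells, of the mean neighbor count of their neighbors, and
#' `b(n) = (n - 6) * mu_m(n) - sigma2` where `sigma2` is the population
#' variance of the neighbor-count distribution of the sample. In any sample
#' `b(6) = -sigma2` identically. A near-linear b(n) with a common slope is
#' characteristic of functional epithelia; shifts of the curve indicate
#' topological rearrangement.
#'
#' Edge cells are excluded as central cells (their neighborhood is not fully
#' observed) but still count as neighbors of bulk cells, with their observed
#' neighbor counts.
#'
#' @param t a `cell_tessellation` after [filter_cells()].
#' @return list of class `topology_curves` element `aboav`: data.frame
#'   (`n`, `mu_m`, `b`, `count`), plus `sigma2`.
#' @export
aboav_weaire <- function(t) {
  cells <- analysis_set(t)
  all_n <- stats::setNames(t$cells$n_neighbors, as.character(t$cells$label))
  sigma2 <- mean((cells$n_neighbors - mean(cells$n_neighbors))^2)
  mean_nb_n <- vapply(as.character(cells$label), function(l) {
    nb <- t$neighbors[[l]]
    mean(all_n[as.character(nb)])
  }, 1.0)
  spl <- split(mean_nb_n, cells$n_neighbors)
  aboav <- data.frame(
    n = as.integer(names(spl)),
    mu_m = vapply(spl, mean, 1.0),
    count = vapply(spl, length, 1L),
    row.names = NULL)
  aboav$b <- (aboav$n - 6) * aboav$mu_m - sigma2
  list(aboav = aboav[, c("n", "mu_m", "b", "count")], sigma2 = sigma2)
}

#' All topology curves of one sample
#'
#' Convenience wrapper computing Lewis' law, Desch's law and the
#' Aboav-Weaire relation of one sample (typically one animal, images
#' pooled), with the cell count used later as pooling weight.
#'
#' @param t a `cell_tessellation` after [filter_cells()].
#' @param sample_id identifier stored with the curves.
#' @param desch_rescale passed to [desch_law()].
#' @return object of class `topology_curves`: list with `lewis`, `desch`,
#'   `aboav` data.frames, `sigma2`, `n_cells`, `sample_id`.
#' @export
topology_curves <- function(t, sample_id = t$source_id,
                            desch_rescale = "mode") {
  aw <- aboav_weaire(t)
  structure(list(lewis = lewis_law(t),
                 desch = desch_law(t, rescale = desch_rescale),
                 aboav = aw$aboav, sigma2 = aw$sigma2,
                 n_cells = nrow(analysis_set(t)), sample_id = sample_id),
            class = "topology_curves")
}

#' @export
print.topology_curves <- function(x, ...) {
  cat(sprintf("<topology_curves> %s: %d cells, sigma2 = %.3f\n",
              x$sample_id, x$n_cells, x$sigma2))
  cat("  n classes:", paste(x$lewis$n, collapse = " "), "\n")
  invisible(x)
}

#' Pool topology curves across animals
#'
#' Per-bin weighted means with weights proportional to each animal's total
#' cell count; bins present in only a subset of animals are pooled over that
#' subset.
#'
#' @param curves list of `topology_curves`.
#' @param weights optional numeric weights; defaults to each sample's
#'   `n_cells`.
#' @return a pooled `topology_curves` (SEM columns dropped; counts summed).
#' @export
pool_across_animals <- function(curves, weights = NULL) {
  if (!length(curves)) stop("no curves to pool")
  stopifnot(all(vapply(curves, inherits, TRUE, "topology_curves")))
  if (is.null(weights)) weights <- vapply(curves, function(x) x$n_cells, 1.0)
  stopifnot(length(weights) == length(curves), all(weights > 0))

  pool_df <- function(dfs, value_cols) {
    long <- do.call(rbind, lapply(seq_along(dfs), function(i) {
      d <- dfs[[i]]
      if (!nrow(d)) return(NULL)
      d$w <- unname(weights[i]); d
    }))
    if (is.null(long))
      return(cbind(data.frame(n = integer(0)),
                   stats::setNames(as.data.frame(rep(list(numeric(0)),
                                                     length(value_cols))),
                                   value_cols),
                   data.frame(count = integer(0))))
    ns <- sort(unique(long$n))
    out <- data.frame(n = ns)
    for (vc in value_cols)
      out[[vc]] <- vapply(ns, function(nn) {
        d <- long[long$n == nn, ]
        sum(d[[vc]] * d$w) / sum(d$w)
      }, 1.0)
    out$count <- vapply(ns, function(nn) as.integer(sum(long$count[long$n == nn])), 1L)
    out
  }
  sigma2 <- sum(weights * vapply(curves, function(x) x$sigma2, 1.0)) / sum(weights)
  structure(list(
    lewis = pool_df(lapply(curves, `[[`, "lewis"), "mean"),
    desch = pool_df(lapply(curves, `[[`, "desch"), "mean"),
    aboav = pool_df(lapply(curves, `[[`, "aboav"), c("mu_m", "b")),
    sigma2 = sigma2,
    n_cells = sum(vapply(curves, function(x) x$n_cells, 1.0)),
    sample_id = paste0("pooled[", length(curves), "]")),
    class = "topology_curves")
}
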