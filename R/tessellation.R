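#' Build a cell tessellation from a segmentation label mask
#'
#' Converts a 2-D integer label image (e.g., exported from a cell
#' segmentation tool) or a skeletonized boundary image into a
#' `cell_tessellation` with per-cell area, perimeter, centroid and
#' elongation in physical units.
#'
#' Preprocessing mirrors the standard morphometric workflow for segmented
#' epithelia: a fixed border margin is cropped to discard poorly segmented
#' image edges; skeleton input is smoothed with a Gaussian filter (to repair
#' single-pixel connectivity defects in the boundary lines) before the
#' enclosed regions are labeled. Thin zero-valued boundary lines between
#' labels are then reassigned to the nearest adjacent cell so that cell
#' supports tile the image; zero pixels bordering only one cell (true
#' background, e.g., an empty margin) are left untouched.
#'
#' Per-cell perimeter and area are both measured on the marching-squares
#' contour of the cell support after Ramer-Douglas-Peucker simplification
#' at sub-pixel tolerance, which removes the digitization staircase (it
#' only ever lengthens a contour) while preserving genuine corners; using
#' one polygon for both keeps the shape index internally consistent. This
#' matters because absolute shape-index values (perimeter over root area,
#' 3.7-4.0 in epithelia) are compared across conditions.
#'
#' @param mask integer matrix: label image (positive integer per cell) or,
#'   with `skeleton = TRUE`, a binary boundary image (boundaries > 0).
#' @param pixel_size_um micrometres per pixel.
#' @param source_id free-text sample identifier.
#' @param trim_px border margin cropped from all four sides before analysis
#'   (default 15 px).
#' @param skeleton logical; treat `mask` as a skeletonized boundary image.
#' @param gaussian_sd standard deviation (px) of the Gaussian filter applied
#'   to skeleton input before labeling (default 2 px).
#' @return A `cell_tessellation` (adjacency not yet built; see
#'   [build_adjacency()]).
#' @export
tessellation_from_mask <- function(mask, pixel_size_um, source_id = "",
                                   trim_px = 15L, skeleton = FALSE,
                                   gaussian_sd = 2) {
  if (is.array(mask) && length(dim(mask)) != 2L)
    stop("mask must be a 2-D image (got ", length(dim(mask)), " dimensions)")
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!skeleton && any(mask != round(mask)))
    stop("label mask must contain integer labels")
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", lo = 1e-9)
  trim_px <- as.integer(trim_px)
  if (trim_px > 0) {
    if (2 * trim_px >= min(dim(mask)))
      stop("image smaller than twice the trim margin")
    mask <- mask[(trim_px + 1):(nrow(mask) - trim_px),
                 (trim_px + 1):(ncol(mask) - trim_px), drop = FALSE]
  }
  if (skeleton) {
    sk <- EBImage::imageData(EBImage::gblur(EBImage::Image(mask > 0),
                                            sigma = gaussian_sd))
    # threshold at half the typical smoothed line amplitude so that thin
    # gaps in the boundary lines are sealed without fattening them unduly
    amp <- stats::median(sk[mask > 0])
    interior <- sk < 0.5 * amp
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(interior)))
    storage.mode(lab) <- "integer"
  } else {
    lab <- mask
    storage.mode(lab) <- "integer"
  }
  if (all(lab == 0L)) stop("empty mask: no labeled cells")
  lab <- fill_boundary_gaps(lab, full = skeleton)
  cells <- measure_labels(lab, pixel_size_um)
  new_cell_tessellation(cells, neighbors = NULL,
                        pixel_size_um = pixel_size_um,
                        image_shape = dim(lab), source_id = source_id,
                        labels = lab)
}

#' Load a label mask or skeleton image from a TIFF file
#'
#' @param path TIFF file (2-D, single channel; 8/16/32-bit integer labels or
#'   binary skeleton).
#' @param pixel_size_um micrometres per pixel.
#' @inheritParams tessellation_from_mask
#' @param ... passed to [tessellation_from_mask()].
#' @return A `cell_tessellation`.
#' @export
load_label_mask <- function(path, pixel_size_um, ...) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      stop("expected a single-channel 2-D image, got ", dim(img)[3], " channels")
    img <- img[, , 1]
  }
  tessellation_from_mask(img, pixel_size_um, ...)
}

# Reassign thin zero-valued boundary lines to the nearest adjacent cell.
# A zero pixel is filled only if at least two distinct labels occur within
# its 5x5 neighborhood (i.e., it lies between cells); background bordering a
# single cell stays zero. Nearest-label assignment by geodesic propagation.
# With `full = TRUE` (skeleton input, where zero pixels are boundary lines
# by construction and no background exists) every remaining zero pixel is
# assigned to its geodesically nearest cell instead.
fill_boundary_gaps <- function(lab, full = FALSE) {
  if (full) {
    if (!any(lab == 0L)) return(lab)
    filled <- EBImage::imageData(EBImage::propagate(
      x = EBImage::Image(matrix(0, nrow(lab), ncol(lab))),
      seeds = EBImage::Image(lab)))
    storage.mode(filled) <- "integer"
    return(filled)
  }
  fill_boundary_gaps_once(lab)
}

fill_boundary_gaps_once <- function(lab) {
  if (!any(lab == 0L)) return(lab)
  big <- max(lab) + 1L
  mx <- lab; mn <- ifelse(lab > 0L, lab, big)
  for (dr in -2:2) for (dc in -2:2) {
    if (dr == 0 && dc == 0) next
    sh <- shift_matrix(lab, dr, dc, fill = 0L)
    mx <- pmax(mx, sh)
    mn <- pmin(mn, ifelse(sh > 0L, sh, big))
  }
  between <- lab == 0L & mx > 0L & mn < big & mx != mn
  if (!any(between)) return(lab)
  fillmask <- lab > 0L | between
  filled <- EBImage::imageData(EBImage::propagate(
    x = EBImage::Image(matrix(0, nrow(lab), ncol(lab))),
    seeds = EBImage::Image(lab), mask = EBImage::Image(fillmask)))
  out <- lab
  out[between] <- as.integer(filled[between])
  out
}

shift_matrix <- function(m, dr, dc, fill = 0L) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Per-label morphometrics on a tiling label image.
measure_labels <- function(lab, ps, min_px = 2L) {
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  by_lab <- split(seq_along(idx), labs)
  ids <- as.integer(names(by_lab))
  n <- length(ids)
  out <- data.frame(label = ids, area_um2 = NA_real_, perimeter_um = NA_real_,
                    centroid_x_um = NA_real_, centroid_y_um = NA_real_,
                    touches_border = FALSE, elongation = NA_real_)
  nr <- nrow(lab); nc <- ncol(lab)
  drop <- logical(n)
  for (k in seq_len(n)) {
    sel <- by_lab[[k]]
    if (length(sel) < min_px) { drop[k] <- TRUE; next }
    r <- rows[sel]; c <- cols[sel]
    cm <- contour_metrics_px(r, c)
    out$area_um2[k] <- cm$area * ps^2
    out$centroid_x_um[k] <- (mean(c) - 0.5) * ps
    out$centroid_y_um[k] <- (mean(r) - 0.5) * ps
    out$touches_border[k] <- any(r == 1L | r == nr | c == 1L | c == nc)
    out$perimeter_um[k] <- cm$perimeter * ps
    out$elongation[k] <- pixel_elongation(r, c)
    if (!is.finite(out$perimeter_um[k]) || is.na(cm$area) ||
        out$perimeter_um[k] <= 0 || cm$area <= 0)
      drop[k] <- TRUE
  }
  if (any(drop)) {
    message(sum(drop), " degenerate region(s) (<", min_px,
            " px or no contour) skipped")
    out <- out[!drop, , drop = FALSE]
  }
  out
}

# Marching-squares contour length of a pixel set. The raw contour carries
# half-pixel staircase excursions that inflate the length; simplifying it
# with the Ramer-Douglas-Peucker algorithm at a sub-pixel tolerance
# straightens digitized line segments while preserving genuine corners.
contour_perimeter_px <- function(r, c, rdp_eps = 0.75) {
  contour_metrics_px(r, c, rdp_eps)$perimeter
}

# Perimeter and area of the simplified half-level contour polygon of a
# pixel set. Using the same polygon for both keeps the shape index
# internally consistent.
contour_metrics_px <- function(r, c, rdp_eps = 0.75) {
  r0 <- min(r); c0 <- min(c)
  sub <- matrix(0L, max(r) - r0 + 5L, max(c) - c0 + 5L)
  sub[cbind(r - r0 + 3L, c - c0 + 3L)] <- 1L
  cl <- grDevices::contourLines(x = seq_len(nrow(sub)), y = seq_len(ncol(sub)),
                                z = sub, levels = 0.5)
  if (!length(cl)) return(list(perimeter = NA_real_, area = NA_real_))
  lens <- vapply(cl, function(ct) length(ct$x), 1L)
  ct <- cl[[which.max(lens)]]
  P <- cbind(ct$x, ct$y)
  if (nrow(P) > 1 && all(P[1, ] == P[nrow(P), ])) P <- P[-nrow(P), , drop = FALSE]
  if (nrow(P) < 3) return(list(perimeter = NA_real_, area = NA_real_))
  S <- rdp_simplify_closed(P, rdp_eps)
  list(perimeter = closed_polyline_length(S), area = polygon_area(S))
}

closed_polyline_length <- function(P) {
  j <- c(seq_len(nrow(P))[-1], 1L)
  sum(sqrt((P[j, 1] - P[, 1])^2 + (P[j, 2] - P[, 2])^2))
}

# Ramer-Douglas-Peucker on a closed polygon: split at the two mutually
# farthest of four extreme anchor vertices, simplify each arc.
rdp_simplify_closed <- function(P, eps) {
  n <- nrow(P)
  if (n <= 4L) return(P)
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  keep1 <- rdp_arc(P, i1, i2, eps)
  keep2 <- rdp_arc(P, i2, i1, eps)
  idx <- unique(c(keep1, keep2))
  P[sort(idx), , drop = FALSE]
}

# Indices kept when simplifying the arc from vertex i to vertex j (walking
# forward cyclically); iterative stack formulation.
rdp_arc <- function(P, i, j, eps) {
  n <- nrow(P)
  arc <- if (i <= j) i:j else c(i:n, 1:j)
  pts <- P[arc, , drop = FALSE]
  m <- nrow(pts)
  keep <- logical(m); keep[c(1L, m)] <- TRUE
  stack <- list(c(1L, m))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- seg[1]; b <- seg[2]
    if (b - a < 2L) next
    A <- pts[a, ]; B <- pts[b, ]
    AB <- B - A
    L2 <- sum(AB^2)
    mid <- (a + 1L):(b - 1L)
    if (L2 == 0) {
      d <- sqrt((pts[mid, 1] - A[1])^2 + (pts[mid, 2] - A[2])^2)
    } else {
      d <- abs(AB[2] * (pts[mid, 1] - A[1]) - AB[1] * (pts[mid, 2] - A[2])) /
        sqrt(L2)
    }
    k <- which.max(d)
    if (d[k] > eps) {
      keep[mid[k]] <- TRUE
      stack[[length(stack) + 1L]] <- c(a, mid[k])
      stack[[length(stack) + 1L]] <- c(mid[k], b)
    }
  }
  arc[keep]
}

# Axis ratio from pixel second moments (1/12 is the variance of a unit pixel).
pixel_elongation <- function(r, c) {
  if (length(r) < 2L) return(1)
  cv <- stats::cov(cbind(c, r)) * (length(r) - 1) / length(r) + diag(2) / 12
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev[1], 0) / max(ev[2], .Machine$double.eps))
}

#' Build the neighbor graph of a tessellation
#'
#' Two cells are neighbors when, after the thin boundary lines separating
#' them have been reassigned (the radius-1 dilation that compensates
#' skeletonized boundaries), their supports touch under 8-connectivity.
#' Diagonal contact counts, except at a genuine four-fold pixel vertex (a
#' 2x2 block holding four distinct labels): there the two crossing diagonal
#' pairs share only a point, not a boundary, and neither is counted. The
#' relation is symmetric by construction and `n_neighbors` is updated.
#'
#' @param t a `cell_tessellation` carrying its label image.
#' @param min_contact_px smallest number of admissible pixel-level contact
#'   events for a neighbor relation (default 1).
#' @return The tessellation with `neighbors` and `n_neighbors` filled in.
#' @export
build_adjacency <- function(t, min_contact_px = 1L) {
  stopifnot(inherits(t, "cell_tessellation"))
  if (is.null(t$labels)) stop("tessellation carries no label image")
  lab <- t$labels
  nr <- nrow(lab); np <- ncol(lab)
  key <- as.numeric(max(lab)) + 1
  enc <- numeric(0)
  for (off in list(c(0L, 1L), c(1L, 0L))) {      # edge-sharing contact
    sh <- shift_matrix(lab, off[1], off[2], fill = 0L)
    sel <- lab > 0L & sh > 0L & lab != sh
    # a contact event whose perpendicular flanks are one third cell on one
    # side and a different third cell on the other is the rendering of a
    # (near-)four-fold vertex, where the pair meets only at a point
    fl <- c(off[2], off[1])   # flank direction perpendicular to the offset
    f1a <- shift_matrix(lab, fl[1], fl[2], fill = 0L)
    f1b <- shift_matrix(sh,  fl[1], fl[2], fill = 0L)
    f2a <- shift_matrix(lab, -fl[1], -fl[2], fill = 0L)
    f2b <- shift_matrix(sh,  -fl[1], -fl[2], fill = 0L)
    crossing <- f1a == f1b & f2a == f2b & f1a > 0L & f2a > 0L &
      f1a != f2a & f1a != lab & f1a != sh & f2a != lab & f2a != sh
    sel <- sel & !crossing
    if (any(sel)) {
      a <- lab[sel]; b <- sh[sel]
      enc <- c(enc, pmin(a, b) * key + pmax(a, b))
    }
  }
  if (nr > 1L && np > 1L) {                      # corner contact per 2x2 block
    A <- lab[-nr, -np]; B <- lab[-nr, -1]; C <- lab[-1, -np]; D <- lab[-1, -1]
    # a diagonal pair separated by two other cells (crossing or pinched neck)
    # meets only at a point: regions sharing a real boundary segment always
    # also touch orthogonally, so such diagonal-only contacts are excluded
    s1 <- A > 0L & D > 0L & A != D &
      !(B > 0L & C > 0L & B != A & B != D & C != A & C != D)
    if (any(s1)) enc <- c(enc, pmin(A[s1], D[s1]) * key + pmax(A[s1], D[s1]))
    s2 <- B > 0L & C > 0L & B != C &
      !(A > 0L & D > 0L & A != B & A != C & D != B & D != C)
    if (any(s2)) enc <- c(enc, pmin(B[s2], C[s2]) * key + pmax(B[s2], C[s2]))
  }
  labs <- sort(unique(t$cells$label))
  neighbors <- stats::setNames(rep(list(integer(0)), length(labs)),
                               as.character(labs))
  if (length(enc)) {
    cnt <- table(enc)
    kept <- as.numeric(names(cnt))[cnt >= min_contact_px]
    if (length(kept)) {
      a <- as.integer(kept %/% key); b <- as.integer(kept %% key)
      pairs <- cbind(c(a, b), c(b, a))
      spl <- split(pairs[, 2], pairs[, 1])
      for (l in names(spl)) neighbors[[l]] <- sort(unique(as.integer(spl[[l]])))
    }
  }
  t$neighbors <- neighbors
  t$cells$n_neighbors <- vapply(as.character(t$cells$label), function(l)
    length(neighbors[[l]]), 1L)
  t
}

#' Flag edge cells and compute rescaled areas
#'
#' A cell is an edge cell when the mean position of its neighbors' centroids
#' lies at or beyond `bulk_threshold_px` pixels from its own centroid (for a
#' cell in the bulk the neighbors surround it and their mean position falls
#' close to the cell itself), when it touches the image border, or when it
#' has no neighbors. Rescaled areas `A_i / <A>` are computed here with `<A>`
#' the per-image mean over border-free cells, before any filtering.
#'
#' @param t a `cell_tessellation` with adjacency built.
#' @param bulk_threshold_px centroid-offset threshold in pixels (default 30).
#' @return The tessellation with `is_edge` and `rescaled_area` filled in.
#' @export
flag_edge_cells <- function(t, bulk_threshold_px = 30) {
  stopifnot(inherits(t, "cell_tessellation"))
  if (is.null(t$neighbors)) stop("run build_adjacency() first")
  ps <- t$pixel_size_um
  cells <- t$cells
  cent <- cells[, c("centroid_x_um", "centroid_y_um")]
  rownames(cent) <- as.character(cells$label)
  off_px <- vapply(seq_len(nrow(cells)), function(i) {
    nb <- t$neighbors[[as.character(cells$label[i])]]
    if (length(nb) == 0L) return(Inf)
    nbm <- colMeans(cent[as.character(nb), , drop = FALSE])
    sqrt(sum((nbm - unlist(cent[i, ]))^2)) / ps
  }, 1.0)
  cells$is_edge <- off_px >= bulk_threshold_px | cells$touches_border
  pop <- !cells$touches_border
  if (!any(pop)) stop("no border-free cells to define the mean area")
  cells$rescaled_area <- cells$area_um2 / mean(cells$area_um2[pop])
  t$cells <- cells
  t
}

#' Apply the analysis-set filters
#'
#' Removes from the analysis set (but not from the tessellation, so neighbor
#' counts of remaining cells are untouched): edge cells, unnaturally large
#' cells (`rescaled_area > max_rescaled_area`, a segmentation-failure guard)
#' and cells with more than `max_neighbors` neighbors.
#'
#' @param t a `cell_tessellation` after [flag_edge_cells()].
#' @param max_rescaled_area largest admissible rescaled area (default 2).
#' @param max_neighbors largest admissible neighbor count (default 10).
#' @return The tessellation with the logical `kept` column filled in.
#' @export
filter_cells <- function(t, max_rescaled_area = 2, max_neighbors = 10) {
  stopifnot(inherits(t, "cell_tessellation"))
  if (all(is.na(t$cells$is_edge)) || all(is.na(t$cells$rescaled_area)))
    stop("run flag_edge_cells() first")
  t$cells$kept <- !t$cells$is_edge &
    t$cells$rescaled_area <= max_rescaled_area &
    t$cells$n_neighbors <= max_neighbors
  t
}

#' Nuclear shape descriptors from a nucleus label mask
#'
#' Uses the common image-analysis definitions: circularity `4*pi*A/P^2`
#' (clipped to at most 1), roundness `4*A/(pi*major^2)` and aspect ratio
#' major/minor of the moment-equivalent ellipse.
#'
#' @param nuclear_mask 2-D integer label image of nuclei.
#' @param pixel_size_um micrometres per pixel.
#' @return data.frame with one row per nucleus: `label`, `area_um2`,
#'   `perimeter_um`, `major_axis_um`, `minor_axis_um`, `circularity`,
#'   `roundness`, `aspect_ratio`. Degenerate (single-pixel) regions are
#'   skipped with a message.
#' @export
nuclear_shape_metrics <- function(nuclear_mask, pixel_size_um = 1) {
  stopifnot(is.matrix(nuclear_mask))
  ps <- pixel_size_um
  idx <- which(nuclear_mask > 0)
  if (!length(idx)) stop("empty nuclear mask")
  labs <- nuclear_mask[idx]
  rows <- ((idx - 1L) %% nrow(nuclear_mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(nuclear_mask)) + 1L
  by_lab <- split(seq_along(idx), labs)
  res <- lapply(names(by_lab), function(l) {
    sel <- by_lab[[l]]
    if (length(sel) < 2L) {
      message("nucleus ", l, " has <2 px; skipped")
      return(NULL)
    }
    r <- rows[sel]; c <- cols[sel]
    cm <- contour_metrics_px(r, c)
    A <- cm$area * ps^2
    P <- cm$perimeter * ps
    cv <- stats::cov(cbind(c, r)) * (length(sel) - 1) / length(sel) + diag(2) / 12
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    major <- 4 * sqrt(max(ev[1], 0)) * ps
    minor <- 4 * sqrt(max(ev[2], 0)) * ps
    data.frame(label = as.integer(l), area_um2 = A, perimeter_um = P,
               major_axis_um = major, minor_axis_um = minor,
               circularity = min(4 * pi * A / P^2, 1),
               roundness = 4 * A / (pi * major^2),
               aspect_ratio = major / max(minor, .Machine$double.eps))
  })
  do.call(rbind, res)
}
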