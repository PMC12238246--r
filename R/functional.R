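#' Phagocytosis efficiency from a labeled particle stack
#'
#' A particle counts as internalized when its volume centroid lies below
#' the apical reference surface at the particle's position (the
#' `"centroid"` rule; `"entire"` requires every voxel below the surface).
#' Efficiency is the summed projected (xy) area of internalized particles
#' divided by the summed projected area of all particles; with equal-size
#' particles this equals the internalized count fraction. Classification
#' uses physical heights, so it is unaffected by z-anisotropy of the
#' voxels.
#'
#' @param stack a `particle_stack` (see [generate_pos_stack()]), or any
#'   list with `labels` (3-D array `[z, y, x]`), `surface_um` (y-x matrix)
#'   and `voxel_size_um` (`c(z, y, x)`).
#' @param rule `"centroid"` (default) or `"entire"`.
#' @return list with `efficiency` (in `[0, 1]`) and `classification`
#'   data.frame (`label`, `centroid_z_um`, `projected_area_um2`,
#'   `internalized`).
#' @export
phagocytosis_efficiency <- function(stack, rule = c("centroid", "entire")) {
  rule <- match.arg(rule)
  lab <- stack$labels; vs <- stack$voxel_size_um
  stopifnot(length(dim(lab)) == 3L)
  idx <- which(lab > 0L)
  if (!length(idx)) stop("no particles in stack: efficiency undefined")
  dims <- dim(lab)
  z <- ((idx - 1L) %% dims[1]) + 1L
  rest <- (idx - 1L) %/% dims[1]
  y <- (rest %% dims[2]) + 1L
  x <- (rest %/% dims[2]) + 1L
  labs <- lab[idx]
  pxa <- vs[2] * vs[3]
  by_lab <- split(seq_along(idx), labs)
  out <- lapply(names(by_lab), function(l) {
    sel <- by_lab[[l]]
    cz <- (mean(z[sel]) - 0.5) * vs[1]
    cy <- round(mean(y[sel])); cx <- round(mean(x[sel]))
    surf <- stack$surface_um[cy, cx]
    internal <- if (rule == "centroid") cz < surf else
      all((z[sel] - 0.5) * vs[1] < stack$surface_um[cbind(y[sel], x[sel])])
    proj <- length(unique((x[sel] - 1L) * dims[2] + y[sel])) * pxa
    data.frame(label = as.integer(l), centroid_z_um = cz,
               projected_area_um2 = proj, internalized = internal)
  })
  cls <- do.call(rbind, out)
  list(efficiency = sum(cls$projected_area_um2[cls$internalized]) /
         sum(cls$projected_area_um2),
       classification = cls)
}

#' Proliferation ratio from nuclear label masks
#'
#' Counts nuclei in the DAPI mask (connected components) within a region of
#' interest and the fraction of them overlapping the EdU-positive mask.
#'
#' @param edu_mask binary or label matrix of EdU-positive signal.
#' @param dapi_mask binary or label matrix of all nuclei.
#' @param roi optional logical matrix; a nucleus belongs to the ROI when
#'   its centroid falls inside (used to restrict to the gel center, away
#'   from edge effects).
#' @return fraction of proliferating nuclei in `[0, 1]`.
#' @export
proliferation_ratio <- function(edu_mask, dapi_mask, roi = NULL) {
  stopifnot(is.matrix(edu_mask), all(dim(edu_mask) == dim(dapi_mask)))
  nuc <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(dapi_mask > 0)))
  ids <- sort(unique(nuc[nuc > 0]))
  if (!length(ids)) stop("no nuclei in the DAPI mask")
  edu <- edu_mask > 0
  pos <- 0L; tot <- 0L
  for (id in ids) {
    pix <- which(nuc == id, arr.ind = TRUE)
    if (!is.null(roi)) {
      cen <- round(colMeans(pix))
      if (!roi[cen[1], cen[2]]) next
    }
    tot <- tot + 1L
    if (any(edu[pix])) pos <- pos + 1L
  }
  if (tot == 0L) stop("no nuclei inside the region of interest")
  pos / tot
}

#' Radial region bins along the visual axis
#'
#' The standard anatomical partition of the flat-mounted eye by distance
#' from the optic nerve head: centre 300-1200 um, mid periphery
#' 1200-2000 um, far periphery 2000-3000 um (half-open intervals).
#'
#' @param centre,mid_periphery,far_periphery numeric `c(lo, hi)` bounds in
#'   um; must be contiguous and non-overlapping.
#' @return a `region_bins` list.
#' @export
region_bins <- function(centre = c(300, 1200), mid_periphery = c(1200, 2000),
                        far_periphery = c(2000, 3000)) {
  b <- list(centre = centre, mid_periphery = mid_periphery,
            far_periphery = far_periphery)
  for (x in b) stopifnot(length(x) == 2L, x[1] < x[2])
  if (centre[2] != mid_periphery[1] || mid_periphery[2] != far_periphery[1])
    stop("region bins must be contiguous")
  structure(b, class = "region_bins")
}

#' Assign radial distances to anatomical regions
#'
#' @param d_um distance(s) from the optic nerve head in um; must be
#'   non-negative.
#' @param bins a [region_bins()].
#' @return factor with levels `centre`, `mid_periphery`, `far_periphery`,
#'   `unassigned` (outside the binned range).
#' @export
region_of_distance <- function(d_um, bins = region_bins()) {
  if (any(d_um < 0)) stop("distances must be non-negative")
  out <- rep("unassigned", length(d_um))
  for (nm in names(bins))
    out[d_um >= bins[[nm]][1] & d_um < bins[[nm]][2]] <- nm
  factor(out, levels = c("centre", "mid_periphery", "far_periphery",
                         "unassigned"))
}

#' Normalize intensities to the per-eye maximum
#'
#' Each value is divided by the maximum of its group (eye/animal), so every
#' group's maximum becomes exactly 1. Idempotent.
#'
#' @param values numeric intensities.
#' @param group grouping vector (eye or animal id), same length.
#' @return normalized values.
#' @export
normalize_per_eye <- function(values, group) {
  stopifnot(length(values) == length(group))
  out <- numeric(length(values))
  for (g in unique(group)) {
    sel <- group == g
    m <- max(values[sel], na.rm = TRUE)
    if (!is.finite(m) || m <= 0)
      stop("group '", g, "' has no positive intensity to normalize by")
    out[sel] <- values[sel] / m
  }
  out
}

#' Mean intensity inside polygonal regions of interest
#'
#' @param image_2d numeric matrix (single optical section).
#' @param rois list of polygons, each a two-column matrix or data.frame of
#'   `(x, y)` vertex coordinates in pixel units (pixel centers at integer
#'   positions, x = column, y = row).
#' @return numeric vector of per-ROI means of the pixel intensities whose
#'   centers fall inside each polygon.
#' @export
roi_mean_intensity <- function(image_2d, rois) {
  stopifnot(is.matrix(image_2d))
  if (!length(rois)) stop("no ROIs supplied")
  vapply(rois, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L) stop("ROI polygons need >= 3 (x, y) vertices")
    if (min(p[, 1]) > ncol(image_2d) || max(p[, 1]) < 1 ||
        min(p[, 2]) > nrow(image_2d) || max(p[, 2]) < 1)
      stop("ROI lies outside the image")
    cs <- max(1L, floor(min(p[, 1]))):min(ncol(image_2d), ceiling(max(p[, 1])))
    rs <- max(1L, floor(min(p[, 2]))):min(nrow(image_2d), ceiling(max(p[, 2])))
    gx <- rep(cs, each = length(rs))
    gy <- rep(rs, times = length(cs))
    inside <- pracma::inpolygon(gx, gy, p[, 1], p[, 2], boundary = TRUE)
    if (!any(inside)) stop("ROI contains no pixel centers")
    mean(image_2d[cbind(gy[inside], gx[inside])])
  }, 1.0)
}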