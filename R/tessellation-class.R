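#' Construct a cell tessellation object
#'
#' A `cell_tessellation` bundles per-cell morphometrics with the neighbor
#' graph of a segmented epithelial monolayer. It is the common substrate for
#' all topology statistics (Lewis' and Desch's laws, Aboav-Weaire) and is
#' produced either by [tessellation_from_mask()] / [load_label_mask()] from a
#' segmentation, or by [generate_monolayer()] with exact ground truth.
#'
#' @param cells data.frame with one row per cell. Required columns:
#'   `label` (positive integer id), `area_um2`, `perimeter_um`,
#'   `centroid_x_um`, `centroid_y_um`. Optional columns (filled by later
#'   pipeline stages when absent): `n_neighbors`, `touches_border`,
#'   `is_edge`, `rescaled_area`, `shape_index`, `elongation`, `kept`.
#' @param neighbors named list mapping each label (as character) to an
#'   integer vector of neighbor labels; must be symmetric.
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#' @param image_shape integer vector `c(rows, cols)` of the source image.
#' @param source_id free-text identifier (animal/experiment and position).
#' @param labels optional integer label matrix retained for adjacency
#'   computations.
#'
#' @return An object of class `cell_tessellation`.
#' @export
new_cell_tessellation <- function(cells, neighbors = NULL, pixel_size_um = 1,
                                  image_shape = NULL, source_id = "",
                                  labels = NULL) {
  stopifnot(is.data.frame(cells))
  req <- c("label", "area_um2", "perimeter_um", "centroid_x_um", "centroid_y_um")
  miss <- setdiff(req, names(cells))
  if (length(miss))
    stop("`cells` is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cells$label) || any(cells$label <= 0))
    stop("cell labels must be unique positive integers")
  if (any(cells$area_um2 <= 0) || any(cells$perimeter_um <= 0))
    stop("cell areas and perimeters must be positive")
  for (col in c("n_neighbors", "touches_border", "is_edge", "rescaled_area",
                "elongation", "kept"))
    if (is.null(cells[[col]])) cells[[col]] <- NA
  cells$shape_index <- cells$perimeter_um / sqrt(cells$area_um2)
  if (!is.null(neighbors)) {
    check_symmetric_neighbors(neighbors)
    cells$n_neighbors <- vapply(as.character(cells$label), function(l) {
      v <- neighbors[[l]]
      if (is.null(v)) 0L else length(v)
    }, 1L)
  }
  structure(
    list(cells = cells, neighbors = neighbors, pixel_size_um = pixel_size_um,
         image_shape = image_shape, source_id = source_id, labels = labels),
    class = "cell_tessellation")
}

check_symmetric_neighbors <- function(neighbors) {
  for (l in names(neighbors)) {
    for (m in neighbors[[l]]) {
      back <- neighbors[[as.character(m)]]
      if (is.null(back) || !(as.integer(l) %in% back))
        stop(sprintf("neighbor relation not symmetric: %s -> %d", l, m))
    }
  }
  invisible(TRUE)
}

#' @export
print.cell_tessellation <- function(x, ...) {
  cat(sprintf("<cell_tessellation> %d cells", nrow(x$cells)))
  if (nzchar(x$source_id)) cat(sprintf(" [%s]", x$source_id))
  cat(sprintf("\n  pixel size: %g um/px", x$pixel_size_um))
  if (!is.null(x$image_shape))
    cat(sprintf("; image %d x %d px", x$image_shape[1], x$image_shape[2]))
  cat("\n")
  if (!all(is.na(x$cells$is_edge)))
    cat(sprintf("  edge-flagged: %d", sum(x$cells$is_edge)))
  if (!all(is.na(x$cells$kept)))
    cat(sprintf("; analysis set: %d", sum(x$cells$kept)))
  cat("\n")
  invisible(x)
}

#' Per-cell table of a tessellation
#'
#' @param t a `cell_tessellation`.
#' @return The per-cell data.frame (label, area, perimeter, shape index,
#'   neighbor count, edge flags, rescaled area, analysis-set flag).
#' @export
cell_table <- function(t) {
  stopifnot(inherits(t, "cell_tessellation"))
  t$cells
}

#' Analysis subset of a tessellation's cell table
#'
#' Returns the rows that survived [filter_cells()]; errors if the filter has
#' not been applied or the set is empty.
#' @param t a `cell_tessellation`.
#' @return data.frame of retained cells.
#' @export
analysis_set <- function(t) {
  stopifnot(inherits(t, "cell_tessellation"))
  if (all(is.na(t$cells$kept)))
    stop("run flag_edge_cells() and filter_cells() first")
  out <- t$cells[which(t$cells$kept), , drop = FALSE]
  if (nrow(out) == 0L) stop("analysis set is empty")
  out
}
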