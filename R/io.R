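#' Write a label mask as a 16-bit TIFF
#'
#' @param mask integer matrix (labels up to 65535).
#' @param path output file.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), max(mask) < 65536)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write / read a force curve as two-column CSV
#'
#' Columns `z_um` (displacement axis) and `F_N` (force); probe radius and
#' Poisson ratio travel in a comment header line.
#'
#' @param curve a `force_curve`.
#' @param path file path.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# probe_radius_um=%g poisson=%g", curve$probe_radius_um,
                     curve$poisson), con)
  utils::write.csv(data.frame(z_um = curve$z_um, F_N = curve$F_N), con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_curve
#' @param probe_radius_um,poisson override values from the file header.
#' @export
read_force_curve <- function(path, probe_radius_um = NULL, poisson = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    kv <- regmatches(first, gregexpr("[a-z_]+=[0-9.eE+-]+", first))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      if (parts[1] == "probe_radius_um" && is.null(probe_radius_um))
        probe_radius_um <- as.numeric(parts[2])
      if (parts[1] == "poisson" && is.null(poisson))
        poisson <- as.numeric(parts[2])
    }
  }
  if (is.null(probe_radius_um) || is.null(poisson))
    stop("probe_radius_um and poisson must come from the header or arguments")
  d <- utils::read.csv(path, skip = skip)
  force_curve(d[[1]], d[[2]], probe_radius_um, poisson, meta = path)
}

#' Write / read a vector field as tidy CSV
#'
#' Columns `x_um`, `y_um`, `vx`, `vy` (row-major over the grid).
#'
#' @param field a `vector_field`.
#' @param path file path.
#' @export
write_vector_field <- function(field, path) {
  stopifnot(inherits(field, "vector_field"))
  d <- data.frame(x_um = rep(field$x_um, each = nrow(field$vx)),
                  y_um = rep(field$y_um, times = ncol(field$vx)),
                  vx = as.vector(field$vx), vy = as.vector(field$vy))
  attr_line <- sprintf("# role=%s spacing_um=%g", field$role, field$spacing_um)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vector_field
#' @export
read_vector_field <- function(path) {
  first <- readLines(path, n = 1L)
  role <- sub(".*role=([a-z_]+).*", "\\1", first)
  spacing <- as.numeric(sub(".*spacing_um=([0-9.eE+-]+).*", "\\1", first))
  d <- utils::read.csv(path, skip = 1L)
  n <- length(unique(d$y_um)); m <- length(unique(d$x_um))
  vector_field(matrix(d$vx, n, m), matrix(d$vy, n, m), spacing, role)
}

#' Write the per-cell table of a tessellation as CSV
#'
#' @param t a `cell_tessellation`.
#' @param path file path.
#' @export
write_cell_table <- function(t, path) {
  utils::write.csv(cell_table(t), path, row.names = FALSE)
  invisible(path)
}
#' Write / read a particle stack as multi-page TIFF with a JSON sidecar
#'
#' Particle labels are stored one z-slice per page (16-bit); the reference
#' surface and voxel size travel in a JSON sidecar next to the stack.
#'
#' @param stack a `particle_stack`.
#' @param path TIFF file path; the sidecar is `<path>.json`.
#' @export
write_particle_stack <- function(stack, path) {
  dims <- dim(stack$labels)
  pages <- lapply(seq_len(dims[1]), function(k)
    matrix(stack$labels[k, , ], dims[2], dims[3]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(voxel_size_um = stack$voxel_size_um,
                            surface_um = stack$surface_um),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_particle_stack
#' @export
read_particle_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- array(0L, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (k in seq_along(pages)) labels[k, , ] <- as.integer(pages[[k]])
  structure(list(labels = labels,
                 surface_um = matrix(meta$surface_um, nrow(pages[[1]]),
                                     ncol(pages[[1]])),
                 voxel_size_um = as.numeric(meta$voxel_size_um)),
            class = "particle_stack")
}
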