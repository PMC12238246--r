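#' Specification for a synthetic particle-internalization stack
#'
#' Emulates the photoreceptor-outer-segment internalization assay: labeled
#' particles in a confocal stack, classified as internalized (below the
#' apical F-actin reference surface, i.e., inside the cell body) or bound
#' (above it). A chosen fraction of particles is placed strictly below the
#' surface.
#'
#' @param n_particles number of particles.
#' @param fraction_internalized fraction placed below the reference surface
#'   (in `[0, 1]`); exactly `round(n * f)` particles are internalized.
#' @param surface_z_um height of the flat apical reference surface (um).
#' @param stack_shape `c(nz, ny, nx)` stack dimensions in voxels.
#' @param voxel_size_um `c(z, y, x)` voxel size (um); anisotropic z typical
#'   of confocal stacks (0.5 um optical sections).
#' @param particle_radius_um particle radius (um); all particles equal.
#' @param seed RNG seed.
#' @return a `pos_spec` list.
#' @export
pos_spec <- function(n_particles = 20, fraction_internalized = 0.5,
                     surface_z_um = 6, stack_shape = c(24L, 128L, 128L),
                     voxel_size_um = c(0.5, 0.25, 0.25),
                     particle_radius_um = 0.8, seed = 1L) {
  stop_if_not_scalar_number(n_particles, "n_particles", lo = 1)
  stop_if_not_scalar_number(fraction_internalized, "fraction_internalized",
                            lo = 0, hi = 1)
  stopifnot(length(stack_shape) == 3L, length(voxel_size_um) == 3L)
  zmax <- stack_shape[1] * voxel_size_um[1]
  if (surface_z_um <= 0 || surface_z_um >= zmax)
    stop("reference surface must lie inside the stack z-range")
  structure(list(n_particles = as.integer(n_particles),
                 fraction_internalized = fraction_internalized,
                 surface_z_um = surface_z_um,
                 stack_shape = as.integer(stack_shape),
                 voxel_size_um = voxel_size_um,
                 particle_radius_um = particle_radius_um,
                 seed = as.integer(seed)),
            class = "pos_spec")
}

#' Generate a synthetic particle stack with known internalized fraction
#'
#' Particle centers are placed on the voxel grid (so equal radii give
#' identical voxel footprints), without overlap, by rejection sampling with
#' a bounded number of retries. Exactly `round(n * f)` particle centers lie
#' strictly below the reference surface, the rest strictly above.
#'
#' @param spec a [pos_spec()].
#' @return object of class `particle_stack`: `labels` (3-D integer array
#'   `[z, y, x]`), `surface_um` (y-x matrix of reference-surface heights),
#'   `voxel_size_um`, and the ground-truth `classification` data.frame.
#' @export
generate_pos_stack <- function(spec) {
  stopifnot(inherits(spec, "pos_spec"))
  dims <- spec$stack_shape; vs <- spec$voxel_size_um
  r <- spec$particle_radius_um
  n_int <- round(spec$n_particles * spec$fraction_internalized)
  rz <- ceiling(r / vs[1]); ry <- ceiling(r / vs[2]); rx <- ceiling(r / vs[3])
  zc_of <- function(k) (k - 0.5) * vs[1]
  below_ks <- which(zc_of(seq_len(dims[1])) < spec$surface_z_um - r &
                    zc_of(seq_len(dims[1])) > r)
  above_ks <- which(zc_of(seq_len(dims[1])) > spec$surface_z_um + r &
                    zc_of(seq_len(dims[1])) < dims[1] * vs[1] - r)
  if (n_int > 0 && !length(below_ks))
    stop("no admissible z-planes below the reference surface")
  if (n_int < spec$n_particles && !length(above_ks))
    stop("no admissible z-planes above the reference surface")
  centers <- matrix(NA_real_, spec$n_particles, 3)  # (z,y,x) voxel indices
  placed <- 0L
  with_seed(spec$seed, {
    for (i in seq_len(spec$n_particles)) {
      ks <- if (i <= n_int) below_ks else above_ks
      ok <- FALSE
      for (try in seq_len(1000L)) {
        cand <- c(sample(ks, 1L),
                  sample((ry + 1L):(dims[2] - ry), 1L),
                  sample((rx + 1L):(dims[3] - rx), 1L))
        if (placed == 0L) { ok <- TRUE }
        else {
          dz <- (centers[seq_len(placed), 1] - cand[1]) * vs[1]
          dy <- (centers[seq_len(placed), 2] - cand[2]) * vs[2]
          dx <- (centers[seq_len(placed), 3] - cand[3]) * vs[3]
          ok <- all(dz^2 + dy^2 + dx^2 > (2 * r)^2)
        }
        if (ok) break
      }
      if (!ok) stop("could not place particle ", i,
                    " without overlap after 1000 retries")
      centers[i, ] <- cand
      placed <- placed + 1L
    }
  })
  labels <- array(0L, dims)
  # identical integer-offset footprint for every particle
  offs <- expand.grid(dz = -rz:rz, dy = -ry:ry, dx = -rx:rx)
  keep <- (offs$dz * vs[1])^2 + (offs$dy * vs[2])^2 + (offs$dx * vs[3])^2 <= r^2
  offs <- offs[keep, ]
  for (i in seq_len(spec$n_particles)) {
    z <- centers[i, 1] + offs$dz; y <- centers[i, 2] + offs$dy
    x <- centers[i, 3] + offs$dx
    labels[cbind(z, y, x)] <- i
  }
  classification <- data.frame(
    label = seq_len(spec$n_particles),
    centroid_z_um = zc_of(centers[, 1]),
    internalized_truth = seq_len(spec$n_particles) <= n_int)
  structure(list(labels = labels,
                 surface_um = matrix(spec$surface_z_um, dims[2], dims[3]),
                 voxel_size_um = vs, classification = classification),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  cat(sprintf("<particle_stack> %d particles, %s voxels, surface at %.2g um\n",
              max(x$labels), paste(dim(x$labels), collapse = " x "),
              mean(x$surface_um)))
  invisible(x)
}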