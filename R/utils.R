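#' @keywords internal
"_PACKAGE"

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a finite number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# Shoelace area (positive for counter-clockwise polygons).
polygon_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(xy) {
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  sum(sqrt((xy[j, 1L] - xy[, 1L])^2 + (xy[j, 2L] - xy[, 2L])^2))
}

polygon_centroid <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}
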