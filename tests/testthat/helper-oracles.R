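# Independent brute-force oracles and toy-object builders shared by tests.
# These deliberately use plain loops and first-principles definitions, not
# the package's vectorized code paths.

# Build a tessellation object directly from hand-specified per-cell data.
# Neighbor lists may be assigned afterwards without symmetry checking so
# that hand-computed topology examples (which need not be realizable as
# simple planar graphs) can be exercised.
toy_tessellation <- function(areas, perims = sqrt(areas) * 4,
                             n_neighbors = NULL, neighbors = NULL,
                             is_edge = FALSE, pixel_size_um = 1) {
  n <- length(areas)
  cells <- data.frame(label = seq_len(n), area_um2 = areas,
                      perimeter_um = perims,
                      centroid_x_um = seq_len(n), centroid_y_um = rep(1, n))
  t <- new_cell_tessellation(cells, neighbors = NULL,
                             pixel_size_um = pixel_size_um,
                             image_shape = c(100L, 100L), source_id = "toy")
  t$cells$touches_border <- FALSE
  t$cells$is_edge <- rep_len(is_edge, n)
  t$cells$rescaled_area <- areas / mean(areas)
  if (!is.null(neighbors)) {
    t$neighbors <- neighbors
    t$cells$n_neighbors <- vapply(as.character(seq_len(n)), function(l)
      length(neighbors[[l]]), 1L)
  }
  if (!is.null(n_neighbors)) t$cells$n_neighbors <- n_neighbors
  t$cells$kept <- !t$cells$is_edge & t$cells$rescaled_area <= 2 &
    t$cells$n_neighbors <= 10
  t
}

# Run the full mask-free pipeline on a generated monolayer truth.
filtered_truth <- function(g) {
  t <- g$truth
  t <- flag_edge_cells(t)
  filter_cells(t)
}

# Generate a filtered synthetic tessellation from truth (no rasterization
# round trip), sized to stay under ~100 bulk cells.
small_tessellation <- function(seed, disorder = 0.35, n_cells = 80) {
  g <- generate_monolayer(monolayer_spec(n_cells = n_cells,
                                         disorder = disorder,
                                         image_size_px = 256,
                                         pixel_size_um = 1, seed = seed))
  filtered_truth(g)
}

# --- brute-force topology oracles (per-cell loops) -----------------------

oracle_bin_means <- function(t, value_col, rescale_by = 1) {
  cells <- t$cells[t$cells$kept, ]
  ns <- sort(unique(cells$n_neighbors))
  out <- data.frame(n = ns, mean = NA_real_, sem = NA_real_, count = NA_integer_)
  for (k in seq_along(ns)) {
    vals <- c()
    for (i in seq_len(nrow(cells)))
      if (cells$n_neighbors[i] == ns[k])
        vals <- c(vals, cells[[value_col]][i] / rescale_by)
    out$mean[k] <- sum(vals) / length(vals)
    out$count[k] <- length(vals)
    out$sem[k] <- if (length(vals) >= 2)
      sqrt(sum((vals - out$mean[k])^2) / (length(vals) - 1)) / sqrt(length(vals))
    else NA_real_
  }
  out
}

oracle_lewis <- function(t) oracle_bin_means(t, "rescaled_area")

oracle_desch <- function(t, mode_val) {
  oracle_bin_means(t, "perimeter_um", rescale_by = mode_val)
}

oracle_aboav <- function(t) {
  cells <- t$cells[t$cells$kept, ]
  all_n <- t$cells$n_neighbors
  names(all_n) <- as.character(t$cells$label)
  mu <- mean(cells$n_neighbors)
  sigma2 <- 0
  for (v in cells$n_neighbors) sigma2 <- sigma2 + (v - mu)^2
  sigma2 <- sigma2 / nrow(cells)
  ns <- sort(unique(cells$n_neighbors))
  out <- data.frame(n = ns, mu_m = NA_real_, b = NA_real_, count = NA_integer_)
  for (k in seq_along(ns)) {
    vals <- c()
    for (i in seq_len(nrow(cells))) {
      if (cells$n_neighbors[i] != ns[k]) next
      nb <- t$neighbors[[as.character(cells$label[i])]]
      s <- 0
      for (m in nb) s <- s + all_n[[as.character(m)]]
      vals <- c(vals, s / length(nb))
    }
    out$mu_m[k] <- sum(vals) / length(vals)
    out$count[k] <- length(vals)
    out$b[k] <- (ns[k] - 6) * out$mu_m[k] - sigma2
  }
  list(aboav = out, sigma2 = sigma2)
}

# Brute-force pixel-scanning adjacency on small masks: same contact
# definition as build_adjacency (orthogonal + corner contact, excluding
# four-fold crossing/pinch signatures), found by explicit per-pixel loops.
oracle_adjacency <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  at <- function(r, c) if (r < 1 || r > nr || c < 1 || c > nc) 0L else lab[r, c]
  pairs <- list()
  add <- function(a, b) {
    k <- paste(min(a, b), max(a, b))
    pairs[[k]] <<- TRUE
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    A <- lab[r, c]
    if (A == 0L) next
    # orthogonal right
    D <- at(r, c + 1)
    if (D > 0L && D != A) {
      up1 <- at(r - 1, c); up2 <- at(r - 1, c + 1)
      dn1 <- at(r + 1, c); dn2 <- at(r + 1, c + 1)
      crossing <- up1 == up2 && dn1 == dn2 && up1 > 0L && dn1 > 0L &&
        up1 != dn1 && !(up1 %in% c(A, D)) && !(dn1 %in% c(A, D))
      if (!crossing) add(A, D)
    }
    # orthogonal down
    D <- at(r + 1, c)
    if (D > 0L && D != A) {
      l1 <- at(r, c - 1); l2 <- at(r + 1, c - 1)
      r1 <- at(r, c + 1); r2 <- at(r + 1, c + 1)
      crossing <- l1 == l2 && r1 == r2 && l1 > 0L && r1 > 0L &&
        l1 != r1 && !(l1 %in% c(A, D)) && !(r1 %in% c(A, D))
      if (!crossing) add(A, D)
    }
    # diagonal down-right (2x2 block with r,c top-left)
    D <- at(r + 1, c + 1)
    B <- at(r, c + 1); C <- at(r + 1, c)
    if (D > 0L && D != A &&
        !(B > 0L && C > 0L && !(B %in% c(A, D)) && !(C %in% c(A, D))))
      add(A, D)
    # diagonal down-left effect covered by the anti-diagonal of the block
    # whose top-left is (r, c-1); handle explicitly:
    D <- at(r + 1, c - 1)
    B <- at(r, c - 1); C <- at(r + 1, c)
    if (D > 0L && D != A &&
        !(B > 0L && C > 0L && !(B %in% c(A, D)) && !(C %in% c(A, D))))
      add(A, D)
  }
  out <- list()
  for (k in names(pairs)) {
    ab <- as.integer(strsplit(k, " ")[[1]])
    out[[as.character(ab[1])]] <- sort(c(out[[as.character(ab[1])]], ab[2]))
    out[[as.character(ab[2])]] <- sort(c(out[[as.character(ab[2])]], ab[1]))
  }
  out
}

# Direct Hertz force evaluation (independent re-derivation, SI units).
oracle_hertz_force_N <- function(delta_m, E_pa, R_m, nu) {
  if (delta_m <= 0) return(0)
  4 / 3 * E_pa / (1 - nu^2) * sqrt(R_m) * delta_m^1.5
}

# Render a filled disc / ellipse / square / regular hexagon label mask.
shape_mask <- function(kind, size = 131, a = 50, b = 25) {
  cx <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size), each = size), size) - cx   # x (col)
  ys <- matrix(rep(seq_len(size), times = size), size) - cx  # y (row)
  M <- matrix(0L, size, size)
  inside <- switch(kind,
    disc = xs^2 + ys^2 <= a^2,
    ellipse = (xs / a)^2 + (ys / b)^2 <= 1,
    square = abs(xs) <= a / 2 & abs(ys) <= a / 2,
    hexagon = {
      ok <- matrix(TRUE, size, size)
      for (th in (0:5) * pi / 3 + pi / 6)
        ok <- ok & (xs * cos(th) + ys * sin(th) <= a * sqrt(3) / 2)
      ok
    })
  M[inside] <- 1L
  M
}
# Temp file cleaned up when the test completes.
withr_local_tempfile <- function(ext, env = parent.frame()) {
  path <- tempfile(fileext = ext)
  withr::defer(unlink(path), envir = env)
  path
}
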