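test_that("shape factor summary reproduces closed forms", {
  # unit squares: p = 4 exactly
  t <- toy_tessellation(areas = rep(1, 8), perims = rep(4, 8),
                        n_neighbors = rep(4, 8))
  expect_equal(shape_factor_summary(t)$mean, 4)
  # regular hexagons from the disorder-0 generator truth
  g <- generate_monolayer(monolayer_spec(64, 0, 512, 1, seed = 1))
  th <- filtered_truth(g)
  expect_equal(shape_factor_summary(th)$mean, 6 / sqrt(3 * sqrt(3) / 2),
               tolerance = 1e-10)
  # empty analysis set errors
  t$cells$kept <- FALSE
  expect_error(shape_factor_summary(t), "empty")
})

test_that("rescaled-area PDF normalizes and finds two-population structure", {
  t <- toy_tessellation(areas = rep(1, 50), n_neighbors = rep(6, 50))
  p <- rescaled_area_pdf(t, bin_width = 0.1)
  expect_equal(sum(p$density * diff(seq(0, 2, 0.1))), 1, tolerance = 1e-6)
  expect_equal(p$mode, 1, tolerance = 0.06)  # all mass in the bin holding 1
  # bimodal mixture: modes near the two component medians
  set.seed(7)
  x <- c(exp(rnorm(4000, log(0.55), 0.08)), exp(rnorm(4000, log(1.45), 0.08)))
  p2 <- rescaled_area_pdf(x, bin_width = 0.1)
  dens <- p2$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  peak_pos <- p2$bin_centers[peaks[order(dens[peaks], decreasing = TRUE)][1:2]]
  expect_equal(sort(peak_pos), c(0.55, 1.45), tolerance = 0.1)
})

test_that("histogram-peak mode estimators recover analytic modes", {
  expect_equal(rescaled_perimeter_mode(rep(84, 60)), 84)
  set.seed(21)
  x <- exp(rnorm(1e4, log(80), 0.25))
  expect_equal(rescaled_perimeter_mode(x), 80 * exp(-0.25^2),
               tolerance = 0.03)
  # hexagonal lattice: all rescaled perimeters are 1
  g <- generate_monolayer(monolayer_spec(64, 0, 512, 1, seed = 1))
  th <- filtered_truth(g)
  d <- desch_law(th)
  expect_equal(d$mean, 1, tolerance = 1e-6)
})

test_that("Lewis and Desch laws reproduce hand-computed toys", {
  nb <- NULL
  t <- toy_tessellation(areas = c(0.8, 0.9, 1.0, 1.2),
                        n_neighbors = c(5, 5, 6, 7))
  t$cells$rescaled_area <- c(0.8, 0.9, 1.0, 1.2)  # as stated in the toy
  lw <- lewis_law(t)
  expect_equal(lw$mean[lw$n == 5], 0.85)
  expect_equal(lw$mean[lw$n == 6], 1.0)
  expect_equal(lw$mean[lw$n == 7], 1.2)
  expect_true(is.na(lw$sem[lw$n == 6]))  # single-cell class: no SEM
  expect_identical(lw$count, c(2L, 1L, 1L))

  t2 <- toy_tessellation(areas = rep(1, 3), perims = c(0.9, 0.9, 1.1),
                         n_neighbors = c(5, 5, 7))
  d <- desch_law(t2, rescale = "mean")
  ref <- mean(c(0.9, 0.9, 1.1))
  expect_equal(d$mean[d$n == 5], 0.9 / ref)
  expect_equal(d$mean[d$n == 7], 1.1 / ref)
})

test_that("Lewis law single point and monotonicity on generated tessellations", {
  g <- generate_monolayer(monolayer_spec(64, 0, 512, 1, seed = 1))
  lw <- lewis_law(filtered_truth(g))
  expect_identical(nrow(lw), 1L)
  expect_identical(lw$n, 6L)
  expect_equal(lw$mean, 1, tolerance = 1e-9)
  # disordered Voronoi: area and perimeter increase with neighbor count
  t <- small_tessellation(seed = 2, disorder = 0.4, n_cells = 300)
  lw2 <- lewis_law(t)
  sel <- lw2$n >= 4 & lw2$n <= 8 & lw2$count >= 5
  expect_true(all(diff(lw2$mean[sel]) > 0))
  d2 <- desch_law(t)
  seld <- d2$n >= 4 & d2$n <= 8 & d2$count >= 5
  expect_true(all(diff(d2$mean[seld]) > 0))
})

test_that("Aboav-Weaire reproduces the hand-computed toy", {
  # n-distribution {5,5,6,6,6,7,7}: mean 6, population variance 4/7
  nbrs <- list(`1` = c(3L, 4L, 5L, 6L, 2L),     # sizes {6,6,6,7,5}
               `2` = c(3L, 4L, 5L, 7L, 1L),     # sizes {6,6,6,7,5}
               `3` = c(1L, 2L, 4L, 5L, 6L, 7L),
               `4` = c(1L, 2L, 3L, 5L, 6L, 7L),
               `5` = c(1L, 2L, 3L, 4L, 6L, 7L),
               `6` = c(1L, 3L, 4L, 5L, 7L, 2L, 3L),
               `7` = c(2L, 3L, 4L, 5L, 6L, 1L, 4L))
  t <- toy_tessellation(areas = rep(1, 7), neighbors = nbrs,
                        n_neighbors = c(5, 5, 6, 6, 6, 7, 7))
  aw <- aboav_weaire(t)
  expect_equal(aw$sigma2, 4 / 7)
  expect_equal(aw$aboav$mu_m[aw$aboav$n == 5], 6.0)
  expect_equal(aw$aboav$b[aw$aboav$n == 5], (5 - 6) * 6 - 4 / 7)
  expect_equal(aw$aboav$b[aw$aboav$n == 5], -6.571, tolerance = 1e-3)
})

test_that("b(6) = -sigma^2 identically on every sample", {
  for (s in 1:5) {
    t <- small_tessellation(seed = s, disorder = 0.45, n_cells = 120)
    aw <- aboav_weaire(t)
    if (any(aw$aboav$n == 6))
      expect_equal(aw$aboav$b[aw$aboav$n == 6], -aw$sigma2, tolerance = 1e-12)
  }
  # hexagonal limit: b(6) = 0; mu_m = 6 for cells whose whole neighborhood
  # lies away from the image border (border cells have truncated
  # neighborhoods, which lowers mu_m near the rim as in real images)
  g <- generate_monolayer(monolayer_spec(64, 0, 512, 1, seed = 1))
  t <- filtered_truth(g)
  aw <- aboav_weaire(t)
  expect_equal(aw$aboav$b, 0)
  border <- t$cells$label[t$cells$touches_border]
  deep <- vapply(as.character(t$cells$label), function(l)
    t$cells$kept[t$cells$label == as.integer(l)] &&
      !any(t$neighbors[[l]] %in% border), TRUE)
  t$cells$kept <- deep
  aw2 <- aboav_weaire(t)
  expect_equal(aw2$aboav$mu_m, 6)
})

test_that("frequency-weighted Lewis mean equals the overall rescaled-area mean", {
  t <- small_tessellation(seed = 9, disorder = 0.4, n_cells = 200)
  lw <- lewis_law(t)
  cells <- analysis_set(t)
  expect_equal(sum(lw$mean * lw$count) / sum(lw$count),
               mean(cells$rescaled_area), tolerance = 1e-12)
})

test_that("pooling across animals is a cell-count-weighted mean", {
  t1 <- small_tessellation(seed = 1)
  c1 <- topology_curves(t1, "m1")
  # one animal: identity
  p1 <- pool_across_animals(list(c1))
  expect_equal(p1$lewis$mean, c1$lewis$mean)
  expect_equal(p1$aboav$b, c1$aboav$b)
  # hand-weighted two-animal case
  mk <- function(b5, n_cells) {
    structure(list(lewis = data.frame(n = 5L, mean = 1, count = n_cells),
                   desch = data.frame(n = 5L, mean = 1, count = n_cells),
                   aboav = data.frame(n = 5L, mu_m = 6, b = b5,
                                      count = n_cells),
                   sigma2 = 0.5, n_cells = n_cells, sample_id = "toy"),
              class = "topology_curves")
  }
  pooled <- pool_across_animals(list(mk(-6, 1000), mk(-8, 3000)))
  expect_equal(pooled$aboav$b, -7.5)
  # equal weights reduce to the simple mean
  pe <- pool_across_animals(list(mk(-6, 10), mk(-8, 10)))
  expect_equal(pe$aboav$b, -7)
  # all-equal inputs are returned unchanged
  pa <- pool_across_animals(list(mk(-6, 10), mk(-6, 99)))
  expect_equal(pa$aboav$b, -6)
  expect_error(pool_across_animals(list()), "no curves")
})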