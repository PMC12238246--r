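test_that("phagocytosis efficiency equals the constructed fraction exactly", {
  for (f in c(0, 0.3, 0.5, 1)) {
    st <- generate_pos_stack(pos_spec(n_particles = 10,
                                      fraction_internalized = f, seed = 2))
    expect_identical(phagocytosis_efficiency(st)$efficiency, f)
  }
  st <- generate_pos_stack(pos_spec(10, 0.3, seed = 2))
  pe <- phagocytosis_efficiency(st)
  expect_identical(sum(pe$classification$internalized), 3L)
  expect_true(all(pe$classification$internalized ==
                  st$classification$internalized_truth))
})

test_that("efficiency is invariant to relabeling and z-anisotropy", {
  st <- generate_pos_stack(pos_spec(12, 0.5, seed = 7))
  e0 <- phagocytosis_efficiency(st)$efficiency
  # permute labels
  perm <- sample(12)
  st2 <- st
  st2$labels[st$labels > 0] <- perm[st$labels[st$labels > 0]]
  expect_identical(phagocytosis_efficiency(st2)$efficiency, e0)
  # classification uses physical heights: halving z-voxel size while
  # doubling slice count leaves every centroid height identical
  st3 <- st
  nz <- dim(st$labels)[1]
  lab3 <- array(0L, c(2 * nz, dim(st$labels)[2], dim(st$labels)[3]))
  lab3[seq(1, 2 * nz, 2), , ] <- st$labels
  lab3[seq(2, 2 * nz, 2), , ] <- st$labels
  st3$labels <- lab3
  st3$voxel_size_um <- c(st$voxel_size_um[1] / 2, st$voxel_size_um[2:3])
  expect_equal(phagocytosis_efficiency(st3)$efficiency, e0)
  # empty stack errors
  st$labels[] <- 0L
  expect_error(phagocytosis_efficiency(st), "undefined")
})

test_that("particle placement respects bounds and determinism", {
  st1 <- generate_pos_stack(pos_spec(20, 0.5, seed = 9))
  st2 <- generate_pos_stack(pos_spec(20, 0.5, seed = 9))
  expect_identical(st1$labels, st2$labels)
  # internalized centroids strictly below the surface, bound strictly above
  pe <- phagocytosis_efficiency(st1)
  surf <- mean(st1$surface_um)
  expect_true(all(pe$classification$centroid_z_um[pe$classification$internalized] < surf))
  expect_true(all(pe$classification$centroid_z_um[!pe$classification$internalized] > surf))
  # an over-packed stack cannot be placed
  expect_error(generate_pos_stack(pos_spec(500, 0.5,
                                           stack_shape = c(24L, 32L, 32L))),
               "overlap|admissible")
})

test_that("proliferation ratio counts EdU-positive nuclei over DAPI nuclei", {
  dapi <- matrix(0L, 120, 120)
  edu <- matrix(0L, 120, 120)
  centers <- expand.grid(r = seq(10, 110, 10), c = seq(10, 110, 10))[1:100, ]
  for (i in seq_len(100)) {
    dapi[centers$r[i] + (-2:2), centers$c[i] + (-2:2)] <- 1L
  }
  for (i in 1:5) edu[centers$r[i], centers$c[i]] <- 1L
  expect_equal(proliferation_ratio(edu, dapi), 0.05)
  # empty EdU mask: ratio 0
  expect_equal(proliferation_ratio(matrix(0L, 120, 120), dapi), 0)
  # ROI restriction by nucleus centroid
  roi <- matrix(FALSE, 120, 120); roi[1:60, 1:120] <- TRUE
  in_roi <- centers$r <= 60
  expect_equal(proliferation_ratio(edu, dapi, roi),
               sum(centers$r[1:5] <= 60) / sum(in_roi))
  expect_error(proliferation_ratio(edu, matrix(0L, 120, 120)), "no nuclei")
})

test_that("radial distances map onto the anatomical regions", {
  expect_identical(as.character(region_of_distance(800)), "centre")
  expect_identical(as.character(region_of_distance(1500)), "mid_periphery")
  expect_identical(as.character(region_of_distance(2500)), "far_periphery")
  expect_identical(as.character(region_of_distance(c(100, 3500))),
                   c("unassigned", "unassigned"))
  # half-open boundaries
  expect_identical(as.character(region_of_distance(1200)), "mid_periphery")
  expect_identical(as.character(region_of_distance(3000)), "unassigned")
  expect_error(region_of_distance(-5), "non-negative")
  expect_error(region_bins(centre = c(300, 1100)), "contiguous")
})

test_that("per-eye normalization fixes each group's maximum at 1 and is idempotent", {
  v <- c(10, 20, 40, 5, 10)
  g <- c("a", "a", "a", "b", "b")
  n1 <- normalize_per_eye(v, g)
  expect_equal(n1, c(0.25, 0.5, 1, 0.5, 1))
  expect_equal(as.numeric(tapply(n1, g, max)), c(1, 1))
  expect_equal(normalize_per_eye(n1, g), n1)
  expect_equal(normalize_per_eye(c(0.2, 0.5, 1.0), rep(1, 3)),
               c(0.2, 0.5, 1.0))
  expect_error(normalize_per_eye(c(0, 0), c(1, 1)), "positive")
})

test_that("ROI mean intensities match analytic values", {
  img <- matrix(7, 50, 50)
  sq <- cbind(c(5, 30, 30, 5), c(5, 5, 30, 30))
  expect_equal(roi_mean_intensity(img, list(sq)), 7)
  # half-0 / half-10 image, ROI symmetric across the split
  img2 <- matrix(0, 50, 50); img2[, 26:50] <- 10
  roi <- cbind(c(15.5, 35.5, 35.5, 15.5), c(10, 10, 40, 40))
  expect_equal(roi_mean_intensity(img2, list(roi)), 5)
  # linear gradient: mean over the ROI equals the analytic midpoint
  gr <- matrix(rep(1:50, each = 50), 50)
  m <- roi_mean_intensity(gr, list(cbind(c(10.5, 20.5, 20.5, 10.5),
                                         c(10, 10, 40, 40))))
  expect_equal(m, 15.5, tolerance = 0.01)
  expect_error(roi_mean_intensity(img, list(cbind(c(100, 110, 110),
                                                  c(100, 100, 110)))),
               "outside")
})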