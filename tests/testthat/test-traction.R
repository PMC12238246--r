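rel_l2 <- function(a, b)
  sqrt(sum((a$vx - b$vx)^2 + (a$vy - b$vy)^2) / sum(b$vx^2 + b$vy^2))

test_that("traction scenes are balanced and linear in the gel modulus", {
  sc <- generate_traction_scene(traction_spec("gaussian_dipole", 170,
                                              gel_E = 4000, grid_n = 32,
                                              grid_spacing_um = 8))
  tt <- sc$truth_traction
  expect_lt(abs(sum(tt$vx)) + abs(sum(tt$vy)),
            1e-9 * mean(sqrt(tt$vx^2 + tt$vy^2)) * length(tt$vx))
  # doubling the gel stiffness halves every displacement
  sp2 <- traction_spec("gaussian_dipole", 170, gel_E = 8000, grid_n = 32,
                       grid_spacing_um = 8)
  sc2 <- generate_traction_scene(sp2)
  expect_equal(sc$displacement$vx, 2 * sc2$displacement$vx, tolerance = 1e-12)
  # zero pattern: identically zero displacement
  sz <- generate_traction_scene(traction_spec("zero", 0, grid_n = 16,
                                              grid_spacing_um = 8))
  expect_identical(max(abs(sz$displacement$vx)), 0)
  expect_identical(max(abs(sz$displacement$vy)), 0)
  # uniform inward annulus is balanced too
  sa <- generate_traction_scene(traction_spec("uniform_disc", 100,
                                              grid_n = 32, grid_spacing_um = 8))
  ta <- sa$truth_traction
  expect_lt(abs(sum(ta$vx)) + abs(sum(ta$vy)),
            1e-9 * mean(sqrt(ta$vx^2 + ta$vy^2)) * length(ta$vx))
})

test_that("FTTC inverts forward-simulated scenes", {
  sc <- generate_traction_scene(traction_spec("gaussian_dipole", 170,
                                              gel_E = 4000, grid_n = 32,
                                              grid_spacing_um = 8))
  gel <- gel_spec(4000, 0.5, 12)
  tr <- fttc(sc$displacement, gel, lambda = 0)
  expect_lt(rel_l2(tr, sc$truth_traction), 0.10)
  # peak recovered within 10%
  expect_equal(max(sqrt(tr$vx^2 + tr$vy^2)),
               max(sqrt(sc$truth_traction$vx^2 + sc$truth_traction$vy^2)),
               tolerance = 0.10)
  # zero displacement -> zero traction
  zu <- vector_field(matrix(0, 16, 16), matrix(0, 16, 16), 8, "displacement")
  tz <- fttc(zu, gel, 0)
  expect_identical(max(abs(tz$vx)) + max(abs(tz$vy)), 0)
  # linearity at fixed lambda
  d2 <- sc$displacement; d2$vx <- 2 * d2$vx; d2$vy <- 2 * d2$vy
  t1 <- fttc(sc$displacement, gel, 1e-10)
  t2 <- fttc(d2, gel, 1e-10)
  expect_equal(2 * t1$vx, t2$vx, tolerance = 1e-8)
  expect_error(fttc(sc$displacement, gel, -1), "non-negative")
})

test_that("FTTC error decreases monotonically under grid refinement", {
  errs <- vapply(c(16, 32, 64), function(gn) {
    sc <- generate_traction_scene(traction_spec("gaussian_dipole", 170,
                                                gel_E = 4000, grid_n = gn,
                                                grid_spacing_um = 256 / gn))
    rel_l2(fttc(sc$displacement, gel_spec(4000, 0.5, 12), 0),
           sc$truth_traction)
  }, 1.0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[2], 0.10)
})

test_that("mean traction handles masks and degenerate inputs", {
  f <- vector_field(matrix(100, 8, 8), matrix(0, 8, 8), 4, "traction")
  expect_equal(mean_traction(f), 100)
  z <- vector_field(matrix(0, 8, 8), matrix(0, 8, 8), 4, "traction")
  expect_identical(mean_traction(z), 0)
  m <- matrix(FALSE, 8, 8); m[1:4, ] <- TRUE
  expect_equal(mean_traction(f, m), 100)
  expect_error(mean_traction(f, matrix(FALSE, 8, 8)), "empty mask")
})

test_that("the stress solver matches the one-dimensional force-balance oracle", {
  n <- 64; d <- 4; T0 <- 100; L <- n * d; h <- 10
  X <- matrix(rep((seq_len(n) - 0.5) * d, each = n), n)
  tx <- matrix(T0, n, n); tx[X >= L / 2] <- -T0
  tf <- vector_field(tx, matrix(0, n, n), d, "traction")
  st <- monolayer_stress(tf, gel_spec(4000, 0.5, height_um = h))
  # midline average normal stress: sigma_xx = T0 L / (2h), sigma_yy = 0
  expect_equal(max(st$avg_normal_pa), T0 * L / (4 * h), tolerance = 0.03)
  # stress scales as 1/h
  st2 <- monolayer_stress(tf, gel_spec(4000, 0.5, height_um = 2 * h))
  expect_equal(st$avg_normal_pa, 2 * st2$avg_normal_pa, tolerance = 1e-9)
  # zero traction -> zero stress
  z <- vector_field(matrix(0, 16, 16), matrix(0, 16, 16), 4, "traction")
  sz <- monolayer_stress(z, gel_spec(4000, 0.5, h))
  expect_equal(max(abs(sz$avg_normal_pa)), 0, tolerance = 1e-12)
  # unbalanced input is rejected with advice
  bad <- vector_field(matrix(10, 16, 16), matrix(0, 16, 16), 4, "traction")
  expect_error(monolayer_stress(bad, gel_spec(4000, 0.5, h)), "DC")
})

test_that("equilibrated moment-free fields have near-zero mean signed stress", {
  sc <- generate_traction_scene(traction_spec("gaussian_quadrupole", 100,
                                              grid_n = 64, grid_spacing_um = 4))
  st <- monolayer_stress(sc$truth_traction, gel_spec(4000, 0.5, 10))
  expect_lt(abs(st$summary$mean_signed_pa), 0.05 * st$summary$mean_abs_pa)
})

test_that("recovered fields satisfy energy consistency", {
  sc <- generate_traction_scene(traction_spec("gaussian_dipole", 170,
                                              gel_E = 4000, grid_n = 32,
                                              grid_spacing_um = 8))
  tr <- fttc(sc$displacement, gel_spec(4000, 0.5, 12), 0)
  # substrate strain energy density is non-negative: <u . T> >= 0
  expect_gt(mean(sc$displacement$vx * tr$vx + sc$displacement$vy * tr$vy), 0)
})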