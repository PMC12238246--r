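test_that("Hertz force matches an independent hand evaluation", {
  # 200 nm indentation, E = 5 kPa, nu = 0.3, R = 3.31 um -> 1.19 nN
  got <- hertz_force(0.2, 5000, 3.31, 0.3)
  want <- oracle_hertz_force_N(0.2e-6, 5000, 3.31e-6, 0.3)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got * 1e9, 1.19, tolerance = 0.005)
  expect_identical(hertz_force(0, 5000, 3.31, 0.3), 0)     # zero at contact
  expect_identical(hertz_force(-1, 5000, 3.31, 0.3), 0)    # zero before contact
})

test_that("generated curves are Hertzian past contact and monotone when noiseless", {
  sp <- force_curve_spec(E_true = 5000, contact_point = 0.8, z_range = 2)
  fc <- generate_force_curve(sp)
  expect_true(all(fc$F_N[fc$z_um < 0.8] == 0))
  expect_true(all(diff(fc$F_N) >= 0))
  # determinism
  sp2 <- force_curve_spec(1500, noise_sd = 1e-10, seed = 3)
  expect_identical(generate_force_curve(sp2)$F_N, generate_force_curve(sp2)$F_N)
})

test_that("background subtraction removes lines and recovers generator slopes", {
  z <- seq(0, 5, length.out = 100)
  linec <- force_curve(z, 2e-9 * z + 1e-10, 10, 0.5)
  out <- subtract_background(linec)
  expect_equal(max(abs(out$F_N)), 0, tolerance = 1e-22)
  zero <- subtract_background(force_curve(z, rep(0, 100), 10, 0.5))
  expect_identical(max(abs(zero$F_N)), 0)
  # synthetic Hertz + line: fitted line matches the generator within 1%
  sp <- force_curve_spec(E_true = 2000, contact_point = 3, probe_radius = 10,
                         poisson = 0.5, background_slope = 5e-10,
                         n_points = 300, z_range = 5)
  fc <- generate_force_curve(sp)
  sub <- subtract_background(fc, tail_fraction = 0.45, baseline = "head")
  bg <- attr(sub, "background")
  expect_equal(unname(bg["slope"]), 5e-10, tolerance = 0.01)
  expect_error(subtract_background(force_curve(z[1:20], rep(0, 20), 10, 0.5),
                                   tail_fraction = 0.1), "5 points")
})

test_that("whole-curve Hertz fit recovers noiseless parameters", {
  sp <- force_curve_spec(E_true = 5000, contact_point = 1, probe_radius = 3.31,
                         poisson = 0.3, z_range = 2, n_points = 200)
  ft <- fit_hertz(generate_force_curve(sp))
  expect_true(ft$converged)
  expect_equal(ft$E_pa, 5000, tolerance = 1e-3)
  expect_lt(abs(ft$contact_point_um - 1), 1e-3)  # within 1 nm
  expect_gt(ft$r_squared, 0.999999)
  # degenerate input
  z <- seq(0, 2, length.out = 50)
  expect_false(fit_hertz(force_curve(z, rep(0, 50), 3.31, 0.3))$converged)
})

test_that("force scaling maps linearly onto the fitted modulus", {
  sp <- force_curve_spec(E_true = 1500, contact_point = 1, probe_radius = 3.31,
                         poisson = 0.3, z_range = 2.5)
  fc <- generate_force_curve(sp)
  f1 <- fit_hertz(fc)
  fc$F_N <- fc$F_N * 3
  f3 <- fit_hertz(fc)
  expect_equal(f3$E_pa / f1$E_pa, 3, tolerance = 1e-6)
})

test_that("an added line changes the fitted modulus by <0.5% after subtraction", {
  sp <- force_curve_spec(E_true = 4000, contact_point = 2, probe_radius = 3.31,
                         poisson = 0.3, z_range = 4, n_points = 300)
  fc <- generate_force_curve(sp)
  e0 <- fit_hertz(fc)$E_pa
  fc2 <- fc
  fc2$F_N <- fc2$F_N + 3e-10 * fc2$z_um + 2e-10
  e1 <- fit_hertz(subtract_background(fc2, baseline = "head"))$E_pa
  expect_lt(abs(e1 / e0 - 1), 0.005)
})

test_that("round-trip recovery meets the accuracy ladder across noise levels", {
  # median relative error <= 0.1%, 2%, 8% at 0%, 1%, 5% force noise
  Es <- c(500, 1500, 4000, 5500, 18000)
  tols <- c(`0` = 0.001, `0.01` = 0.02, `0.05` = 0.08)
  for (noise in c(0, 0.01, 0.05)) {
    errs <- c()
    for (E in Es) {
      fmax <- hertz_force(1.5, E, 3.31, 0.3)
      for (s in 1:10) {
        sp <- force_curve_spec(E_true = E, contact_point = 0.5,
                               probe_radius = 3.31, poisson = 0.3,
                               noise_sd = noise * fmax, n_points = 150,
                               z_range = 2, seed = s)
        ft <- fit_hertz(generate_force_curve(sp))
        errs <- c(errs, abs(ft$E_pa - E) / E)
      }
    }
    expect_lt(stats::median(errs), tols[[as.character(noise)]])
  }
})

test_that("nanoindentation protocol recovers E and applies its gates", {
  sp <- force_curve_spec(E_true = 1500, contact_point = 3, probe_radius = 10,
                         poisson = 0.5, n_points = 400, z_range = 8,
                         noise_sd = 0.01 * hertz_force(5, 1500, 10, 0.5),
                         seed = 2)
  ft <- fit_hertz_nanoindentation(generate_force_curve(sp))
  expect_true(ft$converged)
  expect_true(ft$accepted)
  expect_equal(ft$E_pa, 1500, tolerance = 0.02)
  # contact point must sit in the low-load region
  fc <- generate_force_curve(sp)
  expect_lte(fc$F_N[which.min(abs(fc$z_um - ft$contact_point_um))],
             0.3 * max(fc$F_N))
  # heavy noise destroys the fit quality and the gate rejects it
  spb <- force_curve_spec(E_true = 1500, contact_point = 3, probe_radius = 10,
                          poisson = 0.5, n_points = 400, z_range = 8,
                          noise_sd = 0.35 * hertz_force(5, 1500, 10, 0.5),
                          seed = 4)
  fb <- fit_hertz_nanoindentation(generate_force_curve(spb))
  expect_true(!fb$converged || fb$r_squared <= 0.95)
  if (fb$converged) expect_false(fb$accepted)
  expect_error(fit_hertz_nanoindentation(generate_force_curve(sp),
                                         depth_window_um = c(0, 0)),
               "degenerate")
})

test_that("mode stiffness uses log-spaced histogram peaks", {
  expect_equal(mode_stiffness(rep(4000, 50)), 4000)
  set.seed(12)
  x <- exp(rnorm(1e4, log(2000), 0.5))
  expect_equal(mode_stiffness(x), 2000 * exp(-0.25), tolerance = 0.05)
  expect_error(mode_stiffness(rep(1000, 5)), "median")
})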