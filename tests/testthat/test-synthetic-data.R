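# Seeded generators: determinism, ground-truth fidelity, degenerate cases.

test_that("all generators are pure functions of their spec", {
  fs <- fiber_image_spec(n_fibers = 8, seed = 42)
  expect_identical(generate_fiber_image(fs), generate_fiber_image(fs))
  ss <- spectrum_spec(noise_sd = 0.02, seed = 42)
  expect_identical(generate_spectrum(ss), generate_spectrum(ss))
  cs <- force_curve_spec(noise_sd_nN = 0.05, seed = 42)
  expect_identical(generate_force_curve(cs), generate_force_curve(cs))
  ms <- mask_pair_spec(c(32, 32), 40, 30, 10, seed = 42)
  expect_identical(generate_mask_pair(ms), generate_mask_pair(ms))
})

test_that("empty fiber scene is pure noise with an empty truth mask", {
  sim <- generate_fiber_image(fiber_image_spec(n_fibers = 0, noise_sd = 0.1,
                                               seed = 3))
  expect_equal(sum(sim$truth_mask), 0)
  expect_equal(nrow(sim$fibers), 0)
  expect_equal(sd(sim$image), 0.1, tolerance = 0.05)
  expect_equal(mean(sim$image), 0, tolerance = 0.01)
})

test_that("painted stroke width matches the declared diameter", {
  # 0.5 um fibers at 0.05 um/px are 10 px wide; measure the painted mask
  # directly with the distance transform, independent of the analysis stack
  sim <- generate_fiber_image(fiber_image_spec(
    n_fibers = 30, fiber_width_um = 0.5, width_cv = 0, pixel_size_um = 0.05,
    fiber_length_um = 10, noise_sd = 0, seed = 5))
  edt <- EBImage::distmap(sim$truth_mask)
  # sample the distance transform along each stroke's true centerline
  pts <- do.call(rbind, lapply(seq_len(nrow(sim$fibers)), function(i) {
    f <- sim$fibers[i, ]
    t <- seq(0.05, 0.95, by = 0.05)
    cbind(floor(f$y0 + t * (f$y1 - f$y0)) + 1,
          floor(f$x0 + t * (f$x1 - f$x0)) + 1)
  }))
  keep <- pts[, 1] >= 1 & pts[, 1] <= 512 & pts[, 2] >= 1 & pts[, 2] <= 512
  measured <- 2 * median(edt[pts[keep, , drop = FALSE]]) - 1
  expect_equal(measured, 10, tolerance = 0.1 * 10)
})

test_that("fiber truth table records the drawn orientations and widths", {
  sim <- generate_fiber_image(fiber_image_spec(
    n_fibers = 25, orientation_mode_deg = 45, orientation_kappa = Inf,
    width_cv = 0, seed = 2))
  expect_true(all(sim$fibers$orientation_deg == 45))
  expect_true(all(sim$fibers$width_um == 0.5))
})

test_that("invalid fiber specs are rejected", {
  expect_error(fiber_image_spec(width_px = 0), class = "ecmquant_invalid_spec")
  expect_error(fiber_image_spec(pixel_size_um = -1),
               class = "ecmquant_invalid_spec")
  expect_error(fiber_image_spec(n_fibers = -3),
               class = "ecmquant_invalid_spec")
  expect_error(fiber_image_spec(orientation_kappa = -1),
               class = "ecmquant_invalid_spec")
})

test_that("spectrum components sum exactly to the emitted spectrum", {
  sim <- generate_spectrum(spectrum_spec(noise_sd = 0.02, seed = 9))
  expect_equal(sim$spectrum$intensity_au,
               sim$peak_component + sim$baseline_au + sim$noise_au)
  # no peaks, no noise: spectrum is the baseline polynomial
  bare <- generate_spectrum(spectrum_spec(
    peaks = data.frame(center = numeric(0), height = numeric(0),
                       fwhm = numeric(0)),
    baseline_coeffs = c(1, 2, -1), noise_sd = 0, seed = 1))
  wn <- bare$spectrum$wavenumber_cm1
  u <- (wn - min(wn)) / diff(range(wn))
  expect_equal(bare$spectrum$intensity_au, 1 + 2 * u - u^2)
})

test_that("a single unit peak attains height 1 at its nearest grid point", {
  sim <- generate_spectrum(spectrum_spec(
    wavenumber_grid = seq(1000, 1400, by = 2),
    peaks = data.frame(center = 1200, height = 1, fwhm = 30),
    baseline_coeffs = 0, noise_sd = 0, seed = 1))
  expect_equal(max(sim$spectrum$intensity_au), 1)
  expect_equal(sim$spectrum$wavenumber_cm1[which.max(sim$spectrum$intensity_au)],
               1200)
})

test_that("descending wavenumber grids are rejected", {
  expect_error(spectrum_spec(wavenumber_grid = seq(1800, 600, by = -2)),
               class = "ecmquant_invalid_spec")
  expect_error(spectrum_spec(peaks = data.frame(center = 5000, height = 1,
                                                fwhm = 10)),
               class = "ecmquant_invalid_spec")
})

test_that("noiseless force curves satisfy the Hertz law exactly", {
  # F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2) at delta = 100 nm
  f_manual_nN <- (4 / 3) * (1000 / (1 - 0.25)) * sqrt(5e-6) * (1e-7)^1.5 * 1e9
  expect_equal(hertz_force(100, 1000, 5, 0.5), f_manual_nN)
  cv <- generate_force_curve(force_curve_spec(
    E_pa = 1000, contact_point_nm = 0, max_indentation_nm = 100,
    n_points = 101, noise_sd_nN = 0, seed = 1))
  at100 <- cv$force_nN[which.min(abs(cv$displacement_nm - 100))]
  expect_equal(at100, f_manual_nN, tolerance = 1e-12)
  # pre-contact region is pure baseline
  expect_true(all(cv$force_nN[cv$displacement_nm < 0] == 0))
})

test_that("zero indentation yields an all-baseline curve", {
  cv <- generate_force_curve(force_curve_spec(
    max_indentation_nm = 0, baseline_nN = 0.3, noise_sd_nN = 0, seed = 1))
  expect_true(all(cv$force_nN == 0.3))
})

test_that("invalid force-curve specs are rejected", {
  expect_error(force_curve_spec(poisson_ratio = 0.7),
               class = "ecmquant_invalid_spec")
  expect_error(force_curve_spec(n_points = 5),
               class = "ecmquant_invalid_spec")
  expect_error(force_curve_spec(E_pa = 0), class = "ecmquant_invalid_spec")
})

test_that("mask pairs have exactly the declared counts and overlap", {
  mp <- generate_mask_pair(mask_pair_spec(c(64, 64), 100, 50, 25, seed = 7))
  expect_equal(sum(mp$mask_a), 100)
  expect_equal(sum(mp$mask_b), 50)
  expect_equal(sum(mp$mask_a & mp$mask_b), 25)
  # disjoint and identical edge cases
  dj <- generate_mask_pair(mask_pair_spec(c(16, 16), 30, 20, 0, seed = 1))
  expect_equal(sum(dj$mask_a & dj$mask_b), 0)
  id <- generate_mask_pair(mask_pair_spec(c(16, 16), 40, 40, 40, seed = 1))
  expect_identical(id$mask_a, id$mask_b)
})

test_that("infeasible mask-pair specs are rejected", {
  expect_error(mask_pair_spec(c(8, 8), 40, 40, 50),
               class = "ecmquant_invalid_spec")
  expect_error(mask_pair_spec(c(4, 4), 10, 10, 1),
               class = "ecmquant_invalid_spec")
})

test_that("ellipse rasterization matches the analytic area", {
  m <- draw_ellipse_mask(c(256, 256), c(128, 128), 80, 40, angle_deg = 25)
  expect_equal(sum(m), pi * 80 * 40, tolerance = 0.01 * pi * 80 * 40)
})

test_that("stroke-pair crossing counter agrees with hand-built geometry", {
  cross <- tibble::tibble(x0 = c(0, 0), y0 = c(0, 10), x1 = c(10, 10),
                          y1 = c(10, 0))
  expect_equal(count_segment_crossings(cross), 1L)
  parallel <- tibble::tibble(x0 = c(0, 0), y0 = c(0, 5), x1 = c(10, 10),
                             y1 = c(0, 5))
  expect_equal(count_segment_crossings(parallel), 0L)
  touching <- tibble::tibble(x0 = c(0, 10), y0 = c(0, 10), x1 = c(10, 20),
                             y1 = c(10, 0))  # shared endpoint, no crossing
  expect_equal(count_segment_crossings(touching), 0L)
  outside <- tibble::tibble(x0 = c(0, 0), y0 = c(0, 10), x1 = c(10, 10),
                            y1 = c(10, 0))
  expect_equal(count_segment_crossings(outside, within = c(4, 4)), 0L)
})
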