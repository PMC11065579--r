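# Spectral pipeline: smoothing, background subtraction, normalization,
# band ratios, PCA.

wn_grid <- seq(600, 2000, by = 2)

test_that("Savitzky-Golay smoothing preserves low-degree polynomials", {
  u <- (wn_grid - mean(wn_grid)) / 700
  for (deg in c(4, 5)) {
    y <- rowSums(sapply(0:deg, function(k) (0.5)^k * u^k))
    sm <- raman_smooth(make_spectrum_tbl(wn_grid, y))
    expect_equal(sm$intensity_au, y, tolerance = 1e-10)
  }
  const <- raman_smooth(make_spectrum_tbl(wn_grid, rep(2.5, length(wn_grid))))
  expect_equal(const$intensity_au, rep(2.5, length(wn_grid)))
})

test_that("smoothing strictly reduces white-noise variance", {
  for (s in 1:5) {
    set.seed(s)
    y <- rnorm(length(wn_grid))
    sm <- raman_smooth(make_spectrum_tbl(wn_grid, y))
    expect_lt(var(sm$intensity_au), var(y))
  }
})

test_that("smoothing parameters are validated", {
  spec <- make_spectrum_tbl(wn_grid, rnorm(length(wn_grid)))
  expect_error(raman_smooth(spec, poly_order = 5, window = 5),
               class = "ecmquant_invalid_parameter")
  expect_error(raman_smooth(spec, window = 14),
               class = "ecmquant_invalid_parameter")
})

test_that("background fit reproduces a pure polynomial baseline", {
  u <- (wn_grid - min(wn_grid)) / diff(range(wn_grid))
  y <- 2 - 1.5 * u + 0.8 * u^2 - 0.3 * u^3
  out <- raman_subtract_background(make_spectrum_tbl(wn_grid, y))
  expect_lte(max(abs(out$intensity_au)), 1e-6 * diff(range(y)))
  expect_true(attr(out, "converged"))
})

test_that("peaks on a degree-5 baseline are recovered at their maxima", {
  sp <- spectrum_spec(wavenumber_grid = wn_grid,
                      baseline_coeffs = c(1.2, 0.8, -1.4, 0.6, -0.2, 0.05),
                      noise_sd = 0)
  sim <- generate_spectrum(sp)
  out <- raman_subtract_background(sim$spectrum)
  for (ctr in c(1265, 1300, 1650)) {
    i <- which.min(abs(wn_grid - ctr))
    expect_equal(out$intensity_au[i], sim$peak_component[i],
                 tolerance = 0.02)
  }
})

test_that("an already baseline-free peak spectrum passes nearly unchanged", {
  sp <- spectrum_spec(wavenumber_grid = wn_grid, baseline_coeffs = 0,
                      noise_sd = 0)
  sim <- generate_spectrum(sp)
  out <- raman_subtract_background(sim$spectrum)
  for (ctr in c(1265, 1300, 1650)) {
    i <- which.min(abs(wn_grid - ctr))
    expect_equal(out$intensity_au[i], sim$peak_component[i],
                 tolerance = 0.05)
  }
})

test_that("background subtraction is idempotent within its threshold", {
  sp <- spectrum_spec(wavenumber_grid = wn_grid,
                      baseline_coeffs = c(1.2, 0.8, -1.4, 0.6, -0.2, 0.05),
                      noise_sd = 0)
  once <- raman_subtract_background(generate_spectrum(sp)$spectrum)
  twice <- raman_subtract_background(once[, c("wavenumber_cm1",
                                              "intensity_au")])
  drift <- max(abs(twice$intensity_au - once$intensity_au)) /
    diff(range(once$intensity_au))
  expect_lt(drift, 1e-4)
})

test_that("min-max normalization attains exactly 0 and 1 and is affine
           invariant", {
  sim <- generate_spectrum(spectrum_spec(noise_sd = 0.01, seed = 4))
  nn <- raman_normalize(sim$spectrum)
  expect_equal(min(nn$intensity_norm), 0)
  expect_equal(max(nn$intensity_norm), 1)
  shifted <- sim$spectrum
  shifted$intensity_au <- 3.2 * shifted$intensity_au + 17
  expect_equal(raman_normalize(shifted)$intensity_norm, nn$intensity_norm)
  # midpoint arithmetic: min 2, max 12, value 7 -> 0.5
  y <- c(rep(2, 20), 7, rep(12, 20))
  small <- make_spectrum_tbl(seq_along(y) * 10 + 500, y)
  expect_equal(raman_normalize(small)$intensity_norm[21], 0.5)
  expect_error(raman_normalize(make_spectrum_tbl(wn_grid,
                                                 rep(1, length(wn_grid)))),
               class = "ecmquant_degenerate_input")
})

test_that("band ratios follow the amide/lipid definitions", {
  mk_peak <- function(h, ctr) h * exp(-4 * log(2) * (wn_grid - ctr)^2 / 20^2)
  y <- mk_peak(0.9, 1650) + mk_peak(0.45, 1300) + mk_peak(0.45, 1265)
  spec <- make_spectrum_tbl(wn_grid, y)
  spec$intensity_norm <- y
  pr <- peak_ratios(spec)
  expect_equal(pr$amide1_lipid, 2, tolerance = 0.02)
  expect_equal(pr$amide3_lipid, 1, tolerance = 0.02)
  # equal heights everywhere -> both ratios 1
  y2 <- mk_peak(0.5, 1650) + mk_peak(0.5, 1300) + mk_peak(0.5, 1265)
  s2 <- make_spectrum_tbl(wn_grid, y2)
  pr2 <- peak_ratios(s2)
  expect_equal(pr2$amide1_lipid, 1, tolerance = 0.05)
  # zero lipid band -> flagged undefined, not infinite
  y3 <- mk_peak(0.9, 1650)
  y3[abs(wn_grid - 1300) <= 15] <- 0
  y3[abs(wn_grid - 1265) <= 15] <- 0
  pr3 <- peak_ratios(make_spectrum_tbl(wn_grid, y3))
  expect_true(pr3$undefined_ratio)
  expect_true(is.na(pr3$amide1_lipid))
  # band window outside the grid errors
  expect_error(peak_ratios(spec, bands = c(amide1 = 1995, amide3 = 1265,
                                           lipid = 1300)),
               class = "ecmquant_invalid_parameter")
})

test_that("full pipeline recovers generator peak ratios at low noise", {
  sim <- generate_spectrum(spectrum_spec(noise_sd = 0.9 * 0.02, seed = 6))
  out <- process_spectrum(sim$spectrum)
  truth_peaks <- default_raman_peaks()
  truth_ratio <- truth_peaks$height[truth_peaks$center == 1650] /
    truth_peaks$height[truth_peaks$center == 1300]
  # ratios computed on the corrected (pre-normalization) intensities
  out2 <- out
  out2$intensity_norm <- NULL
  pr <- peak_ratios(out2)
  expect_equal(pr$amide1_lipid, truth_ratio, tolerance = 0.05 * truth_ratio)
})

test_that("PCA handles degenerate identical spectra", {
  sim <- generate_spectrum(spectrum_spec(noise_sd = 0, seed = 1))
  nn <- raman_normalize(sim$spectrum)
  pca <- raman_pca(list(nn, nn, nn))
  expect_true(pca$zero_variance)
  expect_equal(nrow(glance(pca)), 1)
})

test_that("PCA variance fractions are sorted, bounded, and reconstructive", {
  set.seed(3)
  mats <- lapply(1:6, function(i) {
    s <- generate_spectrum(spectrum_spec(noise_sd = 0.05, seed = i))
    raman_normalize(s$spectrum)
  })
  pca <- raman_pca(mats, n_components = 5)
  evf <- pca$all_variance_fractions
  expect_true(all(diff(evf) <= 1e-12))
  expect_true(all(evf >= 0 & evf <= 1))
  expect_lte(sum(evf), 1 + 1e-12)
  # full-rank reconstruction: scores %*% t(loadings) + center = data
  X <- ecmquant:::spectra_matrix(mats)
  sc <- as.matrix(pca$scores[, -1])
  ld <- as.matrix(pca$loadings[, -1])
  recon <- sc %*% t(ld) + matrix(pca$center, nrow(X), ncol(X), byrow = TRUE)
  expect_equal(unname(recon), unname(X), tolerance = 1e-10)
})

test_that("PCA scores separate two classes differing in amide-I height", {
  acc <- sapply(1:5, function(rep) {
    specs <- c(
      lapply(1:8, function(i) process_spectrum(generate_spectrum(
        spectrum_spec(noise_sd = 0.01, seed = rep * 1000 + i))$spectrum)),
      lapply(1:8, function(i) {
        pk <- default_raman_peaks()
        pk$height[pk$center == 1650] <- pk$height[pk$center == 1650] + 0.05
        process_spectrum(generate_spectrum(spectrum_spec(
          peaks = pk, noise_sd = 0.01, seed = rep * 2000 + i))$spectrum)
      }))
    pca <- raman_pca(specs)
    sc <- pca$scores$PC1
    cls <- rep(c(0, 1), each = 8)
    thr <- (mean(sc[cls == 0]) + mean(sc[cls == 1])) / 2
    pred <- as.integer(sc > thr)
    max(mean(pred == cls), mean(pred != cls))
  })
  expect_gte(mean(acc), 0.9)
})

test_that("PCA rejects mismatched wavenumber grids", {
  a <- raman_normalize(generate_spectrum(spectrum_spec(seed = 1))$spectrum)
  b <- raman_normalize(generate_spectrum(spectrum_spec(
    wavenumber_grid = seq(600, 2000, by = 4), seed = 2))$spectrum)
  expect_error(raman_pca(list(a, b)), class = "ecmquant_grid_mismatch")
})
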