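# Morphology, colocalization, invasion, positivity, integrated density,
# fold changes.

test_that("a rasterized disc has form factor and elongation near 1", {
  disc <- draw_ellipse_mask(c(128, 128), c(64, 64), 50, 50)
  m <- shape_metrics(label_objects(disc))
  expect_equal(m$form_factor, 1, tolerance = 0.05)
  expect_equal(m$elongation_index, 1, tolerance = 0.05)
  expect_equal(m$area_um2, pi * 50^2, tolerance = 0.01 * pi * 50^2)
  expect_false(m$touches_border)
})

test_that("a 2:1 ellipse has elongation index near 2 at any angle", {
  for (ang in c(0, 30, 90)) {
    ell <- draw_ellipse_mask(c(256, 256), c(128, 128), 100, 50,
                             angle_deg = ang)
    m <- shape_metrics(label_objects(ell))
    expect_equal(m$elongation_index, 2, tolerance = 0.05)
    expect_equal(m$major_axis_um, 200, tolerance = 0.05 * 200)
  }
})

test_that("morphology is invariant under translation and 90-degree
           rotation", {
  ell <- draw_ellipse_mask(c(200, 200), c(70, 80), 45, 25, angle_deg = 15)
  shifted <- matrix(FALSE, 200, 200)
  shifted[41:200, 31:200] <- ell[1:160, 1:170]
  m1 <- shape_metrics(label_objects(ell))
  m2 <- shape_metrics(label_objects(shifted))
  m3 <- shape_metrics(label_objects(t(ell)[200:1, ]))  # 90-degree rotation
  for (col in c("area_um2", "perimeter_um", "elongation_index",
                "form_factor")) {
    expect_equal(m2[[col]], m1[[col]], tolerance = 1e-8)
    expect_equal(m3[[col]], m1[[col]], tolerance = 0.02)
  }
})

test_that("tiny and border-touching objects are flagged, not fatal", {
  lab <- matrix(0L, 32, 32)
  lab[5, 5] <- 1L          # single pixel
  lab[1:6, 20:26] <- 2L    # touches the border
  m <- shape_metrics(lab)
  expect_true(m$degenerate[m$label == 1])
  expect_true(is.na(m$elongation_index[m$label == 1]))
  expect_true(m$touches_border[m$label == 2])
  expect_false(m$degenerate[m$label == 2])
  expect_error(shape_metrics(matrix(0L, 8, 8)),
               class = "ecmquant_invalid_input")
})

test_that("colocalization equals exact integer pixel arithmetic", {
  mp <- generate_mask_pair(mask_pair_spec(c(48, 48), 100, 50, 25, seed = 3))
  res <- colocalize(mp$mask_a, mp$mask_b)
  expect_identical(res$overlap_pixel_count, overlap_loop(mp$mask_a,
                                                         mp$mask_b))
  expect_equal(res$fraction_a_in_b, 0.25)
  expect_equal(res$fraction_b_in_a, 0.5)
  # randomized masks against the brute-force loop
  for (s in 1:3) {
    mp2 <- generate_mask_pair(mask_pair_spec(c(20, 20), 60, 45, 17,
                                             seed = s))
    r2 <- colocalize(mp2$mask_a, mp2$mask_b)
    expect_identical(r2$overlap_pixel_count,
                     overlap_loop(mp2$mask_a, mp2$mask_b))
  }
})

test_that("identical, disjoint, and empty channels behave as defined", {
  m <- draw_ellipse_mask(c(32, 32), c(16, 16), 8, 5)
  same <- colocalize(m, m)
  expect_equal(same$fraction_a_in_b, 1)
  expect_equal(same$fraction_b_in_a, 1)
  other <- draw_ellipse_mask(c(32, 32), c(8, 26), 4, 3)
  dj <- colocalize(m, other & !m)
  expect_equal(dj$fraction_a_in_b, 0)
  none <- colocalize(m, matrix(FALSE, 32, 32))
  expect_true(none$undefined_b)
  expect_true(is.na(none$fraction_b_in_a))
  expect_error(colocalize(m, matrix(FALSE, 16, 16)),
               class = "ecmquant_shape_mismatch")
})

test_that("invasion index is the invading/migrating ratio", {
  expect_equal(invasion_index(25, 100)$invasion_index, 0.25)
  expect_equal(invasion_index(0, 50)$invasion_index, 0)
  expect_equal(invasion_index(80, 80)$invasion_index, 1)
  expect_error(invasion_index(10, 0), class = "ecmquant_undefined_index")
})

test_that("marker-positive fraction matches a constructed field", {
  nuclei <- matrix(0L, 60, 100)
  for (i in 1:10) {
    r <- 6 * (i - 1) + 2
    nuclei[r:(r + 3), 10:15] <- i
  }
  marker <- matrix(0, 60, 100)
  for (i in c(2, 5, 9)) marker[nuclei == i] <- 10
  res <- positive_fraction(nuclei, marker, threshold_mode = "fixed",
                           threshold = 5)
  expect_equal(res$fraction, 0.3)
  expect_identical(sort(res$calls$label[res$calls$positive]), c(2L, 5L, 9L))
  # zero marker with a positive threshold
  zero <- positive_fraction(nuclei, matrix(0, 60, 100),
                            threshold_mode = "fixed", threshold = 1)
  expect_equal(zero$fraction, 0)
  # monotone non-increasing in the threshold
  fr <- sapply(c(-1, 5, 11), function(th)
    positive_fraction(nuclei, marker, "fixed", threshold = th)$fraction)
  expect_true(all(diff(fr) <= 0))
  # Otsu over identical means is degenerate but not fatal
  expect_warning(
    deg <- positive_fraction(nuclei, matrix(1, 60, 100), "otsu"),
    "degenerate")
  expect_true(deg$degenerate)
  expect_error(positive_fraction(matrix(0L, 4, 4), matrix(0, 4, 4)),
               class = "ecmquant_invalid_input")
})

test_that("raw integrated density is a plain unnormalized sum", {
  img <- matrix(2, 10, 10)
  expect_equal(raw_integrated_density(img), 200)
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(64), 8, 8)
  expect_equal(raw_integrated_density(a + b),
               raw_integrated_density(a) + raw_integrated_density(b))
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  expect_equal(raw_integrated_density(img, half),
               raw_integrated_density(img) / 2)
  expect_error(raw_integrated_density(img, matrix(FALSE, 10, 10)),
               class = "ecmquant_empty_mask")
})

test_that("fold-change filter keeps >= 1.5-fold analytes, sorted", {
  case <- c(gmcsf = 9, ccl2 = 6, il6 = 3, tnfa = 2, weird = 1)
  control <- c(gmcsf = 1, ccl2 = 2, il6 = 2, tnfa = 2, weird = 0,
               unshared = 5)
  out <- fold_change_table(case, control)
  expect_equal(out$analyte, c("gmcsf", "ccl2", "il6"))
  expect_equal(out$fold, c(9, 3, 1.5))  # boundary 1.5 retained (inclusive)
  expect_identical(attr(out, "flagged"), "weird")
  # case == control -> fold 1, filtered out
  expect_equal(nrow(fold_change_table(c(a = 2), c(a = 2))), 0)
  # empty key intersection -> empty table
  expect_equal(nrow(fold_change_table(c(a = 2), c(b = 1))), 0)
})
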