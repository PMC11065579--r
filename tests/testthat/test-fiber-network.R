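# Segmentation, skeleton tracing, and architecture descriptors.

test_that("a constant image yields an empty mask with a warning", {
  img <- micrograph(matrix(0.5, 64, 64), 0.1)
  expect_warning(mask <- segment_fibers(img), "Constant")
  expect_false(any(mask))
  net <- skeletonize_network(mask, pixel_size_um = 0.1)
  d <- compute_descriptors(net)
  expect_equal(d$covered_area_ratio, 0)
  expect_equal(d$porosity, 1)
  expect_true(d$degenerate)
})

test_that("segmentation recovers the painted mask at moderate noise", {
  # peak amplitude 1, noise sd 0.2 (SNR 5)
  sim <- generate_fiber_image(fiber_image_spec(n_fibers = 30, noise_sd = 0.2,
                                               seed = 11))
  mask <- segment_fibers(sim$image)
  expect_gte(jaccard(mask, sim$truth_mask), 0.7)
})

test_that("segmentation is invariant to intensity polarity and affine maps", {
  sim <- generate_fiber_image(fiber_image_spec(n_fibers = 20, seed = 3))
  base <- segment_fibers(sim$image)
  flipped <- micrograph(max(sim$image) - unclass(sim$image), 0.1)
  expect_identical(unclass(segment_fibers(flipped, invert = TRUE))[, ],
                   unclass(base)[, ])
  scaled <- micrograph(7.3 * unclass(sim$image) - 2.5, 0.1)
  expect_identical(unclass(segment_fibers(scaled))[, ], unclass(base)[, ])
})

test_that("a single straight stroke traces to one segment at its angle", {
  for (ang in c(0, 30, 75, 120)) {
    net <- skeletonize_network(paint_stroke(ang), pixel_size_um = 0.1)
    expect_equal(nrow(net$segments), 1)
    expect_equal(sum(net$nodes$n_branches >= 3), 0)
    d_ang <- abs(net$segments$orientation_deg - ang)
    expect_lte(min(d_ang, 180 - d_ang), 2)
  }
})

test_that("two crossing strokes give one intersection and four branches", {
  mask <- paint_stroke(20) | paint_stroke(110)
  net <- skeletonize_network(mask, pixel_size_um = 0.1)
  expect_equal(estimate_intersections(net), 1)
  expect_equal(nrow(net$segments), 4)
  d <- compute_descriptors(net)
  expect_equal(d$n_nodes, 1)
})

test_that("an empty mask produces an empty network", {
  net <- skeletonize_network(matrix(FALSE, 32, 32), pixel_size_um = 0.1)
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$segments), 0)
  expect_false(any(net$skeleton))
})

test_that("orientation index hits its aligned and isotropic endpoints", {
  # all segments parallel -> 100%
  par_mask <- paint_stroke(40, h = 256, w = 256, center = c(80, 80)) |
    paint_stroke(40, h = 256, w = 256, center = c(150, 150)) |
    paint_stroke(40, h = 256, w = 256, center = c(210, 60))
  d <- compute_descriptors(skeletonize_network(par_mask, pixel_size_um = 0.1))
  expect_gte(d$orientation_index_pct, 99)
  # uniform angles: Monte-Carlo of the index formula tends to 0
  set.seed(1)
  oi <- 100 * ecmquant:::axial_resultant(runif(1e4, 0, 180))
  expect_lte(oi, 5)
})

test_that("covered area and porosity are exact complements", {
  sim <- generate_fiber_image(fiber_image_spec(n_fibers = 40, seed = 8))
  d <- compute_descriptors(skeletonize_network(sim$truth_mask,
                                               pixel_size_um = 0.1))
  expect_equal(d$covered_area_ratio + d$porosity, 1)
  expect_equal(d$covered_area_ratio, sum(sim$truth_mask) / 512^2)
})

test_that("descriptors scale correctly with the pixel size", {
  sim <- generate_fiber_image(fiber_image_spec(n_fibers = 80,
                                               fiber_length_um = 20,
                                               seed = 21))
  d1 <- compute_descriptors(skeletonize_network(sim$truth_mask,
                                                pixel_size_um = 0.1))
  d2 <- compute_descriptors(skeletonize_network(sim$truth_mask,
                                                pixel_size_um = 0.2))
  expect_equal(d2$node_density_per_mm2 / d1$node_density_per_mm2, 0.25)
  expect_equal(d2$mean_pore_size_um2 / d1$mean_pore_size_um2, 4)
  expect_equal(d2$mean_fiber_diameter_um / d1$mean_fiber_diameter_um, 2)
  expect_equal(d2$covered_area_ratio, d1$covered_area_ratio)
})

test_that("recovered mean diameter tracks the generator ground truth", {
  rel_err <- sapply(1:3, function(s) {
    sim <- generate_fiber_image(fiber_image_spec(
      n_fibers = 40, fiber_width_um = 0.5, noise_sd = 0.05, seed = s))
    d <- analyze_fibers(sim$image)
    abs(d$mean_fiber_diameter_um - mean(sim$fibers$width_um)) /
      mean(sim$fibers$width_um)
  })
  expect_lte(median(rel_err), 0.15)
})

test_that("orientation index rises with the generator concentration", {
  med_oi <- sapply(c(0, 2, 20), function(kap) {
    median(sapply(1:3, function(s) {
      sim <- generate_fiber_image(fiber_image_spec(
        n_fibers = 60, orientation_kappa = kap, orientation_mode_deg = 30,
        seed = s))
      analyze_fibers(sim$image)$orientation_index_pct
    }))
  })
  expect_true(all(diff(med_oi) >= 0))
})

test_that("pores are interior background components in physical units", {
  # a closed square ring encloses one pore of known size
  m <- matrix(FALSE, 64, 64)
  m[20:44, 20:44] <- TRUE
  m[24:40, 24:40] <- FALSE
  net <- skeletonize_network(m, pixel_size_um = 0.5)
  d <- compute_descriptors(net)
  expect_equal(d$n_pores, 1)
  expect_equal(d$mean_pore_size_um2, 17^2 * 0.25)
  expect_equal(d$mean_pore_size_mm2, 17^2 * 0.25 * 1e-6)
})

test_that("optional graph pruning modes run and only remove segments", {
  sim <- generate_fiber_image(fiber_image_spec(n_fibers = 30, seed = 4))
  mask <- segment_fibers(sim$image)
  full <- skeletonize_network(mask, pixel_size_um = 0.1)
  pruned <- skeletonize_network(mask, pixel_size_um = 0.1, prune = "length")
  gabriel <- skeletonize_network(mask, pixel_size_um = 0.1,
                                 prune = "delaunay")
  expect_lte(nrow(pruned$segments), nrow(full$segments))
  expect_lte(nrow(gabriel$segments), nrow(pruned$segments))
})

test_that("micrograph constructor validates input", {
  expect_error(micrograph(matrix(NA_real_, 4, 4), 0.1),
               class = "ecmquant_invalid_input")
  expect_error(micrograph(matrix(0, 4, 4), 0), class = "ecmquant_invalid_spec")
  expect_error(skeletonize_network(matrix(FALSE, 8, 8)),
               class = "ecmquant_missing_pixel_size")
})
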