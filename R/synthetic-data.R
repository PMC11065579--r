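#' Attach a physical pixel size to a grayscale image
#'
#' A micrograph is an ordinary numeric matrix (rows = image rows, origin at
#' the top-left, 0-based pixel coordinates) carrying the physical sampling
#' step in micrometres per pixel.  All architecture descriptors that report
#' physical units read the pixel size from this attribute.
#'
#' @param pixels Numeric matrix of intensities (any finite range).
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @return The matrix with class `ecm_micrograph` and a `pixel_size_um`
#'   attribute.
#' @export
micrograph <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || !all(is.finite(pixels)))
    stop_ecm("`pixels` must be a finite numeric matrix.", "invalid_input")
  check_number(pixel_size_um, "pixel_size_um", lower = 1e-12)
  structure(pixels, pixel_size_um = pixel_size_um,
            class = c("ecm_micrograph", "matrix", "array"))
}

#' @export
print.ecm_micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %.4g um/px, intensity [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

pixel_size_of <- function(img, pixel_size_um = NULL) {
  ps <- pixel_size_um %||% attr(img, "pixel_size_um")
  if (is.null(ps))
    stop_ecm("A pixel size in um/px is required for physical units; supply `pixel_size_um`.",
             "missing_pixel_size")
  check_number(ps, "pixel_size_um", lower = 1e-12)
  ps
}

#' Specification of a synthetic fibrous micrograph
#'
#' Defines a seeded scene of straight fiber strokes with Gaussian
#' cross-sectional intensity profiles on a dark background, emulating an SEM
#' field of a fibrous scaffold.  Fiber directions are drawn from an axial
#' von Mises distribution: `orientation_kappa = 0` gives an isotropic
#' network, large values an aligned one.  The rendered ground-truth mask is
#' the at-least-half-maximum support of each stroke, so the *true* fiber
#' diameter equals the profile's full width at half maximum.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Sampling step, um/px.
#' @param n_fibers Number of strokes (>= 0).
#' @param fiber_width_um Mean true fiber diameter (FWHM), um.
#' @param width_cv Coefficient of variation of per-fiber width.
#' @param fiber_length_um Stroke length, um.
#' @param orientation_mode_deg Preferred axial direction in [0, 180).
#' @param orientation_kappa Concentration (>= 0; 0 = isotropic, `Inf` =
#'   perfectly parallel).
#' @param noise_sd Additive Gaussian noise standard deviation (fiber peak
#'   amplitude is 1).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A list of class `fiber_image_spec`.
#' @export
fiber_image_spec <- function(width_px = 512L, height_px = 512L,
                             pixel_size_um = 0.1, n_fibers = 30L,
                             fiber_width_um = 0.5, width_cv = 0.1,
                             fiber_length_um = 6,
                             orientation_mode_deg = 0,
                             orientation_kappa = 0,
                             noise_sd = 0.05, seed = 1L) {
  check_number(width_px, "width_px", lower = 8, integerish = TRUE)
  check_number(height_px, "height_px", lower = 8, integerish = TRUE)
  check_number(pixel_size_um, "pixel_size_um", lower = 1e-12)
  check_number(n_fibers, "n_fibers", lower = 0, integerish = TRUE)
  check_number(fiber_width_um, "fiber_width_um", lower = 1e-12)
  check_number(width_cv, "width_cv", lower = 0)
  check_number(fiber_length_um, "fiber_length_um", lower = 1e-12)
  check_number(orientation_mode_deg, "orientation_mode_deg", lower = 0,
               upper = 180 - 1e-9)
  if (!is.numeric(orientation_kappa) || length(orientation_kappa) != 1L ||
      is.na(orientation_kappa) || orientation_kappa < 0)
    stop_ecm("`orientation_kappa` must be a number >= 0 (Inf = parallel).",
             "invalid_spec")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed", integerish = TRUE)
  structure(as.list(environment()), class = "fiber_image_spec")
}

#' Render a synthetic fibrous micrograph with ground truth
#'
#' Paints the scene declared by a [fiber_image_spec()]: each fiber is a
#' straight stroke with a Gaussian intensity cross-section (peak 1, FWHM =
#' its drawn width), composited by maximum, plus i.i.d. Gaussian pixel
#' noise.  Alongside the image the exact painted mask (pixels within half a
#' width of a stroke axis) and the per-fiber truth table are returned.
#'
#' @param spec A [fiber_image_spec()].
#' @return A list of class `fiber_image` with elements `image` (an
#'   [micrograph()]), `truth_mask` (logical matrix), and `fibers` (tibble
#'   with per-fiber `width_um`, `orientation_deg`, `length_um` and stroke
#'   endpoints `x0, y0, x1, y1` in pixel coordinates).
#' @export
generate_fiber_image <- function(spec) {
  if (!inherits(spec, "fiber_image_spec"))
    stop_ecm("`spec` must be a fiber_image_spec.", "invalid_spec")
  withr::with_seed(spec$seed, {
    h <- spec$height_px; w <- spec$width_px
    img <- matrix(0, h, w)
    truth <- matrix(FALSE, h, w)
    n <- spec$n_fibers
    theta <- sample_axial_deg(n, spec$orientation_mode_deg,
                              spec$orientation_kappa)
    wid_um <- spec$fiber_width_um *
      pmax(0.2, 1 + spec$width_cv * rnorm(n))
    cx <- runif(n, 0, w)
    cy <- runif(n, 0, h)
    len_px <- spec$fiber_length_um / spec$pixel_size_um
    wid_px <- wid_um / spec$pixel_size_um
    th <- theta * pi / 180
    # image y grows downward; mathematical angle convention
    x0 <- cx - len_px / 2 * cos(th); x1 <- cx + len_px / 2 * cos(th)
    y0 <- cy + len_px / 2 * sin(th); y1 <- cy - len_px / 2 * sin(th)
    for (i in seq_len(n)) {
      sigma <- wid_px[i] / (2 * sqrt(2 * log(2)))
      pad <- wid_px[i] / 2 + 3 * sigma + 2
      rows <- max(1, floor(min(y0[i], y1[i]) - pad)):
              min(h, ceiling(max(y0[i], y1[i]) + pad))
      cols <- max(1, floor(min(x0[i], x1[i]) - pad)):
              min(w, ceiling(max(x0[i], x1[i]) + pad))
      if (length(rows) == 0L || length(cols) == 0L) next
      px <- rep(cols - 0.5, each = length(rows))
      py <- rep(rows - 0.5, times = length(cols))
      ax <- x0[i]; ay <- y0[i]
      bx <- x1[i] - ax; by <- y1[i] - ay
      t <- pmin(1, pmax(0, ((px - ax) * bx + (py - ay) * by) /
                             (bx^2 + by^2)))
      d <- sqrt((px - (ax + t * bx))^2 + (py - (ay + t * by))^2)
      val <- exp(-d^2 / (2 * sigma^2))
      img[rows, cols] <- pmax(img[rows, cols],
                              matrix(val, length(rows), length(cols)))
      truth[rows, cols] <- truth[rows, cols] |
        matrix(d <= wid_px[i] / 2, length(rows), length(cols))
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(h * w, sd = spec$noise_sd), h, w)
    fibers <- tibble(
      fiber = seq_len(n),
      width_um = wid_um[seq_len(n)],
      orientation_deg = theta,
      length_um = rep(spec$fiber_length_um, n),
      x0 = x0, y0 = y0, x1 = x1, y1 = y1
    )
    structure(list(image = micrograph(img, spec$pixel_size_um),
                   truth_mask = truth, fibers = fibers, spec = spec),
              class = "fiber_image")
  })
}

#' Count pairwise stroke crossings in a fiber truth table
#'
#' Brute-force proper-intersection test over all fiber pairs of a
#' [generate_fiber_image()] truth table, giving the ground-truth number of
#' network intersection points against which detected node counts are
#' benchmarked.  Crossings are counted per intersecting pair (collinear
#' overlaps and shared endpoints are not proper crossings and are ignored).
#'
#' @param fibers Tibble with stroke endpoints `x0, y0, x1, y1`.
#' @param within Optional image size `c(width_px, height_px)`; when given,
#'   only crossings inside the image are counted.
#' @return Integer crossing count.
#' @export
count_segment_crossings <- function(fibers, within = NULL) {
  n <- nrow(fibers)
  if (n < 2L) return(0L)
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  count <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- fibers[i, ]; q <- fibers[j, ]
    d1 <- cross2(q$x0, q$y0, q$x1, q$y1, p$x0, p$y0)
    d2 <- cross2(q$x0, q$y0, q$x1, q$y1, p$x1, p$y1)
    d3 <- cross2(p$x0, p$y0, p$x1, p$y1, q$x0, q$y0)
    d4 <- cross2(p$x0, p$y0, p$x1, p$y1, q$x1, q$y1)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
      if (!is.null(within)) {
        t <- d1 / (d1 - d2)
        ix <- p$x0 + t * (p$x1 - p$x0); iy <- p$y0 + t * (p$y1 - p$y0)
        if (ix < 0 || ix > within[1] || iy < 0 || iy > within[2]) next
      }
      count <- count + 1L
    }
  }
  count
}

#' Specification of a synthetic Raman spectrum
#'
#' A spectrum is the exact sum of Gaussian peaks, a smooth polynomial
#' fluorescence baseline, and i.i.d. Gaussian noise on a fixed wavenumber
#' grid.  Defaults place peaks at the amide III (1265), lipid (1300) and
#' amide I (1650) positions used for tissue collagen/lipid ratios; the
#' default grid extends through the peak-free 1800-2000 1/cm region, which
#' anchors polynomial background estimation the way real fingerprint scans
#' do.
#'
#' @param wavenumber_grid Strictly ascending wavenumbers, 1/cm.
#' @param peaks Data frame with columns `center`, `height`, `fwhm`.
#' @param baseline_coeffs Ascending-order polynomial coefficients of the
#'   baseline, evaluated in the scaled coordinate u = (wn - min)/(max - min).
#' @param noise_sd Noise standard deviation, a.u.
#' @param seed Integer seed.
#' @return A list of class `spectrum_spec`.
#' @export
spectrum_spec <- function(wavenumber_grid = seq(600, 2000, by = 2),
                          peaks = default_raman_peaks(),
                          baseline_coeffs = c(0.6, 1.2, -1.0),
                          noise_sd = 0.01, seed = 1L) {
  if (!is.numeric(wavenumber_grid) || length(wavenumber_grid) < 32L)
    stop_ecm("`wavenumber_grid` must be numeric with at least 32 points.",
             "invalid_spec")
  if (any(diff(wavenumber_grid) <= 0))
    stop_ecm("`wavenumber_grid` must be strictly ascending.", "invalid_spec")
  peaks <- as_tibble(peaks)
  if (nrow(peaks) > 0) {
    if (!all(c("center", "height", "fwhm") %in% names(peaks)))
      stop_ecm("`peaks` needs columns center, height, fwhm.", "invalid_spec")
    rng <- range(wavenumber_grid)
    if (any(peaks$center < rng[1] | peaks$center > rng[2]))
      stop_ecm("All peak centers must lie inside the wavenumber grid.",
               "invalid_spec")
    if (any(peaks$fwhm <= 0))
      stop_ecm("Peak fwhm values must be > 0.", "invalid_spec")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed", integerish = TRUE)
  structure(list(wavenumber_grid = wavenumber_grid, peaks = peaks,
                 baseline_coeffs = baseline_coeffs, noise_sd = noise_sd,
                 seed = seed),
            class = "spectrum_spec")
}

#' Default tissue peak set for synthetic spectra
#'
#' Amide III (1265), lipid CH2 twist (1300) and amide I (1650) bands.
#' @return Tibble with columns `center`, `height`, `fwhm` (1/cm, a.u., 1/cm).
#' @export
default_raman_peaks <- function() {
  tibble(center = c(1265, 1300, 1650),
         height = c(0.5, 0.45, 0.9),
         fwhm = c(22, 18, 40))
}

#' Generate a synthetic Raman spectrum with ground-truth components
#'
#' @param spec A [spectrum_spec()].
#' @return List of class `spectrum_sim`: `spectrum` (tibble `wavenumber_cm1`,
#'   `intensity_au`), and the exact components `peak_component`,
#'   `baseline_au`, `noise_au` (numeric vectors on the same grid) which sum
#'   to the emitted intensities.
#' @export
generate_spectrum <- function(spec) {
  if (!inherits(spec, "spectrum_spec"))
    stop_ecm("`spec` must be a spectrum_spec.", "invalid_spec")
  withr::with_seed(spec$seed, {
    wn <- spec$wavenumber_grid
    u <- (wn - min(wn)) / (max(wn) - min(wn))
    baseline <- rep(0, length(wn))
    for (k in seq_along(spec$baseline_coeffs))
      baseline <- baseline + spec$baseline_coeffs[k] * u^(k - 1)
    peak <- rep(0, length(wn))
    if (nrow(spec$peaks) > 0)
      for (i in seq_len(nrow(spec$peaks)))
        peak <- peak + spec$peaks$height[i] *
          exp(-4 * log(2) * (wn - spec$peaks$center[i])^2 /
                spec$peaks$fwhm[i]^2)
    noise <- if (spec$noise_sd > 0) rnorm(length(wn), sd = spec$noise_sd)
             else rep(0, length(wn))
    structure(list(
      spectrum = tibble(wavenumber_cm1 = wn,
                        intensity_au = peak + baseline + noise),
      peak_component = peak, baseline_au = baseline, noise_au = noise,
      spec = spec), class = "spectrum_sim")
  })
}

#' Hertz force for a rigid spherical indenter
#'
#' F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2) for indentation depth
#' delta >= 0 (0 before contact).  Inputs in instrument units (nm, um, Pa),
#' output in nN.
#'
#' @param delta_nm Indentation depth, nm (values < 0 give 0 force).
#' @param E_pa Young's modulus, Pa.
#' @param tip_radius_um Indenter radius, um.
#' @param poisson_ratio Poisson's ratio in [0, 0.5].
#' @return Force in nN.
#' @export
hertz_force <- function(delta_nm, E_pa, tip_radius_um = 5,
                        poisson_ratio = 0.5) {
  delta_m <- pmax(delta_nm, 0) * 1e-9
  f_n <- (4 / 3) * (E_pa / (1 - poisson_ratio^2)) *
    sqrt(tip_radius_um * 1e-6) * delta_m^1.5
  f_n * 1e9
}

#' Specification of a synthetic AFM force-distance curve
#'
#' @param E_pa True Young's modulus, Pa.
#' @param tip_radius_um Spherical tip radius, um (default 5, a 10-um-diameter
#'   bead).
#' @param poisson_ratio Poisson's ratio in [0, 0.5] (0.5 = incompressible).
#' @param contact_point_nm Displacement at which the tip meets the sample.
#' @param max_indentation_nm Maximum indentation depth beyond contact.
#' @param pre_contact_nm Length of the pre-contact (baseline) ramp.
#' @param baseline_nN Constant force offset.
#' @param n_points Samples along the ramp (>= 20).
#' @param noise_sd_nN Additive force noise, nN.
#' @param seed Integer seed.
#' @return A list of class `force_curve_spec`.
#' @export
force_curve_spec <- function(E_pa = 1000, tip_radius_um = 5,
                             poisson_ratio = 0.5, contact_point_nm = 200,
                             max_indentation_nm = 500, pre_contact_nm = 150,
                             baseline_nN = 0, n_points = 200L,
                             noise_sd_nN = 0, seed = 1L) {
  check_number(E_pa, "E_pa", lower = 1e-12)
  check_number(tip_radius_um, "tip_radius_um", lower = 1e-12)
  check_number(poisson_ratio, "poisson_ratio", lower = 0, upper = 0.5)
  check_number(contact_point_nm, "contact_point_nm")
  check_number(max_indentation_nm, "max_indentation_nm", lower = 0)
  check_number(pre_contact_nm, "pre_contact_nm", lower = 1e-12)
  check_number(baseline_nN, "baseline_nN")
  check_number(n_points, "n_points", lower = 20, integerish = TRUE)
  check_number(noise_sd_nN, "noise_sd_nN", lower = 0)
  check_number(seed, "seed", integerish = TRUE)
  structure(as.list(environment()), class = "force_curve_spec")
}

#' Generate a synthetic force-distance curve
#'
#' Beyond the contact point the noiseless force follows the Hertz law
#' exactly; before contact it is the constant baseline.  Additive Gaussian
#' noise is applied to the whole ramp.
#'
#' @param spec A [force_curve_spec()].
#' @return A `force_curve` tibble with columns `displacement_nm`, `force_nN`
#'   and attributes `tip_radius_um`, `poisson_ratio`, `E_true_pa`,
#'   `contact_point_nm`.
#' @export
generate_force_curve <- function(spec) {
  if (!inherits(spec, "force_curve_spec"))
    stop_ecm("`spec` must be a force_curve_spec.", "invalid_spec")
  withr::with_seed(spec$seed, {
    z <- seq(spec$contact_point_nm - spec$pre_contact_nm,
             spec$contact_point_nm + spec$max_indentation_nm,
             length.out = spec$n_points)
    f <- spec$baseline_nN +
      hertz_force(z - spec$contact_point_nm, spec$E_pa,
                  spec$tip_radius_um, spec$poisson_ratio)
    if (spec$noise_sd_nN > 0)
      f <- f + rnorm(length(z), sd = spec$noise_sd_nN)
    out <- tibble(displacement_nm = z, force_nN = f)
    attr(out, "tip_radius_um") <- spec$tip_radius_um
    attr(out, "poisson_ratio") <- spec$poisson_ratio
    attr(out, "E_true_pa") <- spec$E_pa
    attr(out, "contact_point_nm") <- spec$contact_point_nm
    class(out) <- c("force_curve", class(out))
    out
  })
}

#' Specification of a pair of binary masks with known overlap
#'
#' @param shape_px Image size `c(height, width)`.
#' @param n_pixels_a,n_pixels_b Positive-pixel counts of each mask.
#' @param n_overlap Shared positive pixels (`<= min(n_a, n_b)`; total
#'   distinct pixels must fit in the image).
#' @param seed Integer seed.
#' @return A list of class `mask_pair_spec`.
#' @export
mask_pair_spec <- function(shape_px = c(64L, 64L), n_pixels_a, n_pixels_b,
                           n_overlap, seed = 1L) {
  if (length(shape_px) != 2L) stop_ecm("`shape_px` must be (h, w).",
                                       "invalid_spec")
  check_number(shape_px[1], "shape_px[1]", lower = 1, integerish = TRUE)
  check_number(shape_px[2], "shape_px[2]", lower = 1, integerish = TRUE)
  check_number(n_pixels_a, "n_pixels_a", lower = 0, integerish = TRUE)
  check_number(n_pixels_b, "n_pixels_b", lower = 0, integerish = TRUE)
  check_number(n_overlap, "n_overlap", lower = 0, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  if (n_overlap > min(n_pixels_a, n_pixels_b))
    stop_ecm("`n_overlap` cannot exceed min(n_pixels_a, n_pixels_b).",
             "invalid_spec")
  if (n_pixels_a + n_pixels_b - n_overlap > prod(shape_px))
    stop_ecm("Requested pixel counts do not fit in `shape_px`.",
             "invalid_spec")
  structure(list(shape_px = as.integer(shape_px),
                 n_pixels_a = as.integer(n_pixels_a),
                 n_pixels_b = as.integer(n_pixels_b),
                 n_overlap = as.integer(n_overlap), seed = as.integer(seed)),
            class = "mask_pair_spec")
}

#' Generate two binary masks with exactly the declared overlap
#'
#' @param spec A [mask_pair_spec()].
#' @return List with logical matrices `mask_a` and `mask_b`.
#' @export
generate_mask_pair <- function(spec) {
  if (!inherits(spec, "mask_pair_spec"))
    stop_ecm("`spec` must be a mask_pair_spec.", "invalid_spec")
  withr::with_seed(spec$seed, {
    npx <- prod(spec$shape_px)
    total <- spec$n_pixels_a + spec$n_pixels_b - spec$n_overlap
    idx <- sample.int(npx, total)
    shared <- idx[seq_len(spec$n_overlap)]
    only_a <- idx[seq_len(spec$n_pixels_a - spec$n_overlap) + spec$n_overlap]
    only_b <- setdiff(idx, c(shared, only_a))
    a <- matrix(FALSE, spec$shape_px[1], spec$shape_px[2])
    b <- a
    a[c(shared, only_a)] <- TRUE
    b[c(shared, only_b)] <- TRUE
    list(mask_a = a, mask_b = b)
  })
}

#' Rasterize an elliptical object mask
#'
#' Convenience generator for synthetic cell masks: pixels whose centers fall
#' inside the ellipse are set.
#'
#' @param shape_px Image size `c(height, width)`.
#' @param center `c(row, col)` center in pixel coordinates (0-based,
#'   continuous); defaults to the image center.
#' @param semi_major_px,semi_minor_px Semi-axes in pixels.
#' @param angle_deg Major-axis direction, degrees from the x (column) axis.
#' @return Logical matrix.
#' @export
draw_ellipse_mask <- function(shape_px, center = shape_px / 2,
                              semi_major_px, semi_minor_px, angle_deg = 0) {
  h <- shape_px[1]; w <- shape_px[2]
  x <- rep(seq_len(w) - 0.5, each = h) - center[2]
  y <- rep(seq_len(h) - 0.5, times = w) - center[1]
  th <- angle_deg * pi / 180
  xr <- x * cos(th) - y * sin(th)   # y axis points down; axial symmetry
  yr <- x * sin(th) + y * cos(th)
  matrix((xr / semi_major_px)^2 + (yr / semi_minor_px)^2 <= 1, h, w)
}
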