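# Per-cell readouts: morphology (elongation index, form factor),
# channel colocalization, invasion index, marker positivity, raw
# integrated density, and analyte fold-change filtering.

#' Morphology metrics of labelled objects
#'
#' For each labelled object: area, corner-corrected perimeter
#' (Vossepoel-Smeulders chain-code estimator), equivalent-ellipse axes from
#' second-order moments, elongation index (major/minor), and form factor
#' (`4 pi A / P^2`; 1 for a circle).  Objects touching the image border are
#' computed but flagged; 1-px and collinear objects are flagged degenerate
#' with `NA` shape ratios, never an error.
#'
#' @param labels Integer label matrix (0 = background), e.g. from
#'   [label_objects()].
#' @param pixel_size_um Pixel size, um/px (default 1: pixel units).
#' @return Tibble with one row per object: `label`, `area_um2`,
#'   `perimeter_um`, `major_axis_um`, `minor_axis_um`, `elongation_index`,
#'   `form_factor`, `touches_border`, `degenerate`.
#' @export
shape_metrics <- function(labels, pixel_size_um = 1) {
  if (!is.matrix(labels) || !is.numeric(labels))
    stop_ecm("`labels` must be an integer label matrix.", "invalid_input")
  check_number(pixel_size_um, "pixel_size_um", lower = 1e-12)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L)
    stop_ecm("No labelled objects found.", "invalid_input")
  nr <- nrow(labels); nc <- ncol(labels)
  out <- purrr::map_dfr(ids, function(id) {
    idx <- which(labels == id)
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    area_px <- length(idx)
    touches <- any(rr == 1L | rr == nr | cc == 1L | cc == nc)
    if (area_px < 5L) {
      return(tibble(label = id, area_um2 = area_px * pixel_size_um^2,
                    perimeter_um = NA_real_, major_axis_um = NA_real_,
                    minor_axis_um = NA_real_, elongation_index = NA_real_,
                    form_factor = NA_real_, touches_border = touches,
                    degenerate = TRUE))
    }
    # second-order central moments -> equivalent ellipse (full axes)
    xm <- cc - mean(cc); ym <- rr - mean(rr)
    mu20 <- mean(xm^2) + 1 / 12; mu02 <- mean(ym^2) + 1 / 12
    mu11 <- mean(xm * ym)
    common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    l1 <- (mu20 + mu02 + common) / 2
    l2 <- (mu20 + mu02 - common) / 2
    major <- 4 * sqrt(pmax(l1, 0))
    minor <- 4 * sqrt(pmax(l2, 0))
    per_px <- object_perimeter_px(labels == id)
    degenerate <- minor <= 0 || !is.finite(per_px) || per_px <= 0
    tibble(label = id,
           area_um2 = area_px * pixel_size_um^2,
           perimeter_um = per_px * pixel_size_um,
           major_axis_um = major * pixel_size_um,
           minor_axis_um = minor * pixel_size_um,
           elongation_index = if (degenerate) NA_real_ else major / minor,
           form_factor = if (degenerate) NA_real_ else
             4 * pi * area_px / per_px^2,
           touches_border = touches,
           degenerate = degenerate)
  })
  out
}

# Corner-corrected perimeter from the 8-connected boundary chain:
# P ~ 0.980 * (axial steps) + 1.406 * (diagonal steps) - 0.091 * (corners)
# (Vossepoel & Smeulders weights).
object_perimeter_px <- function(mask) {
  ct <- tryCatch(EBImage::ocontour(EBImage::bwlabel(mask)),
                 error = function(e) NULL)
  if (is.null(ct) || length(ct) == 0L) return(NA_real_)
  total <- 0
  for (poly in ct) {
    if (nrow(poly) < 2L) next
    d <- rbind(diff(poly), poly[1, ] - poly[nrow(poly), ])
    step <- abs(d[, 1]) + abs(d[, 2])
    n_ax <- sum(step == 1)
    n_di <- sum(step == 2)
    dirs <- atan2(d[, 2], d[, 1])
    n_corner <- sum(abs(diff(c(dirs, dirs[1]))) > 1e-9)
    total <- total + 0.980 * n_ax + 1.406 * n_di - 0.091 * n_corner
  }
  total
}

#' Label connected objects in a binary mask
#'
#' Minimal segmentation helper for building fixtures: thresholds an
#' intensity image by Otsu when given one, then labels 8-connected
#' components.
#'
#' @param x Binary mask or intensity image (numeric matrix).
#' @param min_px Drop objects smaller than this.
#' @return Integer label matrix.
#' @export
label_objects <- function(x, min_px = 0L) {
  if (!is_binary_mask(x)) {
    rng <- range(x)
    if (diff(rng) == 0)
      stop_ecm("Constant image cannot be thresholded.", "degenerate_input")
    xn <- (x - rng[1]) / diff(rng)
    x <- xn > EBImage::otsu(xn, range = c(0, 1))
  }
  lab <- cpp_label8(as_mask(x))
  if (min_px > 0L && attr(lab, "n_labels") > 0L) {
    sizes <- tabulate(lab[lab > 0], attr(lab, "n_labels"))
    drop <- which(sizes < min_px)
    lab[lab %in% drop] <- 0L
    old <- sort(unique(lab[lab > 0]))
    lab[lab > 0] <- match(lab[lab > 0], old)
  }
  matrix(as.integer(lab), nrow(lab), ncol(lab))
}

#' Pixel-overlap colocalization of two channels
#'
#' The per-fluorophore colocalized fraction: the number of pixels positive
#' in both channels divided by the positive count of each channel.
#'
#' @param mask_a,mask_b Binary masks of equal shape.
#' @return One-row tibble: `count_a`, `count_b`, `overlap_pixel_count`,
#'   `fraction_a_in_b`, `fraction_b_in_a`, and `undefined_a`/`undefined_b`
#'   flags (a channel with zero positive pixels has an `NA` fraction).
#' @export
colocalize <- function(mask_a, mask_b) {
  mask_a <- as_mask(mask_a, "mask_a")
  mask_b <- as_mask(mask_b, "mask_b")
  if (!all(dim(mask_a) == dim(mask_b)))
    stop_ecm("Masks must have the same shape.", "shape_mismatch")
  ca <- sum(mask_a); cb <- sum(mask_b)
  ov <- sum(mask_a & mask_b)
  tibble(count_a = ca, count_b = cb, overlap_pixel_count = ov,
         fraction_a_in_b = if (ca > 0) ov / ca else NA_real_,
         fraction_b_in_a = if (cb > 0) ov / cb else NA_real_,
         undefined_a = ca == 0, undefined_b = cb == 0)
}

#' Transwell invasion index
#'
#' The number of cells that invaded through the matrix-coated insert
#' divided by the number that migrated through the uncoated control insert.
#'
#' @param n_invading,n_migrating Non-negative cell counts.
#' @return One-row tibble: `n_invading`, `n_migrating`, `invasion_index`.
#' @export
invasion_index <- function(n_invading, n_migrating) {
  check_number(n_invading, "n_invading", lower = 0)
  check_number(n_migrating, "n_migrating", lower = 0)
  if (n_migrating == 0)
    stop_ecm("`n_migrating` is zero: the invasion index is undefined.",
             "undefined_index")
  tibble(n_invading = n_invading, n_migrating = n_migrating,
         invasion_index = n_invading / n_migrating)
}

#' Marker-positive fraction over labelled nuclei
#'
#' Calls each object positive when its mean marker intensity exceeds a
#' threshold: Otsu over the per-object means by default, or a fixed value.
#'
#' @param nuclei Integer label matrix of nuclei.
#' @param marker Intensity image, same shape.
#' @param threshold_mode `"otsu"` or `"fixed"`.
#' @param threshold Fixed threshold (required for `"fixed"`).
#' @return A list of class `positivity_result`: `fraction`, `threshold`,
#'   `degenerate` (all object means identical in Otsu mode), and `calls`
#'   (tibble: `label`, `mean_intensity`, `positive`).
#' @export
positive_fraction <- function(nuclei, marker,
                              threshold_mode = c("otsu", "fixed"),
                              threshold = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (!is.matrix(nuclei) || !is.matrix(marker) ||
      !all(dim(nuclei) == dim(marker)))
    stop_ecm("`nuclei` and `marker` must be matrices of the same shape.",
             "shape_mismatch")
  ids <- sort(unique(nuclei[nuclei > 0]))
  if (length(ids) == 0L)
    stop_ecm("No nuclei objects in the label image.", "invalid_input")
  means <- vapply(ids, function(id) mean(marker[nuclei == id]), numeric(1))
  degenerate <- FALSE
  if (threshold_mode == "fixed") {
    if (is.null(threshold))
      stop_ecm("Fixed mode needs a `threshold`.", "invalid_parameter")
    thr <- threshold
  } else {
    thr <- otsu_vector(means)
    degenerate <- isTRUE(attr(thr, "degenerate"))
    thr <- as.numeric(thr)
    if (degenerate)
      warn("All object means identical: Otsu threshold is degenerate.")
  }
  calls <- tibble(label = ids, mean_intensity = means,
                  positive = means > thr)
  structure(list(fraction = mean(calls$positive), threshold = thr,
                 degenerate = degenerate, calls = calls),
            class = "positivity_result")
}

#' @export
print.positivity_result <- function(x, ...) {
  cat(sprintf("<positivity_result> %.1f%% positive (%d/%d), threshold %.4g\n",
              100 * x$fraction, sum(x$calls$positive), nrow(x$calls),
              x$threshold))
  invisible(x)
}

#' Raw integrated density of a field
#'
#' The plain sum of pixel intensities over the whole field or a mask; no
#' background correction or normalization.
#'
#' @param image Numeric intensity matrix.
#' @param field_mask Optional binary mask restricting the sum.
#' @return Numeric scalar.
#' @export
raw_integrated_density <- function(image, field_mask = NULL) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop_ecm("`image` must be a finite numeric matrix.", "invalid_input")
  if (is.null(field_mask)) return(sum(image))
  field_mask <- as_mask(field_mask, "field_mask")
  if (!all(dim(field_mask) == dim(image)))
    stop_ecm("`field_mask` shape must match the image.", "shape_mismatch")
  if (!any(field_mask))
    stop_ecm("`field_mask` selects no pixels.", "empty_mask")
  sum(image[field_mask])
}

#' Analyte fold-change filter
#'
#' Computes per-analyte `case / control` fold changes over the shared
#' analytes and keeps those at or above `min_fold` (the cutoff is
#' inclusive), sorted by descending fold.  Analytes whose control value is
#' not positive cannot form a ratio; they are excluded and returned in the
#' `flagged` attribute.
#'
#' @param case,control Named numeric vectors, or data frames with columns
#'   `analyte` and `value`.
#' @param min_fold Inclusive fold-change cutoff (default 1.5).
#' @return Tibble `analyte`, `case`, `control`, `fold`, sorted descending;
#'   attribute `flagged` lists analytes with non-positive controls.
#' @export
fold_change_table <- function(case, control, min_fold = 1.5) {
  check_number(min_fold, "min_fold", lower = 0)
  as_analyte_vec <- function(x, name) {
    if (is.data.frame(x)) {
      if (!all(c("analyte", "value") %in% names(x)))
        stop_ecm(sprintf("`%s` needs columns `analyte` and `value`.", name),
                 "schema")
      return(setNames(x$value, x$analyte))
    }
    if (is.null(names(x)))
      stop_ecm(sprintf("`%s` must be named.", name), "schema")
    x
  }
  case <- as_analyte_vec(case, "case")
  control <- as_analyte_vec(control, "control")
  shared <- intersect(names(case), names(control))
  bad <- shared[control[shared] <= 0]
  good <- setdiff(shared, bad)
  case_v <- unname(case[good])
  control_v <- unname(control[good])
  out <- tibble(analyte = good, case = case_v, control = control_v,
                fold = case_v / control_v) |>
    dplyr::filter(.data$fold >= min_fold) |>
    dplyr::arrange(dplyr::desc(.data$fold))
  attr(out, "flagged") <- bad
  out
}
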