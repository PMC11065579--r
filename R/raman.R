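# Raman pipeline: Savitzky-Golay smoothing -> iterative modified-polyfit
# fluorescence background subtraction -> min-max normalization -> band
# ratios and PCA.

as_spectrum <- function(spec) {
  spec <- as_tibble(spec)
  if (!all(c("wavenumber_cm1", "intensity_au") %in% names(spec)))
    stop_ecm("A spectrum needs columns `wavenumber_cm1` and `intensity_au`.",
             "schema")
  if (nrow(spec) < 32L)
    stop_ecm("A spectrum needs at least 32 points.", "invalid_input")
  if (any(diff(spec$wavenumber_cm1) <= 0))
    stop_ecm("`wavenumber_cm1` must be strictly ascending.", "invalid_input")
  if (!all(is.finite(spec$intensity_au)))
    stop_ecm("Spectrum intensities must be finite.", "invalid_input")
  spec
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Local least-squares polynomial smoothing with the standard two-parameter
#' filter: polynomial order `poly_order` over a centred window of `window`
#' points (defaults: order 5, window 15).  Endpoints are handled by the
#' filter's transient projection, equivalent to fitting the edge polynomial
#' and evaluating it at the boundary points, so polynomials up to
#' `poly_order` pass through unchanged.
#'
#' @param spec Tibble with `wavenumber_cm1`, `intensity_au`.
#' @param poly_order Polynomial order (< `window`).
#' @param window Odd window length in points.
#' @return The spectrum tibble with smoothed `intensity_au`.
#' @export
raman_smooth <- function(spec, poly_order = 5L, window = 15L) {
  spec <- as_spectrum(spec)
  if (window %% 2 != 1 || window <= poly_order)
    stop_ecm("`window` must be odd and greater than `poly_order`.",
             "invalid_parameter")
  if (window > nrow(spec))
    stop_ecm("`window` exceeds the number of spectral points.",
             "invalid_parameter")
  spec$intensity_au <-
    as.numeric(signal::sgolayfilt(spec$intensity_au, p = poly_order,
                                  n = window))
  spec
}

#' Iterative modified-polyfit background subtraction
#'
#' Estimates the smooth fluorescence background of a spectrum by the
#' modified polynomial fit (Lieber-type) method: fit a polynomial of degree
#' `poly_order` (default 7) to the working spectrum, clip the working
#' spectrum to the fit wherever it lies above it, and repeat.  The
#' per-round baseline changes decay roughly geometrically, so iteration
#' stops when the projected total remaining change of the fitted baseline
#' (current change divided by one minus the estimated decay ratio),
#' relative to the intensity range of the input, drops below `threshold`
#' (default 1e-4), or at `max_iter` with a convergence warning.  Bounding
#' the projected remainder rather than the last step makes the operation
#' idempotent to within `threshold` times the intensity range.  The final
#' fit is subtracted.
#'
#' @param spec Tibble with `wavenumber_cm1`, `intensity_au`.
#' @param poly_order Baseline polynomial degree.
#' @param threshold Relative-change convergence threshold.
#' @param max_iter Iteration cap.
#' @return The spectrum with background-subtracted `intensity_au`, a
#'   `baseline_au` column, and attributes `n_iterations` and `converged`.
#' @export
raman_subtract_background <- function(spec, poly_order = 7L,
                                      threshold = 1e-4, max_iter = 500L) {
  spec <- as_spectrum(spec)
  if (nrow(spec) <= poly_order + 1L)
    stop_ecm("Spectrum shorter than `poly_order` + 2 points.",
             "invalid_parameter")
  x <- spec$wavenumber_cm1
  u <- (x - mean(x)) / (diff(range(x)) / 2)  # conditioning
  y0 <- spec$intensity_au
  rng <- diff(range(y0))
  if (rng == 0) rng <- 1
  work <- y0
  fit_prev <- NULL
  delta_prev <- Inf
  n_iter <- 0L
  converged <- FALSE
  basis <- stats::poly(u, degree = poly_order, raw = FALSE)
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    co <- stats::lm.fit(cbind(1, basis), work)
    fit <- co$fitted.values
    if (!is.null(fit_prev)) {
      delta <- max(abs(fit - fit_prev))
      q <- if (is.finite(delta_prev) && delta_prev > 0)
        min(delta / delta_prev, 0.95) else 0.5
      if (delta / (1 - q) / rng < threshold) {
        converged <- TRUE
        fit_prev <- fit
        break
      }
      delta_prev <- delta
    }
    fit_prev <- fit
    work <- pmin(work, fit)
  }
  if (!converged)
    warn(sprintf("Background fit did not converge in %d iterations.",
                 max_iter))
  out <- spec
  out$intensity_au <- y0 - fit_prev
  out$baseline_au <- fit_prev
  attr(out, "n_iterations") <- n_iter
  attr(out, "converged") <- converged
  out
}

#' Min-max normalization of a spectrum
#'
#' Rescales intensities to `(I - min) / (max - min)`, exactly attaining 0
#' and 1.  Invariant to positive affine transforms of the input.
#'
#' @param spec Tibble with `wavenumber_cm1`, `intensity_au`.
#' @return The spectrum with an `intensity_norm` column in `[0, 1]`.
#' @export
raman_normalize <- function(spec) {
  spec <- as_spectrum(spec)
  rng <- range(spec$intensity_au)
  if (diff(rng) == 0)
    stop_ecm("Constant spectrum: min-max normalization is undefined.",
             "degenerate_input")
  spec$intensity_norm <- (spec$intensity_au - rng[1]) / diff(rng)
  spec
}

#' Full spectral preprocessing pipeline
#'
#' Smooth, subtract the fluorescence background, and min-max normalize, in
#' that order.
#'
#' @inheritParams raman_smooth
#' @inheritParams raman_subtract_background
#' @return Processed spectrum tibble with `intensity_norm` and
#'   `baseline_au`; attributes `n_iterations`, `converged`.
#' @export
process_spectrum <- function(spec, poly_order = 5L, window = 15L,
                             bg_poly_order = 7L, bg_threshold = 1e-4,
                             bg_max_iter = 500L) {
  spec |>
    raman_smooth(poly_order = poly_order, window = window) |>
    raman_subtract_background(poly_order = bg_poly_order,
                              threshold = bg_threshold,
                              max_iter = bg_max_iter) |>
    raman_normalize()
}

#' Collagen/lipid band intensities and ratios
#'
#' Band intensity is the maximum intensity within `center +/-
#' half_window_cm1` (robust to small calibration shifts).  Ratios follow
#' the tissue convention: amide I (1650) / lipid (1300) and amide III
#' (1265) / lipid (1300).
#'
#' @param spec Processed spectrum (uses `intensity_norm` when present,
#'   otherwise `intensity_au`).
#' @param bands Named positions, 1/cm: `amide1`, `amide3`, `lipid`.
#' @param half_window_cm1 Band half-window, 1/cm.
#' @return One-row tibble with the three band intensities, `amide1_lipid`,
#'   `amide3_lipid`, and `undefined_ratio` flag (set when the lipid band
#'   intensity is not positive; ratios are then `NA`, never infinite).
#' @export
peak_ratios <- function(spec,
                        bands = c(amide1 = 1650, amide3 = 1265,
                                  lipid = 1300),
                        half_window_cm1 = 10) {
  spec <- as_tibble(spec)
  ycol <- if ("intensity_norm" %in% names(spec)) "intensity_norm"
          else "intensity_au"
  if (!all(c("amide1", "amide3", "lipid") %in% names(bands)))
    stop_ecm("`bands` must name amide1, amide3 and lipid positions.",
             "invalid_parameter")
  wn <- spec$wavenumber_cm1
  band_max <- function(center) {
    lo <- center - half_window_cm1; hi <- center + half_window_cm1
    if (lo < min(wn) || hi > max(wn))
      stop_ecm(sprintf("Band window %g +/- %g lies outside the grid.",
                       center, half_window_cm1), "invalid_parameter")
    max(spec[[ycol]][wn >= lo & wn <= hi])
  }
  i1 <- band_max(bands[["amide1"]])
  i3 <- band_max(bands[["amide3"]])
  il <- band_max(bands[["lipid"]])
  undef <- il <= 0
  tibble(amide1_intensity = i1, amide3_intensity = i3,
         lipid_intensity = il,
         amide1_lipid = if (undef) NA_real_ else i1 / il,
         amide3_lipid = if (undef) NA_real_ else i3 / il,
         undefined_ratio = undef)
}

#' Principal component analysis of a set of spectra
#'
#' Column-mean-centred PCA (no variance scaling; spectra are assumed
#' already min-max normalized) by singular value decomposition.  Loading
#' signs are fixed so that each component's largest-magnitude loading is
#' positive.
#'
#' @param spectra Either a list of processed spectrum tibbles on a common
#'   wavenumber grid, or a long tibble with columns `spectrum`,
#'   `wavenumber_cm1` and an intensity column.
#' @param n_components Components to retain.
#' @return A `raman_pca` object with `scores` (tibble: spectrum x PC),
#'   `loadings` (tibble: wavenumber x PC), `explained_variance_fraction`,
#'   `center`, and `zero_variance` flag.  `tidy()` returns scores,
#'   `glance()` the variance summary.
#' @export
raman_pca <- function(spectra, n_components = 2L) {
  mat <- spectra_matrix(spectra)
  if (nrow(mat) < 2L)
    stop_ecm("PCA needs at least 2 spectra.", "invalid_input")
  n_components <- min(n_components, nrow(mat) - 1L, ncol(mat))
  total_var <- sum(apply(mat, 2, var))
  if (total_var <= .Machine$double.eps * ncol(mat)) {
    return(structure(list(
      scores = tibble(spectrum = rownames(mat)),
      loadings = tibble(wavenumber_cm1 = as.numeric(colnames(mat))),
      explained_variance_fraction = numeric(0),
      center = colMeans(mat), zero_variance = TRUE),
      class = "raman_pca"))
  }
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  load <- pc$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    sign(load[which.max(abs(load[, j])), j])
  }, numeric(1))
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(pc$x[, k, drop = FALSE], 2, flip, `*`)
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble(spectrum = rownames(mat)),
                              as_tibble(scores)),
    loadings = dplyr::bind_cols(
      tibble(wavenumber_cm1 = as.numeric(colnames(mat))),
      as_tibble(load)),
    explained_variance_fraction = evf[k],
    all_variance_fractions = evf,
    center = pc$center, zero_variance = FALSE),
    class = "raman_pca")
}

# Accepts a list of spectrum tibbles or a long tibble; returns spectra x
# wavenumber matrix with dimnames.
spectra_matrix <- function(spectra) {
  if (is.data.frame(spectra)) {
    if (!all(c("spectrum", "wavenumber_cm1") %in% names(spectra)))
      stop_ecm("Long input needs columns `spectrum` and `wavenumber_cm1`.",
               "schema")
    ycol <- intersect(c("intensity_norm", "intensity_au"), names(spectra))[1]
    if (is.na(ycol))
      stop_ecm("Long input needs `intensity_norm` or `intensity_au`.",
               "schema")
    wide <- tidyr::pivot_wider(spectra[, c("spectrum", "wavenumber_cm1",
                                           ycol)],
                               names_from = "wavenumber_cm1",
                               values_from = dplyr::all_of(ycol))
    mat <- as.matrix(wide[, -1])
    rownames(mat) <- as.character(wide$spectrum)
    if (anyNA(mat))
      stop_ecm("Spectra are not on a common wavenumber grid.",
               "grid_mismatch")
    return(mat)
  }
  if (!is.list(spectra) || length(spectra) < 1L)
    stop_ecm("`spectra` must be a list of spectra or a long tibble.",
             "invalid_input")
  grids <- lapply(spectra, function(s) s$wavenumber_cm1)
  if (!all(vapply(grids, identical, logical(1), y = grids[[1]])))
    stop_ecm("Spectra are not on a common wavenumber grid.", "grid_mismatch")
  rows <- lapply(spectra, function(s) {
    if ("intensity_norm" %in% names(s)) s$intensity_norm else s$intensity_au
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(spectra) %||% as.character(seq_along(spectra))
  colnames(mat) <- as.character(grids[[1]])
  mat
}

#' @export
print.raman_pca <- function(x, ...) {
  if (x$zero_variance) {
    cat("<raman_pca> degenerate: zero total variance\n")
  } else {
    cat(sprintf("<raman_pca> %d spectra, %d wavenumbers; variance: %s\n",
                nrow(x$scores), nrow(x$loadings),
                paste0(sprintf("%.1f%%",
                               100 * x$explained_variance_fraction),
                       collapse = ", ")))
  }
  invisible(x)
}

#' @rdname raman_pca
#' @param x A `raman_pca` object.
#' @param ... Unused.
#' @export
tidy.raman_pca <- function(x, ...) x$scores

#' @rdname raman_pca
#' @export
glance.raman_pca <- function(x, ...) {
  if (x$zero_variance)
    return(tibble(n_components = 0L, zero_variance = TRUE))
  tibble(n_components = length(x$explained_variance_fraction),
         var_pc1 = x$explained_variance_fraction[1],
         var_pc2 = if (length(x$explained_variance_fraction) > 1)
           x$explained_variance_fraction[2] else NA_real_,
         zero_variance = FALSE)
}
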