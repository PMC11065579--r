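# Readers/writers: images (TIFF/PNG + pixel-size sidecar) and headered CSV
# tables with schema validation.

#' Read a grayscale micrograph
#'
#' Reads 8/16-bit TIFF or PNG.  RGB input is converted to luminance
#' (Rec. 709 weights) with a warning.  The pixel size is taken from the
#' argument or, failing that, a `<path>.json` sidecar with a
#' `pixel_size_um` entry; stages that need physical units error without it.
#'
#' @param path Image file (.tif/.tiff/.png).
#' @param pixel_size_um Pixel size, um/px (optional here).
#' @return A [micrograph()] (or plain matrix when no pixel size is known).
#' @export
read_micrograph <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path))
    stop_ecm(sprintf("Image file not found: %s", path), "io")
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_ecm(sprintf("Unsupported image format '.%s' for %s", ext, path),
             "io")),
    error = function(e)
      stop_ecm(sprintf("Failed to read image %s: %s", path,
                       conditionMessage(e)), "io"))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      warn(sprintf("RGB image %s converted to luminance.", basename(path)))
      arr <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (is.null(pixel_size_um)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      pixel_size_um <- meta$pixel_size_um
    }
  }
  if (is.null(pixel_size_um)) return(arr)
  micrograph(arr, pixel_size_um)
}

#' Write a micrograph as 16-bit grayscale TIFF with a metadata sidecar
#'
#' Intensities are clipped to `[0, 1]` and quantized to 16 bits; the pixel
#' size is recorded in `<path>.json`.
#'
#' @param img A [micrograph()] or numeric matrix.
#' @param path Output .tif path.
#' @param pixel_size_um Pixel size (taken from `img` when attached).
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path, pixel_size_um = NULL) {
  ps <- attr(img, "pixel_size_um") %||% pixel_size_um
  x <- pmin(pmax(unclass(img), 0), 1)
  tiff::writeTIFF(x, path, bits.per.sample = 16L)
  if (!is.null(ps))
    jsonlite::write_json(list(pixel_size_um = ps), paste0(path, ".json"),
                         auto_unbox = TRUE)
  invisible(path)
}

read_csv_checked <- function(path, required, kind) {
  if (!file.exists(path))
    stop_ecm(sprintf("%s file not found: %s", kind, path), "io")
  tab <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e)
      stop_ecm(sprintf("Failed to read %s from %s: %s", kind, path,
                       conditionMessage(e)), "io"))
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop_ecm(sprintf(
      "%s file %s is missing column(s) %s; expected header: %s",
      kind, path, paste(missing, collapse = ", "),
      paste(required, collapse = ",")), "schema")
  for (col in required) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop_ecm(sprintf(
        "Non-numeric value in column `%s` of %s (first offending row: %d).",
        col, path, if (length(bad)) bad[1] else NA_integer_), "parse")
    }
    if (anyNA(v))
      stop_ecm(sprintf("Missing value in column `%s` of %s (row %d).",
                       col, path, which(is.na(v))[1]), "parse")
  }
  tab
}

#' Read a two-column Raman spectrum CSV
#'
#' Expects columns `wavenumber_cm1`, `intensity_au`.  Descending
#' wavenumbers are sorted ascending with a warning (or an error with
#' `strict = TRUE`).
#'
#' @param path CSV file.
#' @param strict Error instead of sorting on a descending grid.
#' @return Spectrum tibble.
#' @export
read_spectrum <- function(path, strict = FALSE) {
  tab <- read_csv_checked(path, c("wavenumber_cm1", "intensity_au"),
                          "spectrum")
  if (any(diff(tab$wavenumber_cm1) <= 0)) {
    if (strict)
      stop_ecm(sprintf("Wavenumbers in %s are not strictly ascending.",
                       path), "invalid_input")
    warn(sprintf("Wavenumbers in %s not ascending: sorting.", path))
    tab <- dplyr::arrange(tab, .data$wavenumber_cm1)
  }
  as_spectrum(tab)
}

#' Read an AFM force curve CSV
#'
#' Expects columns `displacement_nm`, `force_nN`; optional metadata columns
#' are preserved.
#'
#' @param path CSV file.
#' @param tip_radius_um,poisson_ratio Optional probe metadata attached as
#'   attributes for [fit_hertz()].
#' @return Force-curve tibble.
#' @export
read_force_curve <- function(path, tip_radius_um = NULL,
                             poisson_ratio = NULL) {
  tab <- read_csv_checked(path, c("displacement_nm", "force_nN"),
                          "force curve")
  if (!is.null(tip_radius_um)) attr(tab, "tip_radius_um") <- tip_radius_um
  if (!is.null(poisson_ratio)) attr(tab, "poisson_ratio") <- poisson_ratio
  tab
}

#' Read a rheology time sweep CSV
#'
#' Expects columns `time_s`, `storage_modulus_pa`, `loss_modulus_pa`.
#'
#' @param path CSV file.
#' @return Sweep tibble.
#' @export
read_rheology <- function(path) {
  read_csv_checked(path, c("time_s", "storage_modulus_pa",
                           "loss_modulus_pa"), "rheology sweep")
}

#' Read an invasion/migration counts CSV
#'
#' Expects columns `n_invading`, `n_migrating` (one row per replicate).
#'
#' @param path CSV file.
#' @return Counts tibble.
#' @export
read_counts <- function(path) {
  read_csv_checked(path, c("n_invading", "n_migrating"), "counts")
}

#' Read an analyte table CSV
#'
#' Expects columns `analyte`, `value`.
#'
#' @param path CSV file.
#' @return Analyte tibble.
#' @export
read_analytes <- function(path) {
  if (!file.exists(path))
    stop_ecm(sprintf("analyte file not found: %s", path), "io")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("analyte", "value") %in% names(tab)))
    stop_ecm(sprintf(
      "analyte file %s must have header: analyte,value", path), "schema")
  if (!is.numeric(tab$value))
    stop_ecm(sprintf("Non-numeric `value` in %s.", path), "parse")
  tab
}
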