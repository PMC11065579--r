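# Reproducible stage runner: a serializable config fully determines a run;
# every output directory receives the resolved config, a log, and a version
# stamp so the run can be replayed.

#' Run a pipeline stage from a configuration
#'
#' Executes one named stage with all its parameters taken from a config
#' (a named list, or a path to a YAML/JSON file with the same structure):
#'
#' \describe{
#'   \item{simulate_fibers}{params are [fiber_image_spec()] fields; writes
#'     the image (16-bit TIFF + sidecar), truth mask, truth table.}
#'   \item{simulate_spectrum}{params are [spectrum_spec()] fields (peaks as
#'     a list of center/height/fwhm records); writes spectrum and truth
#'     components.}
#'   \item{simulate_afm}{params are [force_curve_spec()] fields; writes the
#'     curve CSV.}
#'   \item{simulate_masks}{params are [mask_pair_spec()] fields; writes both
#'     masks as PNG.}
#'   \item{fibers}{input `image` (+ `pixel_size_um`); segmentation/network
#'     parameters; writes descriptor and segment CSVs.}
#'   \item{raman}{input `spectra` (vector of CSV paths); smoothing /
#'     background parameters; writes processed spectra, peak ratios, and
#'     (for >= 2 spectra) PCA scores/loadings/variance CSVs.}
#'   \item{afm}{input `curves` (vector of CSV paths) plus probe metadata;
#'     writes per-curve fit table and histogram CSV.}
#'   \item{rheology}{input `sweep` CSV; writes the modulus summary.}
#'   \item{cells}{sub-mode `metric` of invasion|foldchange with their
#'     inputs; writes the metric table.}
#' }
#'
#' A `seed` entry (default 1) seeds every stochastic stage.  The stage
#' writes `config.yaml` (fully resolved), `log.txt`, and returns the output
#' paths; re-running from the emitted config reproduces the outputs.
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @param out_dir Output directory (created; overrides `config$out_dir`).
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_ecm(sprintf("Config file not found: %s", config), "io")
    config <- if (tolower(tools::file_ext(config)) == "json")
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$stage))
    stop_ecm("Config must be a list with a `stage` entry.", "config")
  stage <- config$stage
  out_dir <- out_dir %||% config$out_dir %||%
    stop_ecm("Config needs an `out_dir`.", "config")
  config$out_dir <- out_dir
  config$seed <- config$seed %||% 1L
  params <- config$params %||% list()
  inputs <- config$inputs %||% list()
  for (p in unlist(inputs)) {
    if (is.character(p) && !file.exists(p))
      stop_ecm(sprintf("[%s] input file does not exist: %s", stage, p),
               "config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("stage: %s", stage),
                 sprintf("ecmquant version: %s",
                         as.character(utils::packageVersion("ecmquant"))),
                 sprintf("seed: %d", as.integer(config$seed)))
  outputs <- tryCatch(
    run_stage(stage, params, inputs, out_dir, as.integer(config$seed)),
    error = function(e) {
      stop_ecm(sprintf("[stage %s] %s", stage, conditionMessage(e)),
               "stage_failure")
    })
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  writeLines(c(log_lines, sprintf("output: %s", unlist(outputs))),
             file.path(out_dir, "log.txt"))
  invisible(outputs)
}

run_stage <- function(stage, params, inputs, out_dir, seed) {
  path_of <- function(name) file.path(out_dir, name)
  switch(stage,
    simulate_fibers = {
      spec <- do.call(fiber_image_spec, c(params, list(seed = seed)))
      sim <- generate_fiber_image(spec)
      write_micrograph(quantize16(sim$image), path_of("image.tif"),
                       pixel_size_um = spec$pixel_size_um)
      png::writePNG(sim$truth_mask * 1, path_of("truth_mask.png"))
      readr::write_csv(sim$fibers, path_of("truth_fibers.csv"))
      list(image = path_of("image.tif"),
           truth_mask = path_of("truth_mask.png"),
           truth_fibers = path_of("truth_fibers.csv"))
    },
    simulate_spectrum = {
      if (!is.null(params$peaks))
        params$peaks <- as_tibble(as.data.frame(params$peaks))
      spec <- do.call(spectrum_spec, c(params, list(seed = seed)))
      sim <- generate_spectrum(spec)
      readr::write_csv(sim$spectrum, path_of("spectrum.csv"))
      truth <- tibble(wavenumber_cm1 = sim$spectrum$wavenumber_cm1,
                      peak_component = sim$peak_component,
                      baseline_au = sim$baseline_au,
                      noise_au = sim$noise_au)
      readr::write_csv(truth, path_of("truth_components.csv"))
      list(spectrum = path_of("spectrum.csv"),
           truth = path_of("truth_components.csv"))
    },
    simulate_afm = {
      spec <- do.call(force_curve_spec, c(params, list(seed = seed)))
      curve <- generate_force_curve(spec)
      readr::write_csv(curve, path_of("force_curve.csv"))
      list(curve = path_of("force_curve.csv"))
    },
    simulate_masks = {
      spec <- do.call(mask_pair_spec, c(params, list(seed = seed)))
      masks <- generate_mask_pair(spec)
      png::writePNG(masks$mask_a * 1, path_of("mask_a.png"))
      png::writePNG(masks$mask_b * 1, path_of("mask_b.png"))
      list(mask_a = path_of("mask_a.png"), mask_b = path_of("mask_b.png"))
    },
    fibers = {
      img <- read_micrograph(inputs$image,
                             pixel_size_um = params$pixel_size_um)
      seg_args <- params[intersect(names(params),
                                   c("pixel_size_um", "median_window",
                                     "otsu_tile_px", "min_object_px",
                                     "invert", "halfmax_refine",
                                     "peak_radius_px"))]
      net_args <- params[intersect(names(params),
                                   c("spur_prune_px", "node_merge_px",
                                     "prune", "max_length_factor"))]
      res <- do.call(analyze_fibers, c(list(img), seg_args, net_args))
      readr::write_csv(res, path_of("descriptors.csv"))
      readr::write_csv(attr(res, "network")$segments,
                       path_of("segments.csv"))
      list(descriptors = path_of("descriptors.csv"),
           segments = path_of("segments.csv"))
    },
    raman = {
      paths <- unlist(inputs$spectra)
      args <- params[intersect(names(params),
                               c("poly_order", "window", "bg_poly_order",
                                 "bg_threshold", "bg_max_iter"))]
      processed <- lapply(paths, function(p)
        do.call(process_spectrum, c(list(read_spectrum(p)), args)))
      names(processed) <- basename(paths)
      long <- dplyr::bind_rows(lapply(processed, function(s)
        s[, c("wavenumber_cm1", "intensity_norm")]), .id = "spectrum")
      readr::write_csv(long, path_of("processed_spectra.csv"))
      ratios <- dplyr::bind_rows(lapply(processed, peak_ratios),
                                 .id = "spectrum")
      readr::write_csv(ratios, path_of("peak_ratios.csv"))
      out <- list(processed = path_of("processed_spectra.csv"),
                  ratios = path_of("peak_ratios.csv"))
      if (length(processed) >= 2L) {
        pca <- raman_pca(processed)
        readr::write_csv(pca$scores, path_of("pca_scores.csv"))
        readr::write_csv(pca$loadings, path_of("pca_loadings.csv"))
        readr::write_csv(
          tibble(component = seq_along(pca$explained_variance_fraction),
                 explained_variance_fraction =
                   pca$explained_variance_fraction),
          path_of("pca_variance.csv"))
        out$pca_scores <- path_of("pca_scores.csv")
      }
      out
    },
    afm = {
      paths <- unlist(inputs$curves)
      fits <- lapply(paths, function(p)
        fit_hertz(read_force_curve(p,
                                   tip_radius_um = params$tip_radius_um,
                                   poisson_ratio = params$poisson_ratio)))
      tab <- dplyr::bind_rows(lapply(fits, tidy))
      tab$curve <- basename(paths)
      readr::write_csv(tab, path_of("hertz_fits.csv"))
      out <- list(fits = path_of("hertz_fits.csv"))
      if (any(tab$ok)) {
        bw <- params$bin_width_pa %||%
          max(diff(range(tab$E_pa[tab$ok])) / 10, 1)
        dist <- stiffness_histogram(tab[tab$ok, ], bin_width_pa = bw)
        readr::write_csv(dist$histogram, path_of("stiffness_histogram.csv"))
        out$histogram <- path_of("stiffness_histogram.csv")
      }
      out
    },
    rheology = {
      sweep <- read_rheology(inputs$sweep)
      args <- params[intersect(names(params),
                               c("poisson_ratio", "plateau_fraction",
                                 "g_mode"))]
      res <- do.call(youngs_from_rheology, c(list(sweep), args))
      readr::write_csv(res, path_of("youngs_modulus.csv"))
      list(modulus = path_of("youngs_modulus.csv"))
    },
    cells = {
      metric <- params$metric %||%
        stop_ecm("cells stage needs params$metric.", "config")
      res <- switch(metric,
        invasion = {
          counts <- read_counts(inputs$counts)
          dplyr::bind_rows(lapply(seq_len(nrow(counts)), function(i)
            invasion_index(counts$n_invading[i], counts$n_migrating[i])))
        },
        foldchange = {
          fold_change_table(read_analytes(inputs$case),
                            read_analytes(inputs$control),
                            min_fold = params$min_fold %||% 1.5)
        },
        stop_ecm(sprintf("Unknown cells metric '%s'.", metric), "config"))
      readr::write_csv(res, path_of(paste0(metric, ".csv")))
      setNames(list(path_of(paste0(metric, ".csv"))), metric)
    },
    stop_ecm(sprintf("Unknown stage '%s'.", stage), "config")
  )
}

# Quantize a float image to the 16-bit grid so that TIFF round-trips are
# bit-identical.
quantize16 <- function(img) {
  x <- pmin(pmax(unclass(img), 0), 1)
  q <- round(x * 65535) / 65535
  if (!is.null(attr(img, "pixel_size_um")))
    q <- micrograph(q, attr(img, "pixel_size_um"))
  q
}
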