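# Contact mechanics: Hertz spherical-indenter fits of AFM force-distance
# curves, stiffness distributions, and rheology-to-Young's-modulus
# conversion.

as_force_curve <- function(curve) {
  curve <- as_tibble(curve)
  if (!all(c("displacement_nm", "force_nN") %in% names(curve)))
    stop_ecm("A force curve needs columns `displacement_nm` and `force_nN`.",
             "schema")
  if (nrow(curve) < 20L)
    stop_ecm("A force curve needs at least 20 points.", "invalid_input")
  if (!all(is.finite(curve$displacement_nm)) ||
      !all(is.finite(curve$force_nN)))
    stop_ecm("Force-curve values must be finite.", "invalid_input")
  curve
}

#' Convert raw deflection data to a tip-sample force curve
#'
#' For instruments exporting piezo position and cantilever deflection, the
#' force is `F = k d` and the tip-sample separation is `z - d`.
#'
#' @param curve Tibble with `displacement_nm` (piezo) and `deflection_nm`.
#' @param spring_constant_nN_per_nm Calibrated cantilever spring constant.
#' @return Tibble with `displacement_nm` (separation) and `force_nN`.
#' @export
deflection_to_force <- function(curve, spring_constant_nN_per_nm) {
  curve <- as_tibble(curve)
  if (!all(c("displacement_nm", "deflection_nm") %in% names(curve)))
    stop_ecm("Needs columns `displacement_nm` and `deflection_nm`.",
             "schema")
  check_number(spring_constant_nN_per_nm, "spring_constant_nN_per_nm",
               lower = 1e-12)
  tibble(displacement_nm = curve$displacement_nm - curve$deflection_nm,
         force_nN = spring_constant_nN_per_nm * curve$deflection_nm)
}

#' Fit the Hertz spherical-indenter model to a force-distance curve
#'
#' Nonlinear least squares of
#' `F(z) = baseline + (4/3) (E / (1 - nu^2)) sqrt(R) max(z - z0, 0)^(3/2)`
#' with free parameters modulus `E`, contact point `z0`, and `baseline`.
#' For a fixed contact point the model is linear in `(baseline, a)`, so the
#' fit profiles the contact point: a coarse grid over candidate contact
#' points seeds a 1-D refinement of `z0`, each candidate solved by linear
#' least squares with the Hertzian amplitude constrained non-negative.
#'
#' @param curve Tibble with `displacement_nm`, `force_nN` (e.g. a generated
#'   curve or [read_force_curve()] output).
#' @param tip_radius_um Spherical tip radius, um (default 5; taken from the
#'   curve attribute when present).
#' @param poisson_ratio Poisson's ratio (default 0.5).
#' @param n_grid Candidate contact points in the coarse grid.
#' @return A `hertz_fit` object: `E_pa`, `contact_point_nm`, `baseline_nN`,
#'   `rms_residual_nN`, `r_squared`, `ok` (FALSE with a `reason` when no
#'   super-baseline force exists).  `tidy()`/`glance()` return one-row
#'   tibbles.
#' @export
fit_hertz <- function(curve, tip_radius_um = NULL, poisson_ratio = NULL,
                      n_grid = 60L) {
  R_um <- tip_radius_um %||% attr(curve, "tip_radius_um") %||% 5
  nu <- poisson_ratio %||% attr(curve, "poisson_ratio") %||% 0.5
  check_number(R_um, "tip_radius_um", lower = 1e-12)
  check_number(nu, "poisson_ratio", lower = 0, upper = 0.5)
  curve <- as_force_curve(curve)
  z <- curve$displacement_nm
  f <- curve$force_nN
  ord <- order(z)
  z <- z[ord]; f <- f[ord]

  # linear profile for fixed contact point: F = b + a * max(z - z0, 0)^1.5
  sse_at <- function(z0) {
    x <- pmax(z - z0, 0)^1.5
    if (all(x == 0)) {
      b <- mean(f)
      return(list(sse = sum((f - b)^2), a = 0, b = b))
    }
    xm <- mean(x); fm <- mean(f)
    sxx <- sum((x - xm)^2)
    a <- if (sxx > 0) sum((x - xm) * (f - fm)) / sxx else 0
    if (a < 0) a <- 0
    b <- fm - a * xm
    list(sse = sum((f - (b + a * x))^2), a = a, b = b)
  }
  zc <- seq(min(z), max(z) - 0.02 * diff(range(z)), length.out = n_grid)
  sses <- vapply(zc, function(z0) sse_at(z0)$sse, numeric(1))
  i0 <- which.min(sses)
  lo <- zc[max(1L, i0 - 1L)]
  hi <- zc[min(length(zc), i0 + 1L)]
  opt <- optimize(function(z0) sse_at(z0)$sse, c(lo, hi),
                  tol = .Machine$double.eps^0.5 * diff(range(z)))
  best <- sse_at(opt$minimum)
  z0 <- opt$minimum

  a_si <- best$a * 1e-9 / (1e-9)^1.5           # nN/nm^1.5 -> N/m^1.5
  E_pa <- a_si * 0.75 * (1 - nu^2) / sqrt(R_um * 1e-6)
  resid <- f - (best$b + best$a * pmax(z - z0, 0)^1.5)
  ss_tot <- sum((f - mean(f))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  ok <- best$a > 0
  structure(list(
    E_pa = if (ok) E_pa else NA_real_,
    contact_point_nm = if (ok) z0 else NA_real_,
    baseline_nN = best$b,
    rms_residual_nN = sqrt(mean(resid^2)),
    r_squared = r2,
    ok = ok,
    reason = if (ok) NA_character_
             else "no force rise above baseline detected",
    tip_radius_um = R_um, poisson_ratio = nu,
    n_points = length(z), data = tibble(displacement_nm = z, force_nN = f)),
    class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf(
      "<hertz_fit> E = %.4g Pa, contact at %.4g nm, R^2 = %.4f\n",
      x$E_pa, x$contact_point_nm, x$r_squared))
  } else {
    cat(sprintf("<hertz_fit> FAILED: %s\n", x$reason))
  }
  invisible(x)
}

#' @rdname fit_hertz
#' @param x A `hertz_fit` object.
#' @param ... Unused.
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(E_pa = x$E_pa, contact_point_nm = x$contact_point_nm,
         baseline_nN = x$baseline_nN, rms_residual_nN = x$rms_residual_nN,
         r_squared = x$r_squared, ok = x$ok)
}

#' @rdname fit_hertz
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(E_pa = x$E_pa, r_squared = x$r_squared,
         rms_residual_nN = x$rms_residual_nN, n_points = x$n_points,
         ok = x$ok)
}

#' Stiffness distribution over a set of Hertz fits
#'
#' Pools fitted moduli, drops failed fits (counting them), and bins the
#' values into a fixed-width histogram; modes are detected as local maxima
#' of the counts with a prominence of at least `min_prominence` times the
#' tallest bin.
#'
#' @param fits List of `hertz_fit` objects, or a tibble bearing an `E_pa`
#'   column (e.g. row-bound `tidy()` output).
#' @param bin_width_pa Histogram bin width, Pa.
#' @param min_prominence Mode-detection prominence fraction.
#' @return A `stiffness_distribution`: `histogram` tibble
#'   (`bin_mid_pa`, `count`), `moduli_pa`, `mean_pa`, `n_failed`, and
#'   `modes_pa` (bin centres of detected modes).
#' @export
stiffness_histogram <- function(fits, bin_width_pa, min_prominence = 0.2) {
  check_number(bin_width_pa, "bin_width_pa", lower = 1e-12)
  if (is.data.frame(fits)) {
    if (!"E_pa" %in% names(fits))
      stop_ecm("`fits` tibble needs an `E_pa` column.", "schema")
    e <- fits$E_pa
  } else {
    e <- vapply(fits, function(f) {
      if (!inherits(f, "hertz_fit"))
        stop_ecm("`fits` must contain hertz_fit objects.", "invalid_input")
      f$E_pa
    }, numeric(1))
  }
  n_failed <- sum(!is.finite(e))
  e <- e[is.finite(e)]
  if (length(e) == 0L)
    stop_ecm("No successful fits to bin.", "no_successful_fits")
  breaks <- seq(0, max(e) + bin_width_pa, by = bin_width_pa)
  counts <- tabulate(findInterval(e, breaks, rightmost.closed = TRUE),
                     length(breaks) - 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  modes <- mids[find_modes(counts, min_prominence)]
  structure(list(
    histogram = tibble(bin_mid_pa = mids, count = counts),
    moduli_pa = e, mean_pa = mean(e), n_failed = n_failed,
    bin_width_pa = bin_width_pa, modes_pa = modes),
    class = "stiffness_distribution")
}

#' @export
print.stiffness_distribution <- function(x, ...) {
  cat(sprintf(
    "<stiffness_distribution> n = %d (%d failed), mean = %.4g Pa, %d mode(s)\n",
    length(x$moduli_pa), x$n_failed, x$mean_pa, length(x$modes_pa)))
  invisible(x)
}

#' @rdname stiffness_histogram
#' @param x A `stiffness_distribution` object.
#' @param ... Unused.
#' @export
glance.stiffness_distribution <- function(x, ...) {
  tibble(n = length(x$moduli_pa), n_failed = x$n_failed,
         mean_pa = x$mean_pa, median_pa = median(x$moduli_pa),
         n_modes = length(x$modes_pa))
}

#' Young's modulus from an oscillatory rheology time sweep
#'
#' Averages `G = G' + G''` over the gelation plateau (the final
#' `plateau_fraction` of points) and converts with `E = 2 G (1 + nu)`; with
#' nu = 0.5 this is `E = 3 G`.  The sum convention for G follows the tissue
#' rheology workflow this pipeline mirrors; `g_mode = "magnitude"` offers
#' the conventional complex-modulus magnitude `|G*| = sqrt(G'^2 + G''^2)`
#' instead.
#'
#' @param sweep Tibble with `time_s`, `storage_modulus_pa`,
#'   `loss_modulus_pa`.
#' @param poisson_ratio Poisson's ratio (default 0.5, incompressible gel).
#' @param plateau_fraction Final fraction of the sweep averaged.
#' @param g_mode `"sum"` (default) or `"magnitude"`.
#' @return One-row tibble: `G_pa`, `E_pa`, `g_prime_pa`, `g_double_prime_pa`
#'   (plateau means), `n_plateau`.
#' @export
youngs_from_rheology <- function(sweep, poisson_ratio = 0.5,
                                 plateau_fraction = 0.2,
                                 g_mode = c("sum", "magnitude")) {
  g_mode <- match.arg(g_mode)
  sweep <- as_tibble(sweep)
  req <- c("time_s", "storage_modulus_pa", "loss_modulus_pa")
  if (!all(req %in% names(sweep)))
    stop_ecm(paste("A rheology sweep needs columns",
                   paste(req, collapse = ", ")), "schema")
  if (nrow(sweep) == 0L)
    stop_ecm("Empty rheology sweep.", "invalid_input")
  if (any(sweep$storage_modulus_pa < 0) || any(sweep$loss_modulus_pa < 0))
    stop_ecm("Moduli must be non-negative.", "invalid_input")
  check_number(poisson_ratio, "poisson_ratio", lower = 0, upper = 0.5)
  check_number(plateau_fraction, "plateau_fraction", lower = 1e-9, upper = 1)
  n <- nrow(sweep)
  sweep <- dplyr::arrange(sweep, .data$time_s)
  take <- max(1L, ceiling(plateau_fraction * n))
  tailpart <- sweep[(n - take + 1L):n, ]
  gp <- mean(tailpart$storage_modulus_pa)
  gpp <- mean(tailpart$loss_modulus_pa)
  G <- switch(g_mode, sum = gp + gpp, magnitude = sqrt(gp^2 + gpp^2))
  tibble(G_pa = G, E_pa = 2 * G * (1 + poisson_ratio),
         g_prime_pa = gp, g_double_prime_pa = gpp, n_plateau = take,
         poisson_ratio = poisson_ratio, g_mode = g_mode)
}
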