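# Shared fixtures: all built in code at test time.

# Paint a single straight stroke of given axial angle (degrees, math
# convention with y down the rows) and width into a logical mask.
paint_stroke <- function(angle_deg, h = 128, w = 128, width_px = 5,
                         length_px = 90, center = c(w / 2, h / 2)) {
  th <- angle_deg * pi / 180
  x0 <- center[1] - length_px / 2 * cos(th)
  x1 <- center[1] + length_px / 2 * cos(th)
  y0 <- center[2] + length_px / 2 * sin(th)
  y1 <- center[2] - length_px / 2 * sin(th)
  px <- rep(seq_len(w) - 0.5, each = h)
  py <- rep(seq_len(h) - 0.5, times = w)
  bx <- x1 - x0; by <- y1 - y0
  t <- pmin(1, pmax(0, ((px - x0) * bx + (py - y0) * by) / (bx^2 + by^2)))
  d <- sqrt((px - x0 - t * bx)^2 + (py - y0 - t * by)^2)
  matrix(d <= width_px / 2, h, w)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Brute-force double-loop overlap count, the integer oracle for colocalize().
overlap_loop <- function(a, b) {
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (a[i, j] && b[i, j]) n <- n + 1L
  n
}

make_spectrum_tbl <- function(wn, y) {
  tibble::tibble(wavenumber_cm1 = wn, intensity_au = y)
}
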