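# Internal validation and numeric helpers shared across modules.

stop_ecm <- function(msg, class) {
  abort(msg, class = c(paste0("ecmquant_", class), "ecmquant_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ecm(sprintf("`%s` must be a single finite number.", name),
             "invalid_spec")
  if (x < lower || x > upper)
    stop_ecm(sprintf("`%s` must be in [%s, %s], got %s.", name,
                     format(lower), format(upper), format(x)),
             "invalid_spec")
  if (!allow_zero && x == 0)
    stop_ecm(sprintf("`%s` must be non-zero.", name), "invalid_spec")
  if (integerish && x != round(x))
    stop_ecm(sprintf("`%s` must be an integer.", name), "invalid_spec")
  invisible(x)
}

# Axial direction sampler: von Mises on the doubled angle, so that kappa = 0
# is uniform on [0, 180) and large kappa concentrates around mode_deg.
# Best & Fisher (1979) rejection sampler; runs under the caller's RNG.
sample_axial_deg <- function(n, mode_deg, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa <= 0) return(runif(n, 0, 180))
  if (!is.finite(kappa)) return(rep(mode_deg %% 180, n))  # perfectly aligned
  mu <- 2 * mode_deg * pi / 180  # doubled-angle space
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
        theta <- mu + sign(u3 - 0.5) * acos(f)
        out[i] <- (theta / 2 * 180 / pi) %% 180
        break
      }
    }
  }
  out
}

# Mean resultant length of doubled angles; the orientation-index core.
axial_resultant <- function(theta_deg, weights = NULL) {
  if (length(theta_deg) == 0L) return(NA_real_)
  w <- weights %||% rep(1, length(theta_deg))
  if (sum(w) <= 0) return(NA_real_)
  phi <- 2 * theta_deg * pi / 180
  c1 <- sum(w * cos(phi)) / sum(w)
  s1 <- sum(w * sin(phi)) / sum(w)
  sqrt(c1^2 + s1^2)
}

# Length-weighted principal axial direction, degrees in [0, 180).
axial_mean_deg <- function(theta_deg, weights = NULL) {
  w <- weights %||% rep(1, length(theta_deg))
  phi <- 2 * theta_deg * pi / 180
  (atan2(sum(w * sin(phi)), sum(w * cos(phi))) / 2 * 180 / pi) %% 180
}

# Otsu threshold on a plain numeric vector (between-class variance maximum
# over a binned histogram).  Used for per-object marker-positivity calls.
otsu_vector <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(structure(rng[1], degenerate = TRUE))
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  structure(mids[which.max(sigma_b)], degenerate = FALSE)
}

# Local maxima of a non-negative count vector, plateau-aware (a run of
# equal counts is one candidate at its centre), with a simple prominence
# rule: a peak must exceed the higher of the two flanking minima by
# `min_prominence` * max(y).  A cluster split across two adjacent bins is
# one mode, not two: candidates closer than 2 bins keep only the taller.
find_modes <- function(y, min_prominence = 0.1) {
  if (length(y) < 1L || max(y) <= 0) return(integer(0))
  y <- c(0, as.numeric(y), 0)  # pad so edge peaks get full prominence
  n <- length(y)
  r <- rle(y)
  k <- length(r$values)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  cand <- integer(0)
  for (i in seq_len(k)) {
    left <- if (i > 1L) r$values[i - 1L] else -Inf
    right <- if (i < k) r$values[i + 1L] else -Inf
    if (r$values[i] > left && r$values[i] > right && r$values[i] > 0)
      cand <- c(cand, starts[i] + (r$lengths[i] - 1L) %/% 2L)
  }
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    prom <- y[i] - max(min(y[1:i]), min(y[i:n]))
    keep[j] <- prom >= min_prominence * max(y)
  }
  cand <- cand[keep]
  # merge near-adjacent candidates (same cluster straddling a bin edge)
  if (length(cand) > 1L) {
    cand <- cand[order(cand)]
    out <- cand[1]
    for (i in cand[-1]) {
      if (i - out[length(out)] <= 2L) {
        if (y[i] > y[out[length(out)]]) out[length(out)] <- i
      } else out <- c(out, i)
    }
    cand <- out
  }
  cand - 1L  # undo padding offset
}

is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_mask <- function(m, name = "mask") {
  if (!is_binary_mask(m))
    stop_ecm(sprintf("`%s` must be a binary (logical or 0/1) matrix.", name),
             "invalid_input")
  mode(m) <- "logical"
  m
}
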