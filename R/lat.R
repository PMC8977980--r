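#' Detect local activation times on unipolar electrograms
#'
#' Annotates each unipolar channel at the instants of maximum negative slope,
#' the standard LAT landmark for unipolar electrograms. Per channel:
#' the signal is optionally smoothed (moving average), the first derivative is
#' estimated by central differences, local minima of the derivative below
#' `-slope_floor` become candidates, and candidates are accepted greedily in
#' order of slope magnitude subject to a refractory spacing (ties broken by
#' the earlier time).
#'
#' The default slope floor is adaptive: 6 times the derivative noise SD,
#' estimated robustly (scaled median absolute deviation, with a
#' quietest-decile fallback), so that Gaussian noise extrema over a full
#' 30-s window stay below the floor while physiological downstrokes exceed
#' it by an order of magnitude.
#'
#' @param acquisition an `acquisition`
#' @param refractory_ms minimum spacing between accepted LATs, ms
#' @param slope_floor_mv_per_ms absolute slope threshold; `NULL` (default)
#'   uses the adaptive floor
#' @param smooth_samples moving-average width in samples (odd; 0 disables)
#' @return a `lat_series` object: `lats` (list of sorted per-electrode LAT
#'   vectors, ms), `slope_at_lat` (matching slopes, mV/ms), `refractory_ms`,
#'   `slope_floor` (per channel)
#' @export
detect_lats <- function(acquisition, refractory_ms = 60,
                        slope_floor_mv_per_ms = NULL,
                        smooth_samples = 5) {
  fs <- acquisition$sampling_rate_hz
  dt_ms <- 1000 / fs
  uni <- acquisition$unipolar
  n <- nrow(uni)
  lats <- vector("list", ncol(uni))
  slopes <- vector("list", ncol(uni))
  floors <- numeric(ncol(uni))
  for (i in seq_len(ncol(uni))) {
    x <- uni[, i]
    if (smooth_samples > 1) {
      k <- smooth_samples + (1 - smooth_samples %% 2)   # force odd
      x <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
      h <- (k - 1L) %/% 2L
      x[seq_len(h)] <- x[h + 1L]              # hold edges, no step artifact
      x[(n - h + 1L):n] <- x[n - h]
    }
    d <- c(0, (x[3:n] - x[1:(n - 2)]) / (2 * dt_ms), 0)  # mV/ms
    floor_i <- if (is.null(slope_floor_mv_per_ms)) {
      6 * max(stats::mad(d, na.rm = TRUE), .quiet_decile_sd(d))
    } else slope_floor_mv_per_ms
    floors[i] <- floor_i
    # strict local minima of the derivative below -floor
    cand <- which(d[2:(n - 1)] < d[1:(n - 2)] & d[2:(n - 1)] <= d[3:n] &
                    d[2:(n - 1)] < -floor_i) + 1L
    if (length(cand) == 0L) {
      lats[[i]] <- numeric(0)
      slopes[[i]] <- numeric(0)
      next
    }
    # greedy by slope magnitude, earlier time wins ties
    ord <- order(d[cand], cand)
    accepted <- numeric(0)
    refr_samp <- refractory_ms / dt_ms
    for (j in ord) {
      cj <- cand[j]
      if (all(abs(accepted - cj) >= refr_samp)) accepted <- c(accepted, cj)
    }
    accepted <- sort(accepted)
    lats[[i]] <- (accepted - 1) * dt_ms
    slopes[[i]] <- d[accepted]
  }
  names(lats) <- colnames(uni)
  names(slopes) <- colnames(uni)
  structure(list(lats = lats, slope_at_lat = slopes,
                 refractory_ms = refractory_ms,
                 slope_floor = floors,
                 sampling_rate_hz = fs),
            class = "lat_series")
}

# derivative noise SD from the quietest decile of short chunks
.quiet_decile_sd <- function(d, n_chunks = 100) {
  n <- length(d)
  chunk <- max(10L, floor(n / n_chunks))
  starts <- seq(1L, n - chunk + 1L, by = chunk)
  rms <- vapply(starts, function(s) stats::sd(d[s:(s + chunk - 1L)]), numeric(1))
  q <- stats::quantile(rms, 0.1, names = FALSE, na.rm = TRUE)
  m <- mean(rms[rms <= q], na.rm = TRUE)
  if (!is.finite(m) || m == 0) m <- 1e-6
  m
}

#' @export
print.lat_series <- function(x, ...) {
  cat("lat_series:", sum(lengths(x$lats)), "activations over",
      sum(lengths(x$lats) > 0), "channels; refractory",
      x$refractory_ms, "ms\n")
  invisible(x)
}

#' Dominant cycle length of an acquisition
#'
#' The prevailing activation period, estimated as the median over electrodes
#' of the per-electrode median inter-activation interval (robust on short
#' fibrillatory windows, unlike a spectral dominant frequency). Electrodes
#' with fewer than 3 activations are excluded.
#'
#' @param lats a `lat_series`
#' @param band_ms physiological plausibility band; values outside raise a
#'   warning (default 100--300 ms)
#' @return a `dominant_cycle_length` object: `value_ms`, `method`,
#'   `per_electrode_ms`
#' @export
dominant_cycle_length <- function(lats, band_ms = c(100, 300)) {
  ok <- lengths(lats$lats) >= 3L
  if (sum(lengths(lats$lats)) < 3L || sum(ok) < 3L) {
    stop("undefined DCL: need >= 3 activations on >= 3 electrodes", call. = FALSE)
  }
  med <- vapply(lats$lats[ok], function(t) stats::median(diff(t)), numeric(1))
  dcl <- stats::median(med)
  if (dcl < band_ms[1] || dcl > band_ms[2]) {
    warning("DCL ", round(dcl, 1), " ms outside the physiological band [",
            band_ms[1], ", ", band_ms[2], "] ms")
  }
  structure(list(value_ms = dcl,
                 method = "median-of-medians",
                 per_electrode_ms = med),
            class = "dominant_cycle_length")
}

#' @export
print.dominant_cycle_length <- function(x, ...) {
  cat("DCL:", round(x$value_ms, 1), "ms (", x$method, ",",
      length(x$per_electrode_ms), "electrodes )\n")
  invisible(x)
}
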