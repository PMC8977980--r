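#' Synthesize unipolar and bipolar electrograms from an activation field
#'
#' Renders each activation of an [simulate_activation_field()] field as a
#' waveform on the corresponding unipolar channel, such that the maximum
#' negative slope of the inserted waveform falls exactly on the generated LAT
#' (the landmark the LAT detector annotates):
#' \describe{
#'   \item{biphasic (RS)}{derivative-of-Gaussian, positive then negative
#'     deflection; steepest downstroke at its center.}
#'   \item{qs}{monophasic negative Gaussian; inserted shifted by one template
#'     sigma so its steepest downstroke, not its trough, lands on the LAT.}
#' }
#' With `template = "qs"` and a focal source in the field, only electrodes
#' within `qs_source_radius_mm` of the source receive the QS morphology;
#' all other electrodes stay biphasic (a focal origin shows QS, surrounding
#' tissue an RS far/near-field mix). Additive white Gaussian noise and
#' bipolar derivation (difference of the two electrodes of each bipole pair)
#' complete the acquisition.
#'
#' Activations closer together than the template support are summed and a
#' warning is raised.
#'
#' @param field an `activation_field`
#' @param geometry the `catheter_geometry` used to generate `field`
#' @param sampling_rate_hz sampling rate; 1000 Hz default (clinical mapping
#'   convention)
#' @param template `"biphasic"` or `"qs"` (see Details)
#' @param amplitude_mv deflection amplitude, mV
#' @param noise_sd_mv additive white-noise SD, mV
#' @param width_ms template support, ms (sigma = width/4)
#' @param qs_source_radius_mm radius around a focal source inside which the
#'   QS template is used when `template = "qs"`
#' @param duration_s window length in seconds; `NULL` fits the field with a
#'   trailing margin. Clinical acquisitions default to 30 s windows.
#' @param map_position 3-D anchor of the acquisition on the atrial shell, mm
#' @param seed integer seed for the noise stream
#' @return an `acquisition` object: `unipolar` (samples x 20 matrix, mV),
#'   `bipolar` (samples x 15), `sampling_rate_hz`, `duration_s`, `geometry`,
#'   `map_position`, `ground_truth` (the field)
#' @export
synthesize_unipolar <- function(field, geometry,
                                sampling_rate_hz = 1000,
                                template = c("biphasic", "qs"),
                                amplitude_mv = 1,
                                noise_sd_mv = 0.02,
                                width_ms = 10,
                                qs_source_radius_mm = 4,
                                duration_s = NULL,
                                map_position = c(0, 0, 0),
                                seed = 1L) {
  template <- match.arg(template)
  if (sampling_rate_hz < 1000) {
    warning("sampling_rate_hz below the recommended 1000 Hz")
  }
  fs <- sampling_rate_hz
  all_lats <- unlist(field$lat_table, use.names = FALSE)
  if (is.null(duration_s)) {
    duration_s <- ceiling((max(all_lats) + 3 * width_ms) / 100) / 10
  }
  n <- round(duration_s * fs)
  sigma_ms <- width_ms / 4
  half_ms <- 3 * sigma_ms
  tt <- seq(-half_ms, half_ms, by = 1000 / fs)  # template time base, ms

  # unit-amplitude templates with max negative slope at t = 0
  w_biphasic <- -(tt / sigma_ms) * exp(-tt^2 / (2 * sigma_ms^2) + 0.5)
  tq <- tt + sigma_ms                            # QS trough sits sigma after LAT
  w_qs <- -exp(-tq^2 / (2 * sigma_ms^2))

  qs_electrodes <- integer(0)
  if (template == "qs") {
    if (!is.null(field$source_position)) {
      d <- sqrt(rowSums(sweep(geometry$electrode_positions, 2,
                              field$source_position)^2))
      qs_electrodes <- which(d <= qs_source_radius_mm)
    } else {
      qs_electrodes <- 1:20
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  uni <- matrix(0, nrow = n, ncol = 20,
                dimnames = list(NULL, rownames(geometry$electrode_positions)))
  overlap_warned <- FALSE
  half_n <- (length(tt) - 1L) / 2
  for (i in 1:20) {
    lats <- field$lat_table[[i]]
    if (length(lats) > 1L && any(diff(lats) < 2 * half_ms) && !overlap_warned) {
      warning("activations closer than the template support; templates summed")
      overlap_warned <- TRUE
    }
    w <- if (i %in% qs_electrodes) w_qs else w_biphasic
    for (lat in lats) {
      c0 <- round(lat * fs / 1000) + 1L            # sample index of the LAT
      idx <- (c0 - half_n):(c0 + half_n)
      keep <- idx >= 1L & idx <= n
      if (any(keep)) {
        uni[idx[keep], i] <- uni[idx[keep], i] + amplitude_mv * w[keep]
      }
    }
  }
  if (noise_sd_mv > 0) {
    uni <- uni + matrix(stats::rnorm(n * 20, 0, noise_sd_mv), nrow = n)
  }

  new_acquisition(uni, geometry, fs,
                  map_position = map_position,
                  ground_truth = field)
}

#' Build an acquisition from a unipolar signal matrix
#'
#' Derives bipolar channels (difference of the two electrodes of each bipole
#' pair) and assembles the acquisition container used by all detectors.
#'
#' @param unipolar samples x 20 numeric matrix, mV
#' @param geometry a `catheter_geometry`
#' @param sampling_rate_hz sampling rate, Hz
#' @param map_position 3-D anchor on the atrial mesh, mm
#' @param ground_truth optional `activation_field`
#' @return an `acquisition` object
#' @export
new_acquisition <- function(unipolar, geometry, sampling_rate_hz,
                            map_position = c(0, 0, 0),
                            ground_truth = NULL) {
  stopifnot(is.matrix(unipolar), ncol(unipolar) == 20L)
  structure(list(
    unipolar = unipolar,
    bipolar = derive_bipolar(unipolar, geometry),
    sampling_rate_hz = sampling_rate_hz,
    duration_s = nrow(unipolar) / sampling_rate_hz,
    geometry = geometry,
    map_position = as.numeric(map_position),
    ground_truth = ground_truth
  ), class = "acquisition")
}

#' Derive bipolar channels from unipolar channels
#'
#' Bipolar electrogram = proximal minus distal unipolar signal of each
#' adjacent-electrode pair, cancelling far-field components.
#'
#' @param unipolar samples x 20 matrix
#' @param geometry a `catheter_geometry`
#' @return samples x 15 matrix named by bipole
#' @export
derive_bipolar <- function(unipolar, geometry) {
  bp <- geometry$bipole_pairs
  out <- unipolar[, bp[, 1L], drop = FALSE] - unipolar[, bp[, 2L], drop = FALSE]
  colnames(out) <- rownames(bp)
  out
}

#' @export
print.acquisition <- function(x, ...) {
  cat("acquisition:", nrow(x$unipolar), "samples @", x$sampling_rate_hz, "Hz (",
      x$duration_s, "s ), 20 unipolar / 15 bipolar channels\n")
  invisible(x)
}

#' Inject continuous low-amplitude activity into selected electrodes
#'
#' Adds a continuous fibrillatory oscillation (dense derivative-of-Gaussian
#' deflections at `cycle_ms` spacing) to the chosen unipolar channels between
#' `start_ms` and `end_ms`, then re-derives the bipolar channels. Emulates the
#' continuous low-amplitude core activity recorded near a rotor center.
#'
#' @param acquisition an `acquisition`
#' @param electrodes integer electrode indices to modify
#' @param start_ms,end_ms interval of continuous activity, ms
#' @param amplitude_mv oscillation amplitude, mV
#' @param cycle_ms deflection spacing, ms
#' @param seed seed for per-deflection timing scatter
#' @return modified `acquisition`
#' @export
inject_continuous_activity <- function(acquisition, electrodes,
                                       start_ms, end_ms,
                                       amplitude_mv = 0.4,
                                       cycle_ms = 12,
                                       seed = 1L) {
  fs <- acquisition$sampling_rate_hz
  n <- nrow(acquisition$unipolar)
  sigma_ms <- cycle_ms / 5
  tt <- seq(-3 * sigma_ms, 3 * sigma_ms, by = 1000 / fs)
  w <- -(tt / sigma_ms) * exp(-tt^2 / (2 * sigma_ms^2) + 0.5)
  half_n <- (length(tt) - 1L) / 2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (e in electrodes) {
    centers <- seq(start_ms, end_ms, by = cycle_ms) +
      stats::rnorm(length(seq(start_ms, end_ms, by = cycle_ms)), 0, cycle_ms / 10)
    for (cm in centers) {
      c0 <- round(cm * fs / 1000) + 1L
      idx <- (c0 - half_n):(c0 + half_n)
      keep <- idx >= 1L & idx <= n
      if (any(keep)) {
        acquisition$unipolar[idx[keep], e] <-
          acquisition$unipolar[idx[keep], e] + amplitude_mv * w[keep]
      }
    }
  }
  acquisition$bipolar <- derive_bipolar(acquisition$unipolar, acquisition$geometry)
  acquisition
}

#' Simulate a single bipolar channel with a known activity duty cycle
#'
#' Generates alternating bursts of fibrillatory activity and electrical
#' silence with the requested duty cycle, together with the ground-truth
#' per-sample activity mask. Used to calibrate and test the electrical-burden
#' scorer.
#'
#' Active and silent segment lengths are exponential with means
#' `duty * segment_scale_ms` and `(1 - duty) * segment_scale_ms`, so the
#' long-run active fraction equals `duty` while both dwell times stay
#' resolvable at the 50-ms analysis frame across the whole duty range.
#'
#' @param duration_s channel length, s
#' @param sampling_rate_hz sampling rate, Hz
#' @param duty fraction of time active, in \[0, 1\]
#' @param segment_scale_ms active + silent mean segment time scale, ms
#' @param amplitude_mv deflection amplitude during activity, mV
#' @param noise_sd_mv baseline noise SD, mV
#' @param cycle_ms deflection spacing inside a burst, ms
#' @param seed integer seed
#' @return list with `signal` (numeric vector, mV), `active_mask` (logical per
#'   sample), `duty` (realized active fraction), `sampling_rate_hz`
#' @export
simulate_burst_channel <- function(duration_s = 10,
                                   sampling_rate_hz = 1000,
                                   duty = 0.3,
                                   segment_scale_ms = 2000,
                                   amplitude_mv = 1,
                                   noise_sd_mv = 0.02,
                                   cycle_ms = 12,
                                   seed = 1L) {
  stopifnot(duty >= 0, duty <= 1)
  fs <- sampling_rate_hz
  n <- round(duration_s * fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  mask <- logical(n)
  if (duty > 0) {
    if (duty >= 1) {
      mask[] <- TRUE
    } else {
      t <- 0
      active <- stats::runif(1) < duty
      active_ms <- duty * segment_scale_ms
      silence_ms <- (1 - duty) * segment_scale_ms
      while (t < n) {
        len_ms <- stats::rexp(1, rate = 1 / (if (active) active_ms else silence_ms))
        len <- max(1L, round(len_ms * fs / 1000))
        idx <- (t + 1L):min(n, t + len)
        mask[idx] <- active
        t <- t + len
        active <- !active
      }
    }
  }

  x <- stats::rnorm(n, 0, noise_sd_mv)
  if (any(mask)) {
    sigma_ms <- cycle_ms / 5
    tt <- seq(-3 * sigma_ms, 3 * sigma_ms, by = 1000 / fs)
    w <- -(tt / sigma_ms) * exp(-tt^2 / (2 * sigma_ms^2) + 0.5)
    half_n <- (length(tt) - 1L) / 2
    step <- max(1L, round(cycle_ms * fs / 1000))
    centers <- which(mask)[c(TRUE, rep(FALSE, step - 1L))]
    for (c0 in centers) {
      idx <- (c0 - half_n):(c0 + half_n)
      keep <- idx >= 1L & idx <= n
      amp <- amplitude_mv * stats::runif(1, 0.7, 1.3)
      x[idx[keep]] <- x[idx[keep]] + amp * w[keep]
    }
  }
  list(signal = x, active_mask = mask, duty = mean(mask),
       sampling_rate_hz = fs)
}
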