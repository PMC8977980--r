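#' Classify the unipolar morphology at a LAT as QS
#'
#' A QS (monophasic negative) unipolar morphology marks the origin of a focal
#' activation: tissue at the source sees only a departing wavefront, so the
#' R (positive) wave disappears. Within a window centered on the LAT the
#' deflection is QS iff the ratio of maximum positive to maximum negative
#' excursion is below `rs_ratio_threshold` (strict) and the negative
#' excursion clears the channel noise floor.
#'
#' @param unipolar_channel numeric vector, mV
#' @param lat_ms activation time, ms
#' @param sampling_rate_hz sampling rate, Hz
#' @param morphology_window_ms analysis window centered on the LAT (default 40)
#' @param rs_ratio_threshold R/S excursion ratio bound (default 0.15, strict
#'   inequality)
#' @param noise_sd_mv channel noise SD; `NULL` estimates it from the quietest
#'   decile of the channel
#' @return logical; attribute `truncated = TRUE` when the window was cut by a
#'   recording edge
#' @export
classify_qs <- function(unipolar_channel, lat_ms, sampling_rate_hz,
                        morphology_window_ms = 40,
                        rs_ratio_threshold = 0.15,
                        noise_sd_mv = NULL) {
  fs <- sampling_rate_hz
  n <- length(unipolar_channel)
  c0 <- round(lat_ms * fs / 1000) + 1L
  if (c0 < 1L || c0 > n) stop("lat outside the recording", call. = FALSE)
  half <- round(morphology_window_ms / 2 * fs / 1000)
  idx <- (c0 - half):(c0 + half)
  truncated <- any(idx < 1L | idx > n)
  idx <- idx[idx >= 1L & idx <= n]
  x <- unipolar_channel[idx]
  if (is.null(noise_sd_mv)) {
    noise_sd_mv <- .channel_noise_sd(unipolar_channel)
  }
  max_pos <- max(c(x, 0))
  max_neg <- -min(c(x, 0))
  out <- (max_neg > 4 * noise_sd_mv) &&
    (max_pos / max_neg < rs_ratio_threshold)
  if (truncated) attr(out, "truncated") <- TRUE
  out
}

# robust amplitude noise floor: mean SD of the quietest decile of short chunks
.channel_noise_sd <- function(x, n_chunks = 100) {
  n <- length(x)
  chunk <- max(10L, floor(n / n_chunks))
  starts <- seq(1L, n - chunk + 1L, by = chunk)
  rms <- vapply(starts, function(s) stats::sd(x[s:(s + chunk - 1L)]), numeric(1))
  q <- stats::quantile(rms, 0.1, names = FALSE, na.rm = TRUE)
  m <- mean(rms[rms <= q], na.rm = TRUE)
  if (!is.finite(m) || m == 0) m <- 1e-9
  m
}

#' Detect repetitive focal-activity (FAc) events
#'
#' Per beat (beat grid derived from the dominant cycle length), QS-classified
#' activations are screened with the earliest-origin rule: a QS activation is
#' an origin candidate iff no other QS activation within `radius_mm` has its
#' LAT in the `precede_window_ms` before it. Chains of origin candidates on
#' consecutive beats (per-beat origin drift up to `radius_mm`; a missed
#' intermediate beat breaks the chain) of length at least `min_beats` become
#' FAc events.
#'
#' @param acquisition an `acquisition`
#' @param lats `lat_series`
#' @param dcl optional `dominant_cycle_length`; computed from `lats` if `NULL`
#' @param radius_mm spatial radius of the earliest-origin rule (default 10)
#' @param precede_window_ms temporal window of the rule (default 50)
#' @param min_beats minimum consecutive beats (default 2)
#' @param rs_ratio_threshold passed to [classify_qs()]
#' @param acquisition_id identifier carried into the events
#' @return data.frame of class `fac_events`: `origin_electrode`, `n_beats`,
#'   `first_beat_ms`, `last_beat_ms`, `duration_ms`, `beat_times_ms` (list),
#'   `acquisition_id`, `map_x/map_y/map_z` (origin electrode position offset
#'   by the acquisition anchor)
#' @export
detect_fac <- function(acquisition, lats, dcl = NULL,
                       radius_mm = 10, precede_window_ms = 50,
                       min_beats = 2L, rs_ratio_threshold = 0.15,
                       acquisition_id = "acq1") {
  fs <- acquisition$sampling_rate_hz
  geometry <- acquisition$geometry
  if (is.null(dcl)) dcl <- dominant_cycle_length(lats)
  dcl_ms <- dcl$value_ms

  # all QS-classified activations
  qs <- list()
  for (e in 1:20) {
    noise_e <- .channel_noise_sd(acquisition$unipolar[, e])
    for (t in lats$lats[[e]]) {
      if (isTRUE(as.logical(classify_qs(acquisition$unipolar[, e], t, fs,
                                        rs_ratio_threshold = rs_ratio_threshold,
                                        noise_sd_mv = noise_e)))) {
        qs[[length(qs) + 1L]] <- c(electrode = e, lat = t)
      }
    }
  }
  empty <- .empty_fac_events()
  if (length(qs) == 0L) return(empty)
  qs <- as.data.frame(do.call(rbind, qs))
  pos <- geometry$electrode_positions
  dmat <- as.matrix(stats::dist(pos))

  # earliest-origin rule
  is_origin <- logical(nrow(qs))
  for (i in seq_len(nrow(qs))) {
    near <- dmat[qs$electrode[i], qs$electrode] <= radius_mm
    preceding <- qs$lat >= qs$lat[i] - precede_window_ms & qs$lat < qs$lat[i]
    is_origin[i] <- !any(near & preceding & seq_len(nrow(qs)) != i)
  }
  org <- qs[is_origin, , drop = FALSE]
  if (nrow(org) == 0L) return(empty)
  org$beat <- round((org$lat - min(org$lat)) / dcl_ms)
  # one origin per focal source and beat: among co-located candidates of the
  # same beat keep the earliest (ties: lowest electrode index)
  org <- org[order(org$beat, org$lat, org$electrode), , drop = FALSE]
  keep <- rep(TRUE, nrow(org))
  for (i in seq_len(nrow(org))) {
    if (!keep[i]) next
    dup <- keep & org$beat == org$beat[i] &
      dmat[org$electrode[i], org$electrode] <= radius_mm &
      seq_len(nrow(org)) > i
    keep[dup] <- FALSE
  }
  org <- org[keep, , drop = FALSE]

  # chain origin candidates across consecutive beats, drift <= radius_mm
  chains <- list()   # each: electrodes, lats, last_beat
  closed <- list()
  for (b in sort(unique(org$beat))) {
    cand <- org[org$beat == b, , drop = FALSE]
    open_now <- vapply(chains, function(ch) ch$last_beat == b - 1L, logical(1))
    used <- logical(nrow(cand))
    if (any(open_now)) {
      for (ci in which(open_now)) {
        last_e <- chains[[ci]]$electrodes[length(chains[[ci]]$electrodes)]
        dists <- dmat[last_e, cand$electrode]
        dists[used] <- Inf
        j <- which.min(dists)
        if (length(j) && is.finite(dists[j]) && dists[j] <= radius_mm) {
          chains[[ci]]$electrodes <- c(chains[[ci]]$electrodes, cand$electrode[j])
          chains[[ci]]$lats <- c(chains[[ci]]$lats, cand$lat[j])
          chains[[ci]]$last_beat <- b
          used[j] <- TRUE
        }
      }
    }
    # close chains not extended at this beat
    done <- vapply(chains, function(ch) ch$last_beat < b, logical(1))
    closed <- c(closed, chains[done])
    chains <- chains[!done]
    for (j in which(!used)) {
      chains[[length(chains) + 1L]] <- list(electrodes = cand$electrode[j],
                                            lats = cand$lat[j], last_beat = b)
    }
  }
  closed <- c(closed, chains)
  closed <- closed[vapply(closed, function(ch)
    length(ch$lats) >= min_beats, logical(1))]
  if (length(closed) == 0L) return(empty)

  rows <- lapply(closed, function(ch) {
    tab <- table(ch$electrodes)
    origin <- as.integer(names(tab)[which.max(tab)])
    data.frame(origin_electrode = origin,
               n_beats = length(ch$lats),
               first_beat_ms = min(ch$lats),
               last_beat_ms = max(ch$lats),
               duration_ms = max(ch$lats) - min(ch$lats),
               acquisition_id = acquisition_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$beat_times_ms <- I(lapply(closed, function(ch) sort(ch$lats)))
  # site position = mean of the per-beat origin positions: with jitter of
  # the order of the conduction delay across the grid, a single beat's
  # earliest electrode is noisy but the average converges on the source
  opos <- t(vapply(closed, function(ch)
    colMeans(pos[ch$electrodes, , drop = FALSE]), numeric(3)))
  out$map_x <- acquisition$map_position[1L] + opos[, 1L]
  out$map_y <- acquisition$map_position[2L] + opos[, 2L]
  out$map_z <- acquisition$map_position[3L] + opos[, 3L]
  class(out) <- c("fac_events", "data.frame")
  out
}

.empty_fac_events <- function() {
  out <- data.frame(origin_electrode = integer(0), n_beats = integer(0),
                    first_beat_ms = numeric(0), last_beat_ms = numeric(0),
                    duration_ms = numeric(0), acquisition_id = character(0),
                    stringsAsFactors = FALSE)
  out$beat_times_ms <- I(list())
  out$map_x <- numeric(0); out$map_y <- numeric(0); out$map_z <- numeric(0)
  class(out) <- c("fac_events", "data.frame")
  out
}

#' Per-patient focal-activity summary
#'
#' @param events a `fac_events` data.frame
#' @param n_acquisitions total accepted acquisitions for the patient
#' @param dcl_ms optional DCL values of acquisitions with FAc
#' @param site_radius_mm site clustering radius (default 10)
#' @return list `has_fac`, `n_sites`, `n_events`, `events_per_acquisition`,
#'   `mean_event_duration_ms`, `total_event_duration_per_acquisition_ms`,
#'   `dominant_cycle_length_for_fac_acquisitions_ms`
#' @export
summarize_fac <- function(events, n_acquisitions = 1L, dcl_ms = NULL,
                          site_radius_mm = 10) {
  if (nrow(events) == 0L) {
    return(list(has_fac = FALSE, n_sites = 0L, n_events = 0L,
                events_per_acquisition = 0,
                mean_event_duration_ms = NA_real_,
                total_event_duration_per_acquisition_ms = NA_real_,
                dominant_cycle_length_for_fac_acquisitions_ms = NA_real_))
  }
  pos <- as.matrix(events[, c("map_x", "map_y", "map_z")])
  n_fac_acq <- length(unique(events$acquisition_id))
  list(
    has_fac = TRUE,
    n_sites = cluster_sites(pos, radius_mm = site_radius_mm),
    n_events = nrow(events),
    events_per_acquisition = nrow(events) / n_acquisitions,
    mean_event_duration_ms = mean(events$duration_ms),
    total_event_duration_per_acquisition_ms = sum(events$duration_ms) / n_fac_acq,
    dominant_cycle_length_for_fac_acquisitions_ms =
      if (is.null(dcl_ms)) NA_real_ else mean(dcl_ms)
  )
}
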