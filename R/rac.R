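#' Rotation span and staircase test for one concentric ring in one beat
#'
#' Orders the ring's five electrodes by azimuth, picks for each electrode the
#' LAT nearest the beat-window center (undefined if an electrode has no LAT
#' inside the window), and evaluates the rotational signature: a "staircase"
#' is a strictly monotone LAT sequence in circular electrode order, modulo a
#' single wrap-around step. The span fraction is the LAT range divided by the
#' dominant cycle length; a full rotor sampled by 5 electrodes spans 4/5 of
#' the cycle.
#'
#' @param lats a `lat_series`
#' @param geometry the `catheter_geometry`
#' @param ring ring index 1..4
#' @param beat_window numeric(2), window (ms) containing the beat
#' @param dcl_ms dominant cycle length, ms
#' @return list `span_fraction`, `chirality` (+1 LAT increasing with azimuth,
#'   -1 decreasing, NA if not staircase), `is_staircase`, `ring_lats`
#'   (azimuth-ordered representative LATs), or `NULL` if any ring electrode
#'   lacks a LAT in the window
#' @export
ring_rotation_span <- function(lats, geometry, ring, beat_window, dcl_ms) {
  el <- ring_electrodes(geometry, ring)
  center <- mean(beat_window)
  x <- numeric(length(el))
  for (j in seq_along(el)) {
    t <- lats$lats[[el[j]]]
    t <- t[t >= beat_window[1] & t <= beat_window[2]]
    if (length(t) == 0L) return(NULL)
    x[j] <- t[which.min(abs(t - center))]
  }
  steps <- diff(c(x, x[1L]))          # circular steps in azimuth order
  n_pos <- sum(steps > 0)
  n_neg <- sum(steps < 0)
  is_staircase <- (n_pos + n_neg == length(x)) &&
    (n_neg == 1L || n_pos == 1L)
  chirality <- if (!is_staircase) NA_integer_ else if (n_neg == 1L) 1L else -1L
  list(span_fraction = (max(x) - min(x)) / dcl_ms,
       chirality = chirality,
       is_staircase = is_staircase,
       ring_lats = x)
}

#' Detect rotational-activity (RAc) events
#'
#' Slides beat-by-beat over the acquisition (beats anchored on the
#' external-ring electrode with the most activations). A rotation qualifies
#' when at least `rings_required` concentric rings simultaneously show a
#' staircase activation sequence with identical chirality whose LAT span
#' exceeds `span_threshold` of the dominant cycle length. Maximal runs of at
#' least `min_rotations` consecutive qualifying rotations with constant
#' chirality become RAc events; event boundaries run from the first LAT of
#' the first qualifying rotation to the last LAT of the last.
#'
#' @param acquisition an `acquisition`
#' @param lats `lat_series` from [detect_lats()]
#' @param dcl `dominant_cycle_length` from [dominant_cycle_length()]
#' @param min_rotations minimum consecutive qualifying rotations (default 2)
#' @param span_threshold minimum span as fraction of the DCL (default 0.5)
#' @param rings_required number of rings that must satisfy the rule (default
#'   4, the strict reading; lower for sensitivity analyses)
#' @param acquisition_id identifier carried into the events
#' @return data.frame of class `rac_events`, one row per event: `start_ms`,
#'   `end_ms`, `duration_ms`, `n_rotations`, `chirality`, `rings_satisfying`
#'   (list), `span_fraction_per_rotation` (list), `acquisition_id`, and
#'   `map_x/map_y/map_z`
#' @export
detect_rac <- function(acquisition, lats, dcl,
                       min_rotations = 2L,
                       span_threshold = 0.5,
                       rings_required = 4L,
                       acquisition_id = "acq1") {
  dcl_ms <- dcl$value_ms
  geometry <- acquisition$geometry
  ring1 <- ring_electrodes(geometry, 1L)
  anchor <- ring1[which.max(lengths(lats$lats[ring1]))]
  anchors <- lats$lats[[anchor]]
  empty <- .empty_rac_events()
  if (length(anchors) == 0L) return(empty)

  per_beat <- vector("list", length(anchors))
  for (k in seq_along(anchors)) {
    win <- anchors[k] + c(-1, 1) * dcl_ms
    rings <- lapply(1:4, function(r)
      ring_rotation_span(lats, geometry, r, win, dcl_ms))
    ok <- vapply(rings, function(ri) {
      !is.null(ri) && ri$is_staircase && ri$span_fraction > span_threshold
    }, logical(1))
    chir <- vapply(rings, function(ri)
      if (is.null(ri)) NA_integer_ else ri$chirality, integer(1))
    qual_rings <- which(ok)
    # all qualifying rings must share one chirality
    if (length(qual_rings) >= rings_required &&
        length(unique(chir[qual_rings])) == 1L) {
      used <- unlist(lapply(rings[qual_rings], `[[`, "ring_lats"))
      per_beat[[k]] <- list(qualifies = TRUE,
                            chirality = chir[qual_rings][1L],
                            rings = qual_rings,
                            span = mean(vapply(rings[qual_rings],
                                               `[[`, numeric(1), "span_fraction")),
                            lat_min = min(used), lat_max = max(used))
    } else {
      per_beat[[k]] <- list(qualifies = FALSE)
    }
  }

  q <- vapply(per_beat, `[[`, logical(1), "qualifies")
  ch <- vapply(per_beat, function(b)
    if (b$qualifies) b$chirality else NA_integer_, integer(1))
  # runs of consecutive qualifying beats with constant chirality
  run_id <- cumsum(c(TRUE, !(q[-1] & q[-length(q)] &
                               ch[-1] == ch[-length(ch)] &
                               !is.na(ch[-1]) & !is.na(ch[-length(ch)]))))
  events <- list()
  for (rid in unique(run_id)) {
    idx <- which(run_id == rid)
    idx <- idx[q[idx]]
    if (length(idx) >= min_rotations) {
      beats <- per_beat[idx]
      events[[length(events) + 1L]] <- data.frame(
        start_ms = beats[[1L]]$lat_min,
        end_ms = beats[[length(beats)]]$lat_max,
        n_rotations = length(idx),
        chirality = beats[[1L]]$chirality,
        acquisition_id = acquisition_id,
        stringsAsFactors = FALSE
      )
      attr(events[[length(events)]], "rings") <-
        Reduce(intersect, lapply(beats, `[[`, "rings"))
      attr(events[[length(events)]], "spans") <-
        vapply(beats, `[[`, numeric(1), "span")
    }
  }
  if (length(events) == 0L) return(empty)
  out <- do.call(rbind, events)
  out$duration_ms <- out$end_ms - out$start_ms
  out$rings_satisfying <- I(lapply(events, attr, "rings"))
  out$span_fraction_per_rotation <- I(lapply(events, attr, "spans"))
  out$map_x <- acquisition$map_position[1L]
  out$map_y <- acquisition$map_position[2L]
  out$map_z <- acquisition$map_position[3L]
  class(out) <- c("rac_events", "data.frame")
  out
}

.empty_rac_events <- function() {
  out <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                    n_rotations = integer(0), chirality = integer(0),
                    acquisition_id = character(0),
                    duration_ms = numeric(0), stringsAsFactors = FALSE)
  out$rings_satisfying <- I(list())
  out$span_fraction_per_rotation <- I(list())
  out$map_x <- numeric(0); out$map_y <- numeric(0); out$map_z <- numeric(0)
  class(out) <- c("rac_events", "data.frame")
  out
}

#' Automated surrogate of expert RAc confirmation
#'
#' The clinical rule confirms a detected rotational event only when it shows
#' more than 2 rotations with a staircase sequence together with acceleration
#' of discrete electrograms and the appearance of continuous activity at the
#' rotor core. The surrogate implemented here confirms an event iff
#' `n_rotations > 2` and, on at least one internal-ring bipole, the
#' electrical-burden score inside the event interval exceeds the score
#' outside the event by `margin`.
#'
#' @param event one row of a `rac_events` data.frame
#' @param acquisition the `acquisition` the event was detected in
#' @param margin required inside-minus-outside burden contrast (default 0.15)
#' @param burden_fn function(channel, sampling_rate_hz) returning a list with
#'   `active` (logical per frame) and `center_ms` (frame centers); the default
#'   uses [extract_activity_features()] + [fit_burden_hmm()]
#' @return logical; `NA` with attribute `flag = "unconfirmed"` when the burden
#'   score is unavailable
#' @export
confirm_rac <- function(event, acquisition, margin = 0.15, burden_fn = NULL) {
  if (event$n_rotations <= 2L) return(FALSE)
  if (is.null(burden_fn)) {
    burden_fn <- function(channel, fs) {
      feats <- extract_activity_features(channel, sampling_rate_hz = fs)
      res <- fit_burden_hmm(feats, seed = 1L)
      list(active = res$state_path == "active", center_ms = feats$center_ms)
    }
  }
  inner <- which(acquisition$geometry$bipole_ring == 3L)
  contrast <- rep(NA_real_, length(inner))
  for (j in seq_along(inner)) {
    res <- tryCatch(
      burden_fn(acquisition$bipolar[, inner[j]], acquisition$sampling_rate_hz),
      error = function(e) NULL)
    if (is.null(res)) next
    inside <- res$center_ms >= event$start_ms & res$center_ms <= event$end_ms
    if (any(inside) && any(!inside)) {
      contrast[j] <- mean(res$active[inside]) - mean(res$active[!inside])
    }
  }
  if (all(is.na(contrast))) {
    return(structure(NA, flag = "unconfirmed"))
  }
  any(contrast > margin, na.rm = TRUE)
}

#' Per-patient rotational-activity summary
#'
#' Clusters event positions into sites (single-linkage clustering cut at
#' `site_radius_mm`) and computes the per-patient summary statistics used in
#' driver-mapping cohort tables.
#'
#' @param events a `rac_events` data.frame (possibly from several
#'   acquisitions of one patient)
#' @param n_acquisitions total accepted acquisitions for the patient
#' @param dcl_ms optional named numeric: DCL per acquisition with RAc
#' @param site_radius_mm site clustering radius (default 10)
#' @return list `has_rac`, `n_sites`, `n_events`, `events_per_acquisition`,
#'   `mean_event_duration_ms`, `total_event_duration_per_acquisition_ms`,
#'   `dominant_cycle_length_for_rac_acquisitions_ms`
#' @export
summarize_rac <- function(events, n_acquisitions = 1L, dcl_ms = NULL,
                          site_radius_mm = 10) {
  if (nrow(events) == 0L) {
    return(list(has_rac = FALSE, n_sites = 0L, n_events = 0L,
                events_per_acquisition = 0,
                mean_event_duration_ms = NA_real_,
                total_event_duration_per_acquisition_ms = NA_real_,
                dominant_cycle_length_for_rac_acquisitions_ms = NA_real_))
  }
  pos <- as.matrix(events[, c("map_x", "map_y", "map_z")])
  n_sites <- cluster_sites(pos, radius_mm = site_radius_mm)
  n_rac_acq <- length(unique(events$acquisition_id))
  list(
    has_rac = TRUE,
    n_sites = n_sites,
    n_events = nrow(events),
    events_per_acquisition = nrow(events) / n_acquisitions,
    mean_event_duration_ms = mean(events$duration_ms),
    total_event_duration_per_acquisition_ms = sum(events$duration_ms) / n_rac_acq,
    dominant_cycle_length_for_rac_acquisitions_ms =
      if (is.null(dcl_ms)) NA_real_ else mean(dcl_ms)
  )
}

#' Count spatial sites by single-linkage clustering
#'
#' @param positions n x 3 matrix of event positions, mm
#' @param radius_mm linkage cut height
#' @return integer number of clusters
#' @export
cluster_sites <- function(positions, radius_mm = 10) {
  n <- nrow(positions)
  if (n <= 1L) return(n)
  hc <- stats::hclust(stats::dist(positions), method = "single")
  length(unique(stats::cutree(hc, h = radius_mm)))
}
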