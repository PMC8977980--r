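#' Simulate a ground-truth activation-time field over a catheter
#'
#' Generates per-electrode local activation times (LATs) for one of three
#' activation regimes observed during atrial fibrillation mapping:
#' \describe{
#'   \item{planar}{a plane wave: `LAT_i = t0 + k*CL + (x_i . d) / v` for beat
#'     `k`, unit direction `d` and conduction velocity `v`.}
#'   \item{focal}{a centrifugal source: `LAT_i = t0 + k*CL + |x_i - s| / v`
#'     with source position `s`.}
#'   \item{rotational}{a rotor about `source_position`:
#'     `LAT_i = t0 + k*CL + chirality * theta_i * CL / (2*pi)` where `theta_i`
#'     is the electrode azimuth about the rotation center, so one rotation's
#'     staircase expands the full cycle.}
#' }
#' Independent zero-mean Gaussian jitter (`jitter_sd_ms`) is added per beat
#' and electrode; times are then forced to respect a refractory floor.
#'
#' @param geometry a [make_catheter_geometry()] object
#' @param pattern `"planar"`, `"rotational"` or `"focal"`
#' @param cycle_length_ms base activation period (> 0), ms
#' @param n_beats number of beats/rotations (>= 1)
#' @param source_position numeric(3) rotor center / focal source, mm; required
#'   for rotational and focal patterns
#' @param direction numeric(3) propagation direction for planar fields
#' @param chirality +1 or -1 rotation sense (rotational only)
#' @param jitter_sd_ms per-beat timing jitter SD, ms
#' @param conduction_velocity_mm_per_ms conduction velocity (> 0)
#' @param t0_ms time of the first activation reference, ms
#' @param refractory_floor_ms minimum same-electrode interval enforced after
#'   jitter, ms
#' @param seed integer seed; identical seeds give identical fields
#' @return an `activation_field` object with `lat_table` (list of sorted
#'   per-electrode activation times, ms) and the generating parameters
#' @export
simulate_activation_field <- function(geometry,
                                      pattern = c("planar", "rotational", "focal"),
                                      cycle_length_ms = 170,
                                      n_beats = 10,
                                      source_position = NULL,
                                      direction = c(1, 0, 0),
                                      chirality = 1L,
                                      jitter_sd_ms = 0,
                                      conduction_velocity_mm_per_ms = 1,
                                      t0_ms = 60,
                                      refractory_floor_ms = 80,
                                      seed = 1L) {
  pattern <- match.arg(pattern)
  if (cycle_length_ms <= 0) stop("cycle_length_ms must be > 0", call. = FALSE)
  if (n_beats < 1) stop("n_beats must be >= 1", call. = FALSE)
  if (conduction_velocity_mm_per_ms <= 0) stop("velocity must be > 0", call. = FALSE)
  if (pattern %in% c("rotational", "focal") && is.null(source_position)) {
    stop("missing source: ", pattern, " pattern requires source_position", call. = FALSE)
  }
  if (!chirality %in% c(-1L, 1L)) stop("chirality must be +1 or -1", call. = FALSE)

  pos <- geometry$electrode_positions
  v <- conduction_velocity_mm_per_ms
  phase <- switch(pattern,
    planar = {
      d <- direction / sqrt(sum(direction^2))
      as.vector(pos %*% d) / v
    },
    focal = {
      s <- as.numeric(source_position)
      sqrt(rowSums(sweep(pos, 2, s)^2)) / v
    },
    rotational = {
      s <- as.numeric(source_position)
      theta <- atan2(pos[, 2] - s[2], pos[, 1] - s[1]) %% (2 * pi)
      chirality * theta * cycle_length_ms / (2 * pi)
    })
  # anchor so that the earliest electrode of beat 0 activates at t0
  phase <- phase - min(phase)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lat_table <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    k <- 0:(n_beats - 1L)
    lats <- t0_ms + k * cycle_length_ms + phase[i] +
      if (jitter_sd_ms > 0) stats::rnorm(n_beats, 0, jitter_sd_ms) else 0
    lats <- sort(lats)
    # enforce the refractory floor: push violating beats forward
    if (n_beats > 1L) {
      for (b in 2:n_beats) {
        lats[b] <- max(lats[b], lats[b - 1L] + refractory_floor_ms)
      }
    }
    lat_table[[i]] <- lats
  }
  names(lat_table) <- rownames(pos)

  structure(list(
    pattern = pattern,
    cycle_length_ms = cycle_length_ms,
    n_beats = n_beats,
    lat_table = lat_table,
    source_position = if (!is.null(source_position)) as.numeric(source_position),
    chirality = if (pattern == "rotational") as.integer(chirality),
    jitter_sd_ms = jitter_sd_ms,
    conduction_velocity_mm_per_ms = v,
    t0_ms = t0_ms,
    refractory_floor_ms = refractory_floor_ms,
    seed = seed
  ), class = "activation_field")
}

#' @export
print.activation_field <- function(x, ...) {
  cat("activation_field:", x$pattern, "CL", x$cycle_length_ms, "ms,",
      x$n_beats, "beats, jitter SD", x$jitter_sd_ms, "ms\n")
  invisible(x)
}

# save/restore .Random.seed so generators don't disturb the caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
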