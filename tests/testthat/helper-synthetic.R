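# shared fixture builders: short acquisitions keep unit tests fast; the
# acceptance suite scales the same builders up

default_geometry <- function() make_catheter_geometry()

rotor_acquisition <- function(seed = 1L, n_beats = 5L, cycle_length_ms = 170,
                              jitter_sd_ms = 0, chirality = 1L,
                              duration_s = NULL, noise_sd_mv = 0.02,
                              geometry = default_geometry()) {
  f <- simulate_activation_field(
    geometry, "rotational", cycle_length_ms = cycle_length_ms,
    n_beats = n_beats, source_position = c(0, 0, 0),
    chirality = chirality, jitter_sd_ms = jitter_sd_ms, seed = seed)
  synthesize_unipolar(f, geometry, duration_s = duration_s,
                      noise_sd_mv = noise_sd_mv, seed = seed + 10000L)
}

planar_acquisition <- function(seed = 1L, n_beats = 5L, cycle_length_ms = 170,
                               jitter_sd_ms = 0, direction = c(1, 0.3, 0),
                               noise_sd_mv = 0.02,
                               geometry = default_geometry()) {
  f <- simulate_activation_field(
    geometry, "planar", cycle_length_ms = cycle_length_ms,
    n_beats = n_beats, direction = direction,
    jitter_sd_ms = jitter_sd_ms, seed = seed)
  synthesize_unipolar(f, geometry, noise_sd_mv = noise_sd_mv,
                      seed = seed + 10000L)
}

focal_acquisition <- function(seed = 1L, n_beats = 5L, cycle_length_ms = 170,
                              source_position = c(0, 0, 0),
                              jitter_sd_ms = 0, noise_sd_mv = 0.02,
                              geometry = default_geometry()) {
  f <- simulate_activation_field(
    geometry, "focal", cycle_length_ms = cycle_length_ms,
    n_beats = n_beats, source_position = source_position,
    jitter_sd_ms = jitter_sd_ms, seed = seed)
  synthesize_unipolar(f, geometry, template = "qs",
                      noise_sd_mv = noise_sd_mv, seed = seed + 10000L)
}

detect_chain <- function(acquisition, ...) {
  lats <- detect_lats(acquisition)
  dcl <- suppressWarnings(dominant_cycle_length(lats))
  detect_rac(acquisition, lats, dcl, ...)
}

# brute-force staircase oracle: try all 5 circular starts x 2 directions
staircase_oracle <- function(x) {
  n <- length(x)
  for (dir in list(seq_len(n), rev(seq_len(n)))) {
    for (s in 0:(n - 1L)) {
      seqv <- x[dir][((seq_len(n) - 1L + s) %% n) + 1L]
      if (all(diff(seqv) > 0)) return(TRUE)
    }
  }
  FALSE
}
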