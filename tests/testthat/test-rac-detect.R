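test_that("ring rotation span matches the rotor construction", {
  geo <- default_geometry()
  a <- rotor_acquisition(seed = 1, n_beats = 4, jitter_sd_ms = 0)
  lats <- detect_lats(a)
  dcl <- dominant_cycle_length(lats)
  win <- lats$lats[[1]][2] + c(-1, 1) * dcl$value_ms
  for (r in 1:4) {
    rs <- ring_rotation_span(lats, geo, r, win, dcl$value_ms)
    expect_true(rs$is_staircase)
    expect_equal(rs$span_fraction, 0.8, tolerance = 0.02)
    expect_equal(rs$chirality, 1L)
  }
})

test_that("simultaneous activation of a ring is not a staircase", {
  geo <- default_geometry()
  lats <- structure(list(lats = rep(list(100), 20)), class = "lat_series")
  rs <- ring_rotation_span(lats, geo, 1L, c(0, 200), 170)
  expect_equal(rs$span_fraction, 0)
  expect_false(rs$is_staircase)
  # a ring electrode without a LAT in the window -> undefined
  lats2 <- structure(list(lats = c(list(numeric(0)), rep(list(100), 19))),
                     class = "lat_series")
  expect_null(ring_rotation_span(lats2, geo, 1L, c(0, 200), 170))
})

test_that("staircase detection agrees with the exhaustive circular oracle", {
  geo <- default_geometry()
  set.seed(99)
  for (i in 1:200) {
    vals <- sample(seq(10, 150, by = 10), 5)
    lats <- structure(list(
      lats = lapply(1:20, function(e) {
        if (geo$ring_index[e] == 1L) {
          vals[which(ring_electrodes(geo, 1L) == e)]
        } else numeric(0)
      })), class = "lat_series")
    rs <- ring_rotation_span(lats, geo, 1L, c(0, 200), 170)
    expect_equal(rs$is_staircase, staircase_oracle(rs$ring_lats),
                 info = paste(vals, collapse = ","))
  }
})

test_that("rotors produce one event with the generated rotation count", {
  ev <- detect_chain(rotor_acquisition(seed = 3, n_beats = 3))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_rotations, 3L)
  expect_equal(ev$chirality, 1L)
  # 3 rotations at CL 170: two full cycles plus the ring span
  expect_gte(ev$duration_ms, 340)
  expect_lte(ev$duration_ms, 510)

  ev2 <- detect_chain(rotor_acquisition(seed = 4, n_beats = 6, chirality = -1L))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$n_rotations, 6L)
  expect_equal(ev2$chirality, -1L)
})

test_that("planar and focal activations yield no rotational events", {
  expect_equal(nrow(detect_chain(planar_acquisition(seed = 5))), 0L)
  a <- focal_acquisition(seed = 6)
  lats <- detect_lats(a)
  dcl <- dominant_cycle_length(lats)
  expect_equal(nrow(detect_rac(a, lats, dcl)), 0L)
})

test_that("a single rotation stays below the repetition threshold", {
  # one rotor beat then planar continuation
  geo <- default_geometry()
  fr <- simulate_activation_field(geo, "rotational", n_beats = 1,
                                  source_position = c(0, 0, 0), seed = 7)
  fp <- simulate_activation_field(geo, "planar", n_beats = 4, t0_ms = 300,
                                  seed = 7)
  f <- fr
  f$lat_table <- Map(function(a, b) sort(c(a, b)), fr$lat_table, fp$lat_table)
  f$n_beats <- 5L
  a <- synthesize_unipolar(f, geo, duration_s = 1.2, seed = 8)
  ev <- detect_chain(a)
  expect_equal(nrow(ev), 0L)
})

test_that("event counts are monotone in the detection thresholds", {
  a <- rotor_acquisition(seed = 9, n_beats = 8, jitter_sd_ms = 4)
  lats <- detect_lats(a)
  dcl <- dominant_cycle_length(lats)
  n_ev <- function(...) {
    ev <- detect_rac(a, lats, dcl, ...)
    if (nrow(ev)) sum(ev$n_rotations) else 0L
  }
  expect_gte(n_ev(span_threshold = 0.5), n_ev(span_threshold = 0.7))
  expect_gte(n_ev(span_threshold = 0.7), n_ev(span_threshold = 0.95))
  expect_gte(n_ev(min_rotations = 2), n_ev(min_rotations = 5))
  expect_gte(n_ev(rings_required = 2), n_ev(rings_required = 4))
})

test_that("the confirmation surrogate requires >2 rotations and burden contrast", {
  a <- rotor_acquisition(seed = 11, n_beats = 3, duration_s = 4)
  ev <- detect_chain(a)
  expect_equal(nrow(ev), 1L)
  ev2 <- ev[1, ]; ev2$n_rotations <- 2L
  expect_false(confirm_rac(ev2, a))

  # continuous low-amplitude core activity inside the event -> confirmed
  inner <- which(a$geometry$ring_index >= 3L)
  a_act <- inject_continuous_activity(a, inner, ev$start_ms, ev$end_ms,
                                      amplitude_mv = 0.5, seed = 12)
  expect_true(confirm_rac(ev[1, ], a_act))
  # uniform burden (no contrast) -> not confirmed
  expect_false(isTRUE(confirm_rac(ev[1, ], a)))
  # unavailable burden passes through flagged
  failing <- function(channel, fs) stop("no burden")
  res <- confirm_rac(ev[1, ], a, burden_fn = failing)
  expect_true(is.na(res))
  expect_equal(attr(res, "flag"), "unconfirmed")
})

test_that("per-patient summaries count events and cluster sites", {
  empty <- summarize_rac(detect_chain(planar_acquisition(seed = 13)))
  expect_false(empty$has_rac)
  expect_equal(empty$n_sites, 0L)
  expect_equal(empty$n_events, 0L)

  ev <- detect_chain(rotor_acquisition(seed = 14, n_beats = 3))
  three <- do.call(rbind, list(ev, ev, ev))
  s <- summarize_rac(three, n_acquisitions = 2L)
  expect_true(s$has_rac)
  expect_equal(s$n_sites, 1L)
  expect_equal(s$n_events, 3L)
  expect_equal(s$events_per_acquisition, 1.5)
  expect_equal(s$mean_event_duration_ms, ev$duration_ms)

  # two positions 25 mm apart: single-linkage oracle at 10 mm gives 2 sites
  far <- ev; far$map_x <- far$map_x + 25
  two <- rbind(ev, far)
  pos <- as.matrix(two[, c("map_x", "map_y", "map_z")])
  oracle <- length(unique(cutree(hclust(dist(pos), "single"), h = 10)))
  s2 <- summarize_rac(two, n_acquisitions = 2L)
  expect_equal(s2$n_sites, oracle)
  expect_equal(s2$n_sites, 2L)
})
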