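test_that("QS classification uses the strict R/S excursion ratio", {
  fs <- 1000
  tt <- seq(-20, 20, by = 1)
  qs <- -exp(-tt^2 / (2 * 4^2))
  ch <- c(numeric(200), qs, numeric(200))
  expect_true(classify_qs(ch, 220, fs, noise_sd_mv = 0.01))
  # symmetric biphasic (ratio 1) is not QS
  bi <- c(numeric(200), -(tt / 4) * exp(-tt^2 / (2 * 4^2)), numeric(200))
  expect_false(classify_qs(bi, 224, fs, noise_sd_mv = 0.01))
  # ratio exactly at the threshold fails the strict inequality
  synth <- c(numeric(200), qs, numeric(200))
  synth[239] <- 0.15                     # positive excursion = 0.15 * |S|
  expect_false(classify_qs(synth, 220, fs, noise_sd_mv = 0.01))
  synth[239] <- 0.149
  expect_true(classify_qs(synth, 220, fs, noise_sd_mv = 0.01))
  # below the noise floor nothing is QS
  expect_false(classify_qs(0.001 * ch, 220, fs, noise_sd_mv = 0.01))
  # truncated window flagged
  res <- classify_qs(ch, 5, fs, noise_sd_mv = 0.01)
  expect_true(isTRUE(attr(res, "truncated")))
  expect_error(classify_qs(ch, 1e6, fs), "outside")
})

test_that("focal simulations give one event at the source electrode", {
  geo <- default_geometry()
  src <- geo$electrode_positions[1, ]
  a <- focal_acquisition(seed = 1, n_beats = 3, source_position = src)
  lats <- detect_lats(a)
  ev <- detect_fac(a, lats)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$origin_electrode, 1L)
  expect_equal(ev$n_beats, 3L)
  expect_length(ev$beat_times_ms[[1]], 3L)
})

test_that("single-beat QS and non-QS regimes yield no focal events", {
  geo <- default_geometry()
  src <- geo$electrode_positions[1, ]
  a1 <- focal_acquisition(seed = 2, n_beats = 1, source_position = src)
  # a single beat has insufficient context for a DCL; supply one
  lats <- detect_lats(a1)
  dcl <- structure(list(value_ms = 170), class = "dominant_cycle_length")
  expect_equal(nrow(detect_fac(a1, lats, dcl)), 0L)
  # planar and rotor fields with biphasic templates never classify QS
  expect_equal(nrow(detect_fac(planar_acquisition(seed = 3),
                               detect_lats(planar_acquisition(seed = 3)))), 0L)
  ar <- rotor_acquisition(seed = 4, n_beats = 4)
  expect_equal(nrow(detect_fac(ar, detect_lats(ar))), 0L)
})

test_that("the earliest QS within radius and window wins the origin", {
  geo <- default_geometry()
  fs <- 1000
  # hand-built: QS trains on electrodes 1 and 2 (5.1 mm apart), electrode 1
  # leading by 20 ms -> electrode 2 is suppressed by the 10 mm / 50 ms rule
  tt <- seq(-7.5, 7.5, by = 1)
  qs <- -exp(-(tt + 2.5)^2 / (2 * 2.5^2))
  uni <- matrix(0, 2000, 20, dimnames = list(NULL, rownames(geo$electrode_positions)))
  put <- function(ch, t0) {
    idx <- (t0 - 7):(t0 + 8)
    uni[idx, ch] <<- uni[idx, ch] + qs
  }
  for (k in 0:4) { put(1, 200 + k * 170); put(2, 220 + k * 170) }
  a <- new_acquisition(uni, geo, fs)
  lats <- detect_lats(a, slope_floor_mv_per_ms = 0.05)
  dcl <- structure(list(value_ms = 170), class = "dominant_cycle_length")
  ev <- detect_fac(a, lats, dcl)
  # brute-force oracle: for each QS activation check the rule directly
  d12 <- sqrt(sum((geo$electrode_positions[1, ] - geo$electrode_positions[2, ])^2))
  expect_lt(d12, 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$origin_electrode, 1L)
  expect_equal(ev$n_beats, 5L)
})

test_that("event counts are monotone in the repetition threshold", {
  geo <- default_geometry()
  a <- focal_acquisition(seed = 5, n_beats = 6,
                         source_position = geo$electrode_positions[9, ])
  lats <- detect_lats(a)
  n2 <- sum(detect_fac(a, lats, min_beats = 2)$n_beats)
  n4 <- sum(detect_fac(a, lats, min_beats = 4)$n_beats)
  n7 <- sum(detect_fac(a, lats, min_beats = 7)$n_beats)
  expect_gte(n2, n4); expect_gte(n4, n7)
})

test_that("focal summaries cluster sites like the rotational ones", {
  geo <- default_geometry()
  a <- focal_acquisition(seed = 6, n_beats = 4,
                         source_position = geo$electrode_positions[1, ])
  ev <- detect_fac(a, detect_lats(a))
  s0 <- summarize_fac(ev[0, ])
  expect_false(s0$has_fac)
  s1 <- summarize_fac(ev, n_acquisitions = 1L)
  expect_true(s1$has_fac)
  expect_equal(s1$n_events, nrow(ev))
  far <- ev; far$map_x <- far$map_x + 30
  s2 <- summarize_fac(rbind(ev, far), n_acquisitions = 2L)
  expect_equal(s2$n_sites, 2L)
})
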