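test_that("catheter geometry follows the ring/spline numbering convention", {
  geo <- make_catheter_geometry(ring_radii_mm = c(10, 7, 4, 2), deployment = 0)
  # external ring holds electrodes 1,5,...,17; internal ring 4,8,...,20
  expect_setequal(which(geo$ring_index == 1L), c(1, 5, 9, 13, 17))
  expect_setequal(which(geo$ring_index == 4L), c(4, 8, 12, 16, 20))
  expect_equal(unname(table(geo$ring_index)), rep(5L, 4L), ignore_attr = TRUE)
  expect_equal(unname(table(geo$spline_index)), rep(4L, 5L), ignore_attr = TRUE)
  # external-ring electrodes sit 10 mm from the axis, planar deployment flat
  r1 <- sqrt(rowSums(geo$electrode_positions[geo$ring_index == 1L, 1:2]^2))
  expect_equal(r1, rep(10, 5), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(geo$electrode_positions[, 3], rep(0, 20), ignore_attr = TRUE)
  # pairwise angular spacing within a ring is exactly 72 degrees
  az <- sort(geo$azimuth_rad[geo$ring_index == 1L])
  expect_equal(diff(az), rep(2 * pi / 5, 4), tolerance = 1e-12)
  # bipolar rings pair electrodes k,k+1 along each spline
  expect_equal(geo$bipole_pairs[geo$bipole_ring == 1L, 1], c(1, 5, 9, 13, 17),
               ignore_attr = TRUE)
  expect_equal(geo$bipole_pairs[geo$bipole_ring == 3L, 2], c(4, 8, 12, 16, 20),
               ignore_attr = TRUE)
})

test_that("invalid geometries are rejected", {
  expect_error(make_catheter_geometry(c(10, 7, 7, 2)), "strictly decreasing")
  expect_error(make_catheter_geometry(c(2, 4, 7, 10)), "strictly decreasing")
  expect_error(make_catheter_geometry(c(10, 7, 4)), "4 positive")
})

test_that("activation fields realize the three propagation models", {
  geo <- make_catheter_geometry()
  # planar: LAT difference equals projected distance / velocity
  f <- simulate_activation_field(geo, "planar", cycle_length_ms = 170,
                                 n_beats = 1, direction = c(1, 0, 0),
                                 conduction_velocity_mm_per_ms = 1, seed = 1)
  x <- geo$electrode_positions[, 1]
  lat1 <- vapply(f$lat_table, `[`, numeric(1), 1L)
  expect_equal(unname(lat1 - min(lat1)), unname(x - min(x)), tolerance = 1e-9)

  # rotational: within-beat span over a ring = 4/5 of the cycle
  fr <- simulate_activation_field(geo, "rotational", cycle_length_ms = 170,
                                  n_beats = 1, source_position = c(0, 0, 0),
                                  jitter_sd_ms = 0, seed = 1)
  ring1 <- ring_electrodes(geo, 1L)
  span <- diff(range(vapply(fr$lat_table[ring1], `[`, numeric(1), 1L)))
  expect_equal(span, 4 / 5 * 170, tolerance = 1e-9)

  # focal at the ring axis: same-ring electrodes activate simultaneously
  ff <- simulate_activation_field(geo, "focal", n_beats = 1,
                                  source_position = c(0, 0, 0), seed = 1)
  ring_lats <- vapply(ff$lat_table[ring1], `[`, numeric(1), 1L)
  expect_equal(diff(range(ring_lats)), 0, tolerance = 1e-9)

  expect_error(simulate_activation_field(geo, "focal", n_beats = 1),
               "missing source")
  expect_error(simulate_activation_field(geo, "rotational", n_beats = 1),
               "missing source")
})

test_that("activation fields respect ordering, refractoriness and seeds", {
  geo <- make_catheter_geometry()
  f1 <- simulate_activation_field(geo, "rotational", n_beats = 20,
                                  source_position = c(0, 0, 0),
                                  jitter_sd_ms = 8, seed = 42)
  f2 <- simulate_activation_field(geo, "rotational", n_beats = 20,
                                  source_position = c(0, 0, 0),
                                  jitter_sd_ms = 8, seed = 42)
  expect_identical(f1$lat_table, f2$lat_table)    # bit-reproducible
  for (lats in f1$lat_table) {
    expect_true(all(diff(lats) >= f1$refractory_floor_ms - 1e-9))
  }
})

test_that("waveform synthesis places the slope landmark on the LAT", {
  geo <- make_catheter_geometry()
  f <- simulate_activation_field(geo, "planar", n_beats = 1, t0_ms = 100,
                                 direction = c(1, 0, 0), seed = 1)
  # single activation at a known time, no noise: the discrete-derivative
  # argmin over all samples (brute force) must fall on the LAT sample
  a <- synthesize_unipolar(f, geo, noise_sd_mv = 0, duration_s = 0.5, seed = 1)
  for (e in c(1L, 7L, 14L)) {
    lat <- f$lat_table[[e]][1L]
    d <- diff(a$unipolar[, e])
    expect_equal(which.min(d), round(lat) + 1L, tolerance = 1)
  }
  # QS template is monophasic negative on the source channel
  ff <- simulate_activation_field(geo, "focal", n_beats = 1,
                                  source_position = geo$electrode_positions[4, ],
                                  seed = 1)
  aq <- synthesize_unipolar(ff, geo, template = "qs", noise_sd_mv = 0,
                            duration_s = 0.5, seed = 1)
  ratio <- max(aq$unipolar[, 4]) / abs(min(aq$unipolar[, 4]))
  expect_lt(ratio, 0.15)
  # zero-amplitude field leaves pure noise at the requested SD
  az <- synthesize_unipolar(f, geo, amplitude_mv = 0, noise_sd_mv = 0.05,
                            duration_s = 2, seed = 3)
  expect_equal(sd(as.vector(az$unipolar)), 0.05, tolerance = 0.005)
  # activations inside one template support are summed with a warning
  f2 <- f
  f2$lat_table <- lapply(f$lat_table, function(t) c(t, t + 4))
  expect_warning(synthesize_unipolar(f2, geo, duration_s = 0.5, seed = 1),
                 "summed")
})

test_that("bipolar channels are adjacent-electrode differences", {
  geo <- make_catheter_geometry()
  uni <- matrix(rnorm(200 * 20), 200, 20,
                dimnames = list(NULL, rownames(geo$electrode_positions)))
  bip <- derive_bipolar(uni, geo)
  expect_equal(ncol(bip), 15L)
  expect_equal(bip[, "Penta 1-2"], uni[, 1] - uni[, 2], ignore_attr = TRUE)
  expect_equal(bip[, "Penta 19-20"], uni[, 19] - uni[, 20], ignore_attr = TRUE)
})

test_that("synthetic atrium fixes voltage, ostia and patch coverage", {
  m <- make_synthetic_atrium(n_vertices = 900, base_voltage_mv = 1.0, seed = 1)
  expect_true(all(m$voltage_mv == 1.0))
  expect_length(m$pv_ostia, 4L)
  expect_true(all(lengths(m$pv_ostia) > 0))
  expect_error(make_synthetic_atrium(n_vertices = 100), ">= 500")
  expect_error(make_synthetic_atrium(
    fibrosis_patches = list(list(center = c(0, 0, 0), radius_mm = 5,
                                 voltage_mv = -1))), "non-negative")

  # a patch covering about half the surface drives the <0.35 mV fraction to
  # about 50%; oracle = exact per-vertex area integration of the indicator
  m2 <- make_synthetic_atrium(
    n_vertices = 900, base_voltage_mv = 1.0, seed = 1,
    fibrosis_patches = list(list(center = c(0, 0, 40), radius_mm = 53,
                                 voltage_mv = 0.1)))
  w <- vertex_areas(m2)
  oracle_frac <- 100 * sum(w[m2$voltage_mv < 0.35]) / sum(w)
  vm <- voltage_metrics(m2)
  expect_equal(unname(vm$area_fraction_below["<0.35 mV"]), oracle_frac,
               tolerance = 1e-9)
  expect_gt(oracle_frac, 30); expect_lt(oracle_frac, 70)
})

test_that("cohort generator honors its specification", {
  # degenerate parameter cases
  co <- simulate_cohort(cohort_spec(
    n_men = 400, n_women = 200,
    rac_prevalence_by_gender = c(men = 0.7, women = 0),
    seed = 5))
  expect_false(any(co$has_rac[co$gender == "women"]))
  expect_identical(co$has_rac, co$rac_location_class != "none")

  co0 <- simulate_cohort(cohort_spec(
    n_men = 5000, n_women = 5000,
    recurrence_logit_coefficients = c(intercept = 0, rac_outside = 0,
                                      lva50_pct = 0, la_volume = 0),
    seed = 6))
  expect_equal(mean(co0$recurrence), 0.5, tolerance = 0.02)

  # reproducibility
  expect_identical(simulate_cohort(cohort_spec(seed = 9)),
                   simulate_cohort(cohort_spec(seed = 9)))
  expect_error(cohort_spec(rac_prevalence_by_gender = c(men = 1.3, women = 0.4)),
               "probabilities")
})

test_that("cohort frequencies converge to the specified probabilities", {
  spec <- cohort_spec(n_men = 6000, n_women = 4000, seed = 21)
  co <- simulate_cohort(spec)
  for (g in c("men", "women")) {
    p <- spec$rac_prevalence_by_gender[[g]]
    n <- sum(co$gender == g)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(co$has_rac[co$gender == g]) - p), 3 * se)
    ph <- spec$confounders$hypertension[[g]]
    expect_lt(abs(mean(co$hypertension[co$gender == g]) - ph),
              3 * sqrt(ph * (1 - ph) / n))
  }
  p_out <- spec$rac_outside_probability
  n_rac <- sum(co$has_rac)
  expect_lt(abs(mean(co$rac_location_class[co$has_rac] == "outside") - p_out),
            3 * sqrt(p_out * (1 - p_out) / n_rac))
})

test_that("a 10,000-patient draw recovers the generating odds ratio", {
  co <- simulate_cohort(cohort_spec(n_men = 7500, n_women = 2500, seed = 31))
  co$rac_outside <- co$rac_location_class == "outside"
  fit <- logistic_or(co, exposure = "rac_outside",
                     adjustment_set = c("lva50_pct", "la_volume_cm3"))
  expect_gt(fit$ci_low, 3.4)
  expect_lt(fit$ci_high, 4.7)
  expect_equal(fit$odds_ratio, 4, tolerance = 0.15)
})
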