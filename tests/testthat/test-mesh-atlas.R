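test_that("centering puts the vertex centroid exactly at the origin", {
  m <- make_synthetic_atrium(seed = 1)
  m$vertices <- sweep(m$vertices, 2, c(5, 5, 5), `+`)
  cm <- center_mesh(m)
  expect_equal(colMeans(cm$vertices), c(0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(center_mesh(cm)$vertices, cm$vertices)  # idempotent
  one <- new_atrium_mesh(matrix(c(3, -2, 7), 1), matrix(c(1, 1, 1), 1))
  expect_equal(center_mesh(one)$vertices, matrix(0, 1, 3), ignore_attr = TRUE)
})

test_that("registration recovers identity, rigid and smooth warps", {
  ref <- center_mesh(make_synthetic_atrium(n_vertices = 900, seed = 1))

  reg0 <- nonrigid_icp(ref, ref)
  expect_lt(reg0$rms_post_mm, 1e-8)
  expect_lt(max(abs(reg0$displacement)), 1e-8)

  th <- 12 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rig <- ref
  rig$vertices <- sweep(ref$vertices %*% t(R), 2, c(6, -4, 3), `+`)
  rig <- center_mesh(rig)
  reg1 <- nonrigid_icp(rig, ref)
  expect_lt(reg1$rms_post_mm, 0.1)

  warp <- ref
  w <- 3 * sin(ref$vertices[, 1] / 20) * cos(ref$vertices[, 2] / 25)
  warp$vertices <- ref$vertices + cbind(w, 0.6 * w, -0.5 * w)
  warp <- center_mesh(warp)
  reg2 <- nonrigid_icp(warp, ref)
  expect_lte(reg2$rms_post_mm, 0.1 * reg2$rms_pre_mm)
  expect_lte(reg2$rms_post_mm, reg2$rms_pre_mm)
  expect_error(nonrigid_icp(ref, ref, stiffness_schedule = c(1, 5)),
               "decreasing")
})

test_that("projection averages, drops distant points and conserves mass", {
  ref <- make_synthetic_atrium(n_vertices = 900, seed = 1)
  v7 <- ref$vertices[7, ]
  pr <- project_scalars(rbind(v7), 1.0, ref)
  expect_equal(pr$values[7], 1.0)
  pr2 <- project_scalars(rbind(v7, v7 + 0.01), c(0.2, 0.4), ref)
  expect_equal(pr2$values[7], 0.3)
  expect_equal(pr2$n_points[7], 2L)
  far <- v7 * 3                              # ~60 mm off the shell
  pr3 <- project_scalars(rbind(v7, far), c(1, 9), ref, max_distance_mm = 10)
  expect_equal(pr3$n_dropped, 1L)
  expect_true(is.na(pr3$values[which.min(colSums((t(ref$vertices) - far)^2))]) ||
                pr3$values[7] == 1)
  # mass conservation over a random cloud near the surface
  set.seed(4)
  idx <- sample(nrow(ref$vertices), 200, replace = TRUE)
  pts <- ref$vertices[idx, ] + matrix(rnorm(600, 0, 0.5), ncol = 3)
  vals <- runif(200)
  pr4 <- project_scalars(pts, vals, ref, max_distance_mm = 10)
  expect_equal(sum(pr4$values * pr4$n_points, na.rm = TRUE), sum(vals),
               tolerance = 1e-9)
})

test_that("area-weighted voltage metrics honor thresholds and exclusions", {
  m <- make_synthetic_atrium(n_vertices = 900, base_voltage_mv = 1, seed = 1)
  vm <- voltage_metrics(m)
  expect_equal(vm$mean_voltage_mv, 1)
  expect_equal(unname(vm$area_fraction_below), c(0, 0, 0))
  # half the area at 0.05 mV: all three fractions equal that area share
  w <- vertex_areas(m)
  m2 <- m
  low <- m$vertices[, 3] > 0                 # upper hemisphere
  m2$voltage_mv[low] <- 0.05
  share <- 100 * sum(w[low]) / sum(w)
  vm2 <- voltage_metrics(m2)
  expect_equal(unname(vm2$area_fraction_below), rep(share, 3), tolerance = 1e-9)
  # nesting: fraction(<0.1) <= fraction(<0.35) <= fraction(<0.5)
  m3 <- m
  set.seed(7)
  m3$voltage_mv <- runif(length(m$voltage_mv), 0, 1)
  vm3 <- voltage_metrics(m3)
  f <- unname(vm3$area_fraction_below)
  expect_lte(f[3], f[2]); expect_lte(f[2], f[1])
  # unobserved vertices leave numerator and denominator
  m4 <- m2
  m4$voltage_mv[low] <- NA
  expect_equal(voltage_metrics(m4)$mean_voltage_mv, 1)
  m5 <- m; m5$voltage_mv <- rep(NA_real_, length(m$voltage_mv))
  expect_error(voltage_metrics(m5), "undefined metric")
  # region areas sum to the total mesh area
  areas <- tapply(w, m$region, sum)
  expect_equal(sum(areas), sum(w), tolerance = 1e-9)
})

test_that("landmark-seeded segmentation matches the planted regions", {
  m <- make_synthetic_atrium(n_vertices = 1800, seed = 2)
  seg <- segment_regions(m)
  expect_false(any(is.na(seg)))
  agreement <- mean(as.character(seg) == as.character(m$region))
  expect_gte(agreement, 0.95)
  # the 1-cm rule: close to an ostium -> antra; far on the posterior -> not
  g <- mesh_graph(m)
  d_ost <- apply(vapply(m$pv_ostia, function(l) geodesic_from(g, l),
                        numeric(nrow(m$vertices))), 1, min)
  near <- d_ost < 5 & as.character(m$region) == "PV_antra"
  expect_true(all(seg[near] == "PV_antra"))
  post <- which(d_ost > 15 & as.character(m$region) == "posterior")
  expect_true(mean(seg[post] == "posterior") > 0.95)
  # missing landmarks are reported by name
  m_bad <- m; m_bad$laa_neck <- NULL
  expect_error(segment_regions(m_bad), "laa_neck")
  m_bad2 <- m; m_bad2$region_seeds$roof <- NULL
  expect_error(segment_regions(m_bad2), "roof")
})

test_that("driver sites classify against the ablation line geodesically", {
  m <- make_synthetic_atrium(n_vertices = 1200, seed = 3)
  ost <- colMeans(m$vertices[m$pv_ostia[["LSPV"]], ])
  laa <- m$vertices[m$laa_apex, ]
  expect_equal(classify_driver_location(m, rbind(ost)), "inside")
  expect_equal(classify_driver_location(m, rbind(laa)), "outside")
  on_line <- m$vertices[m$ablation_line[[1]][1], ]
  expect_equal(classify_driver_location(m, rbind(on_line)), "inside")
  m_no <- m; m_no$ablation_line <- NULL
  expect_error(classify_driver_location(m_no, rbind(ost)), "classification")
  # patient-level class
  expect_equal(rac_location_class(character(0)), "none")
  expect_equal(rac_location_class(c("inside", "inside")), "inside_only")
  expect_equal(rac_location_class(c("inside", "outside")), "outside")
})
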