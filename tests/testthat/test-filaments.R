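# Density masks, skeleton tracing, population statistics, clustering,
# inter-puncta spacing, colocalization.

test_that("density_mask covers filaments and separates distant ones", {
  # empty table: empty mask
  empty <- tibble::tibble(x_nm = numeric(), y_nm = numeric())
  expect_false(any(density_mask(empty)))

  # dense straight filament: one component covering the curve footprint
  fl <- make_filament_localizations(filament_scene_spec(geometry = "line",
                                                        seed = 7))
  mk <- density_mask(fl$locs)
  lab <- llpstools:::label_components(mk * 1L, 8L)
  expect_equal(max(lab), 1)
  crv <- fl$truth$curves[[1]]$points
  org <- attr(mk, "origin_nm")
  ii <- floor((crv[, 2] - org[2]) / 10) + 1
  jj <- floor((crv[, 1] - org[1]) / 10) + 1
  inside <- mk[cbind(pmin(pmax(ii, 1), nrow(mk)), pmin(pmax(jj, 1), ncol(mk)))]
  expect_gte(mean(inside), 0.9)

  # two parallel filaments far beyond the smoothing scale: two components
  shift <- fl$locs
  crv_dir <- crv[nrow(crv), ] - crv[1, ]
  perp <- c(-crv_dir[2], crv_dir[1]) / sqrt(sum(crv_dir^2))
  shift$x_nm <- shift$x_nm + 400 * perp[1]
  shift$y_nm <- shift$y_nm + 400 * perp[2]
  both <- dplyr::bind_rows(fl$locs, shift)
  mk2 <- density_mask(both)
  expect_equal(max(llpstools:::label_components(mk2 * 1L, 8L)), 2)
})

test_that("tracing recovers circle and bar geometry from clean masks", {
  # synthetic bar mask of known length (noise-free geometry)
  bar <- matrix(FALSE, 60, 260)
  bar[28:33, 21:240] <- TRUE   # 220 px long, 6 px wide
  tb <- trace_filaments(bar, sr_pixel_nm = 10, origin_nm = c(0, 0))
  expect_equal(nrow(tb), 1)
  expect_false(tb$closed)
  expect_lt(abs(tb$length_nm - 2200) / 2200, 0.05)

  # ring mask: one closed trace of length ~ 2 pi R
  nr <- 160
  rr <- llpstools:::pixel_radius(nr, nr, 79.5, 79.5)
  ring <- rr > 57 & rr < 63
  tr <- trace_filaments(ring, sr_pixel_nm = 10, origin_nm = c(0, 0))
  expect_equal(nrow(tr), 1)
  expect_true(tr$closed)
  expect_lt(abs(tr$length_nm - 2 * pi * 600) / (2 * pi * 600), 0.05)

  # empty mask: empty trace table
  expect_equal(nrow(trace_filaments(matrix(FALSE, 20, 20),
                                    sr_pixel_nm = 10)), 0)
})

test_that("closed/open classification and length recovery hold across seeds", {
  for (s in c(2, 5, 8, 13, 21)) {
    fc <- make_filament_localizations(filament_scene_spec(geometry = "circle",
                                                          seed = s))
    tc <- trace_filaments(density_mask(fc$locs))
    expect_equal(nrow(tc), 1)
    expect_true(tc$closed)
    expect_lt(abs(tc$length_nm - fc$truth$filaments$contour_length_nm) /
                fc$truth$filaments$contour_length_nm, 0.05)

    fl <- make_filament_localizations(filament_scene_spec(geometry = "line",
                                                          seed = s + 50))
    tl <- trace_filaments(density_mask(fl$locs))
    expect_equal(nrow(tl), 1)
    expect_false(any(tl$closed))
    expect_lt(abs(tl$length_nm - fl$truth$filaments$contour_length_nm) /
                fl$truth$filaments$contour_length_nm, 0.05)
  }
})

test_that("population statistics summarize filament lengths", {
  fake <- tibble::tibble(length_um = c(2, 2, 2))
  ps <- population_stats(fake, threshold_um = 5)
  expect_equal(ps$mean_um, 2)
  expect_equal(ps$sd_um, 0)
  expect_equal(ps$fraction_above_threshold, 0)

  ps2 <- population_stats(tibble::tibble(length_um = c(2, 10)),
                          threshold_um = 5)
  expect_equal(ps2$fraction_above_threshold, 0.5)
  expect_equal(glance(ps2)$n, 2)

  expect_error(population_stats(fake[0, ]), "no traces")
})

test_that("single-filament population recovers the generator parameters", {
  # 30 filaments from the single-NPF preset (2.1 um mean, 0.4 um SD)
  lens <- numeric(0); true_lens <- numeric(0)
  for (s in 1:3) {
    sc <- make_filament_localizations(filament_scene_spec(
      geometry = "line", n_filaments = 10, unit_length_sd_nm = 400,
      field_extent_nm = 18000, seed = 600 + s))
    tr <- trace_filaments(density_mask(sc$locs))
    lens <- c(lens, tr$length_um)
    true_lens <- c(true_lens, sc$truth$filaments$contour_length_nm / 1000)
  }
  ps <- population_stats(tibble::tibble(length_um = lens), threshold_um = 5)
  expect_equal(ps$n, 30)
  expect_lt(abs(ps$mean_um - 2.1), 0.2)
  # mean and SD recover the generator parameters within 2 SE
  se_mean <- ps$sd_um / sqrt(ps$n)
  expect_lt(abs(ps$mean_um - mean(true_lens)), 2 * se_mean + 0.05)
  expect_lt(abs(ps$sd_um - sd(true_lens)), 2 * ps$sd_um / sqrt(2 * ps$n) + 0.05)
})

test_that("cluster detection separates bundles from single filaments", {
  # well-separated single filaments: no clusters
  fs <- make_filament_localizations(filament_scene_spec(
    geometry = "line", n_filaments = 6, field_extent_nm = 15000, seed = 6))
  trs <- trace_filaments(density_mask(fs$locs))
  expect_equal(nrow(trs), 6)
  expect_equal(nrow(detect_clusters(trs)), 0)

  # a crossing bundle of 3: at least one cluster holding >= 3 traces
  fb <- make_filament_localizations(filament_scene_spec(
    geometry = "line", bundle_multiplicity = 3, seed = 5))
  trb <- trace_filaments(density_mask(fb$locs))
  cl <- detect_clusters(trb)
  expect_gte(nrow(cl), 1)
  expect_gte(max(cl$n_traces), 3)

  # a lone circle is a cycle, not a cluster
  fc <- make_filament_localizations(filament_scene_spec(geometry = "circle",
                                                        seed = 2))
  tc <- trace_filaments(density_mask(fc$locs))
  expect_equal(nrow(detect_clusters(tc)), 0)
})

test_that("inter-puncta spacing reproduces junction geometry", {
  # 0 or 1 punctum: no spacings
  trace_pts <- cbind(seq(0, 2000, by = 10), rep(0, 201))
  empty <- tibble::tibble(x_nm = numeric(), y_nm = numeric())
  r0 <- inter_puncta_spacing(trace_pts, empty)
  expect_length(r0$spacings_nm, 0)
  one <- tibble::tibble(x_nm = rnorm(20, 1000, 10), y_nm = rnorm(20, 0, 10))
  expect_length(inter_puncta_spacing(trace_pts, one)$spacings_nm, 0)

  # puncta at both ends of a straight trace: one spacing equal to its length
  ends <- tibble::tibble(x_nm = c(rnorm(15, 0, 5), rnorm(15, 2000, 5)),
                         y_nm = rnorm(30, 0, 5))
  re <- inter_puncta_spacing(trace_pts, ends)
  expect_length(re$spacings_nm, 1)
  expect_lt(abs(re$spacings_nm - 2000), 150)

  # distant puncta are reported unassigned
  far <- tibble::tibble(x_nm = rnorm(10, 1000, 5), y_nm = rnorm(10, 900, 5))
  rf <- inter_puncta_spacing(trace_pts, far)
  expect_equal(rf$n_unassigned, 1)

  # junction puncta on tethers recover the unit length for k in {3, 4}
  for (k in c(3, 4)) {
    ft <- make_filament_localizations(filament_scene_spec(
      geometry = "line", n_units_tethered = k, puncta_at_junctions = TRUE,
      seed = 40 + k))
    trt <- trace_filaments(density_mask(ft$locs))
    main <- trt[which.max(trt$length_nm), ]
    sp <- inter_puncta_spacing(main, ft$puncta)
    expect_length(sp$spacings_nm, k - 2)
    expect_true(all(abs(sp$spacings_nm - 2100) / 2100 < 0.1))
  }

  # k = 2: the lone junction punctum sits at one unit of arc length
  f2 <- make_filament_localizations(filament_scene_spec(
    geometry = "line", n_units_tethered = 2, puncta_at_junctions = TRUE,
    seed = 42))
  tr2 <- trace_filaments(density_mask(f2$locs))
  sp2 <- inter_puncta_spacing(tr2[which.max(tr2$length_nm), ], f2$puncta)
  pos <- sp2$puncta$arc_nm[sp2$puncta$assigned]
  expect_length(pos, 1)
  expect_lt(abs(pos - 2100) / 2100, 0.1)
})

test_that("tethered filaments recover additive contour length", {
  ft <- make_filament_localizations(filament_scene_spec(
    geometry = "line", n_units_tethered = 4, seed = 44))
  trt <- trace_filaments(density_mask(ft$locs))
  expect_lt(abs(max(trt$length_nm) - 4 * 2100) / (4 * 2100), 0.1)
})

test_that("colocalization fractions match exact and closed-form expectations", {
  fc <- make_filament_localizations(filament_scene_spec(seed = 3))
  self <- colocalization_fraction(fc$locs, fc$locs, 50)
  expect_equal(self$fraction_ab, 1)
  expect_equal(self$fraction_ba, 1)

  moved <- fc$locs
  moved$x_nm <- moved$x_nm + 1e6
  expect_equal(colocalization_fraction(fc$locs, moved, 50)$fraction_ab, 0)

  # B a uniform spatial Poisson field: fraction ~ 1 - exp(-rho pi r^2)
  set.seed(19)
  A <- tibble::tibble(x_nm = runif(400, 1000, 4000),
                      y_nm = runif(400, 1000, 4000))
  nB <- 2000
  B <- tibble::tibble(x_nm = runif(nB, 0, 5000), y_nm = runif(nB, 0, 5000))
  r <- 100
  rho <- nB / 5000^2
  expected <- 1 - exp(-rho * pi * r^2)
  got <- colocalization_fraction(A, B, r)$fraction_ab
  expect_lt(abs(got - expected), 4 * sqrt(expected * (1 - expected) / 400))

  expect_error(colocalization_fraction(A, B, 0), "radius")
  expect_error(colocalization_fraction(A[0, ], B, 5), "non-empty")
})
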