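# Ground-truth contracts of the synthetic-scene generators.

test_that("brightfield generator: empty scenes, determinism, truth completeness", {
  spec0 <- brightfield_scene_spec(field_shape = c(128, 128), n_fields = 2,
                                  seed = 1)
  s0 <- make_brightfield_set(spec0)
  expect_length(s0$images, 2)
  expect_equal(nrow(s0$truth), 0)

  # identical (spec, seed) -> bit-identical output
  s0b <- make_brightfield_set(spec0)
  expect_identical(s0$images, s0b$images)
  s0c <- make_brightfield_set(brightfield_scene_spec(
    field_shape = c(128, 128), n_fields = 2, seed = 2))
  expect_false(identical(s0$images[[1]], s0c$images[[1]]))

  spec20 <- brightfield_scene_spec(n_fields = 1, n_droplets_in_focus = 20,
                                   seed = 5)
  s20 <- make_brightfield_set(spec20)
  expect_equal(nrow(s20$truth), 20)
  expect_true(all(s20$truth$in_focus))

  expect_error(brightfield_scene_spec(field_shape = c(0, 10)), "field_shape")
})

test_that("in-focus droplet rims carry gradients far above the background", {
  spec <- brightfield_scene_spec(n_fields = 1, n_droplets_in_focus = 20,
                                 seed = 5)
  s <- make_brightfield_set(spec)
  tpl <- s$templates[[1]]          # noise-free template
  g <- farid_gradient(tpl)
  rim <- matrix(FALSE, nrow(tpl), ncol(tpl))
  for (d in seq_len(nrow(s$truth))) {
    r <- llpstools:::pixel_radius(nrow(tpl), ncol(tpl),
                                  s$truth$x[d], s$truth$y[d])
    rim <- rim | (abs(r - s$truth$radius_px[d]) < 1)
  }
  expect_gt(mean(g[rim]), 10 * sd(g[!rim]))
})

test_that("condensate generator: exact intensity ratios and noise models", {
  # E = 1, no noise: constant image
  s1 <- make_condensate_image(condensate_scene_spec(enrichment = 1,
                                                    noise_model = "none",
                                                    seed = 3))
  expect_equal(diff(range(s1$image)), 0)

  # E = 5, no noise: interior/exterior ratio exactly 5 (band excluded)
  s5 <- make_condensate_image(condensate_scene_spec(enrichment = 5,
                                                    noise_model = "none",
                                                    seed = 3))
  interior <- s5$truth$interior_mask > 0
  exterior <- s5$truth$full_mask == 0
  expect_equal(mean(s5$image[interior]) / mean(s5$image[exterior]), 5,
               tolerance = 1e-12)

  expect_error(condensate_scene_spec(enrichment = -1), "enrichment")

  # determinism
  expect_identical(s5$image,
                   make_condensate_image(condensate_scene_spec(
                     enrichment = 5, noise_model = "none", seed = 3))$image)
})

test_that("Poisson-noise condensates recover the enrichment within Monte-Carlo error", {
  # 50 condensates across 5 fields, E = 3, background 100 counts
  ratios <- numeric(0)
  ses <- numeric(0)
  for (s in 1:5) {
    sc <- make_condensate_image(condensate_scene_spec(
      field_shape = c(400, 400), n_condensates = 10, enrichment = 3,
      background_level = 100, noise_model = "poisson", seed = 300 + s))
    for (l in seq_len(10)) {
      px <- sc$truth$interior_mask == l
      ratios <- c(ratios, mean(sc$image[px]) /
                    mean(sc$image[sc$truth$full_mask == 0]))
    }
  }
  se <- sd(ratios) / sqrt(length(ratios))
  expect_equal(length(ratios), 50)
  expect_lt(abs(mean(ratios) - 3), 3 * se)
})

test_that("filament generator: counts, junctions, and puncta contracts", {
  # circle: localization count within 4 * sqrt(expected) of expected
  spc <- filament_scene_spec(geometry = "circle", seed = 11)
  fc <- make_filament_localizations(spc)
  L <- fc$truth$filaments$contour_length_nm
  expected <- 0.1 * L
  expect_lt(abs(nrow(fc$locs) - expected), 4 * sqrt(expected))
  # count conservation between table and truth
  expect_equal(nrow(fc$locs), fc$truth$filaments$n_locs)

  # k = 1 with puncta flag: no junctions, empty puncta table
  f1 <- make_filament_localizations(filament_scene_spec(
    geometry = "line", n_units_tethered = 1, puncta_at_junctions = TRUE,
    seed = 12))
  expect_equal(nrow(f1$puncta), 0)
  expect_equal(nrow(f1$truth$junctions), 0)

  # k = 3 line: junctions at L/3 and 2L/3 of the full curve
  f3 <- make_filament_localizations(filament_scene_spec(
    geometry = "line", n_units_tethered = 3, puncta_at_junctions = TRUE,
    seed = 13))
  Lt <- f3$truth$filaments$contour_length_nm
  expect_equal(sort(f3$truth$junctions$arc_nm), c(Lt / 3, 2 * Lt / 3),
               tolerance = 1e-6)
  expect_equal(nrow(f3$truth$junctions), 2)
  # puncta cluster around junction coordinates within a few sigma
  for (j in 1:2) {
    pj <- f3$puncta[(1:30) + (j - 1) * 30, ]
    expect_lt(sqrt((mean(pj$x_nm) - f3$truth$junctions$x_nm[j])^2 +
                   (mean(pj$y_nm) - f3$truth$junctions$y_nm[j])^2),
              4 * 25 / sqrt(30))
  }

  expect_error(filament_scene_spec(localization_density = 0), "density")

  # determinism
  expect_identical(fc$locs, make_filament_localizations(spc)$locs)
})

test_that("blink movies obey the photon bookkeeping contracts", {
  em <- data.frame(x = c(20, 44), y = c(30, 12))

  # p_on = 0: only baseline + read noise
  off <- make_blink_movie(em, blink_movie_spec(n_frames = 5, p_on = 0,
                                               camera_baseline = 7,
                                               read_noise_sd = 0, seed = 1))
  expect_equal(nrow(off$events), 0)
  expect_true(all(vapply(off$movie, function(f) all(f == 7), logical(1))))

  # ON-event count near n_emitters * n_frames * p_on
  spec <- blink_movie_spec(n_frames = 150, p_on = 0.3, read_noise_sd = 0,
                           camera_baseline = 0, seed = 2)
  mv <- make_blink_movie(em, spec)
  n_exp <- 2 * 150 * 0.3
  sd_bin <- sqrt(2 * 150 * 0.3 * 0.7)
  expect_lt(abs(nrow(mv$events) - n_exp), 4 * sd_bin)

  # photon conservation: frame sum equals recorded photons (no noise/baseline)
  f1 <- mv$events$frame[1]
  expect_equal(sum(mv$movie[[f1]]),
               sum(mv$events$photons_recorded[mv$events$frame == f1]))
  # recorded <= drawn (PSF truncation only)
  expect_true(all(mv$events$photons_recorded <= mv$events$photons_drawn))

  expect_error(blink_movie_spec(psf_sigma_px = 0), "psf_sigma_px")
  expect_error(make_blink_movie(data.frame(x = 1000, y = 2), spec), "within")
})

test_that("AFM stacks compose base, tilt, noise, and outliers as declared", {
  base <- matrix(0, 40, 50)
  base[10:20, 15:35] <- 3

  # single noise-free untilted frame reproduces the base map
  s1 <- make_afm_stack(base, tilt = c(0, 0), n_frames = 1, noise_sd = 0)
  expect_equal(s1$stack[, , 1], base)

  # tilt only: frame minus base is an exact plane
  st <- make_afm_stack(base, tilt = c(0.2, -0.1), n_frames = 1, noise_sd = 0)
  d <- st$stack[, , 1] - base
  xg <- matrix(rep(0:49, each = 40), 40)
  yg <- matrix(rep(0:39, 50), 40)
  expect_equal(d, 0.2 * xg - 0.1 * yg, tolerance = 1e-12)

  # 5 frames, 1 outlier: per-pixel median equals base + plane exactly
  s5 <- make_afm_stack(base, tilt = c(0.2, -0.1), n_frames = 5,
                       outlier_frames = 1, noise_sd = 0, seed = 4)
  expect_length(s5$truth$outlier_frames, 1)
  expect_equal(median_project(s5$stack), base + 0.2 * xg - 0.1 * yg,
               tolerance = 1e-12)

  expect_error(make_afm_stack(base, n_frames = 4, outlier_frames = 2),
               "median")
})
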