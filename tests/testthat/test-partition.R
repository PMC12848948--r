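# Condensate segmentation, partition coefficients, and line profiles.

test_that("pixel_features returns the declared per-scale feature stack", {
  img <- matrix(5, 40, 40)
  fs <- pixel_features(img, scales = c(1, 2))
  expect_equal(dim(fs), c(40, 40, 6))
  # constant image: intensity features constant, gradient and LoG zero
  expect_equal(max(abs(fs[, , "s1_intensity"] - 5)), 0, tolerance = 1e-10)
  expect_equal(max(abs(fs[, , "s2_gradmag"])), 0, tolerance = 1e-10)
  expect_equal(max(abs(fs[, , "s2_log"])), 0, tolerance = 1e-10)

  expect_error(pixel_features(img, scales = numeric()), "scales")

  # scale-normalized LoG of a bright disk is strongest near the disk scale
  sc <- make_condensate_image(condensate_scene_spec(
    field_shape = c(96, 96), n_condensates = 1, radius_px = c(6, 6),
    enrichment = 4, noise_model = "none", seed = 2))
  ctr <- round(c(sc$truth$condensates$y[1], sc$truth$condensates$x[1])) + 1
  # LoG response at center across scales; |LoG| peaks near r/sqrt(2) ~ 4.2
  resp <- vapply(c(1, 4, 12), function(s) {
    abs(pixel_features(sc$image, scales = s)[ctr[1], ctr[2], 3])
  }, numeric(1))
  expect_gt(resp[2], resp[1])
  expect_gt(resp[2], resp[3])
})

test_that("threshold segmentation recovers noise-free condensates almost exactly", {
  sc <- make_condensate_image(condensate_scene_spec(enrichment = 5,
                                                    noise_model = "none",
                                                    seed = 2))
  mk <- segment_condensates(sc$image)
  expect_equal(max(mk), nrow(sc$truth$condensates))
  jac <- per_condensate_jaccard(mk, sc$truth, exclude_band = TRUE)
  expect_true(all(jac >= 0.95))
  # quality gate on the footprint itself
  expect_true(all(per_condensate_jaccard(mk, sc$truth) >= 0.9))

  # constant image: empty mask with a warning, not an error
  expect_warning(mk0 <- segment_condensates(matrix(4, 64, 64)), "constant")
  expect_equal(max(mk0), 0)

  # two disjoint disks give exactly two labels
  sc2 <- make_condensate_image(condensate_scene_spec(
    field_shape = c(128, 128), n_condensates = 2, enrichment = 4,
    noise_model = "none", seed = 6))
  expect_equal(max(segment_condensates(sc2$image)), 2)
})

test_that("trained segmentation works from sparse annotations", {
  sc <- make_condensate_image(condensate_scene_spec(
    field_shape = c(128, 128), n_condensates = 2, enrichment = 4,
    noise_model = "gaussian", noise_sd = 8, seed = 6))
  tr <- sc$truth
  set.seed(10)
  fgpx <- which(tr$interior_mask > 0, arr.ind = TRUE)
  bgpx <- which(tr$full_mask == 0, arr.ind = TRUE)
  ann <- rbind(
    data.frame(row = fgpx[sample(nrow(fgpx), 30), 1],
               col = fgpx[sample(nrow(fgpx), 30), 2], class = 1),
    data.frame(row = bgpx[sample(nrow(bgpx), 30), 1],
               col = bgpx[sample(nrow(bgpx), 30), 2], class = 0))
  mk <- segment_condensates(sc$image, mode = "trained", annotations = ann)
  expect_equal(max(mk), 2)
  expect_identical(attr(mk, "provenance"), "trained")

  # fewer than 20 pixels per class is refused
  expect_error(segment_condensates(sc$image, mode = "trained",
                                   annotations = ann[c(1:10, 31:60), ]),
               ">= 20")
})

test_that("partition coefficients are exact on constructed scenes", {
  # uniform image: every PC = 1 regardless of the mask
  sc <- make_condensate_image(condensate_scene_spec(enrichment = 1,
                                                    noise_model = "none",
                                                    seed = 4))
  ps <- partition_coefficients(sc$image, sc$truth$interior_mask,
                               exclusion_ring_px = 0)
  expect_true(all(tidy(ps)$pc == 1))
  expect_equal(ps$mean, 1)
  expect_equal(ps$sd, 0)

  # E = 5 noise-free with ground-truth interior masks: PC exactly 5
  s5 <- make_condensate_image(condensate_scene_spec(enrichment = 5,
                                                    noise_model = "none",
                                                    seed = 4))
  p5 <- partition_coefficients(s5$image, s5$truth$interior_mask,
                               exclusion_ring_px = 2)
  expect_equal(tidy(p5)$pc, rep(5, p5$n_condensates), tolerance = 1e-12)

  # PC invariant to gain, not to offset
  pg <- partition_coefficients(3 * s5$image, s5$truth$interior_mask,
                               exclusion_ring_px = 2)
  expect_equal(pg$mean, p5$mean, tolerance = 1e-12)
  po <- partition_coefficients(s5$image + 50, s5$truth$interior_mask,
                               exclusion_ring_px = 2)
  expect_false(isTRUE(all.equal(po$mean, p5$mean)))

  # degenerate background rejected
  expect_error(partition_coefficients(s5$image - 1e4,
                                      s5$truth$interior_mask), "> 0")

  # summary statistics agree with an independent streaming pass
  pcs <- tidy(p5)$pc
  s_n <- 0; s_m <- 0; s_m2 <- 0
  for (v in pcs) {
    s_n <- s_n + 1
    d <- v - s_m
    s_m <- s_m + d / s_n
    s_m2 <- s_m2 + d * (v - s_m)
  }
  expect_equal(p5$mean, s_m, tolerance = 1e-12)
  expect_equal(p5$sd, sqrt(s_m2 / (s_n - 1)), tolerance = 1e-12)
})

test_that("partition coefficients recover E = 3 under Poisson noise", {
  pcs <- numeric(0)
  for (s in 1:5) {
    sc <- make_condensate_image(condensate_scene_spec(
      field_shape = c(400, 400), n_condensates = 10, enrichment = 3,
      background_level = 100, noise_model = "poisson", seed = 500 + s))
    ps <- partition_coefficients(sc$image, sc$truth$interior_mask,
                                 exclusion_ring_px = 3)
    pcs <- c(pcs, tidy(ps)$pc)
  }
  se <- sd(pcs) / sqrt(length(pcs))
  expect_lt(abs(mean(pcs) - 3), 3 * se)
})

test_that("line profiles interpolate multi-channel intensities along a segment", {
  # constant channel: flat profile
  lp <- line_profile(list(a = matrix(4, 40, 40)), from = c(2, 5),
                     to = c(30, 5))
  expect_true(all(lp$intensity == 4))

  # horizontal profile of I(x, y) = x is the identity ramp
  img <- matrix(rep(0:59, each = 40), 40, 60)
  lp2 <- line_profile(list(r = img), from = c(5, 20), to = c(50, 20))
  expect_equal(lp2$intensity, 5:50)

  # profile across a noise-free E = 5 condensate: plateau at 5 x background
  sc <- make_condensate_image(condensate_scene_spec(
    field_shape = c(128, 128), n_condensates = 1, radius_px = c(10, 10),
    enrichment = 5, background_level = 100, noise_model = "none", seed = 8))
  cx <- sc$truth$condensates$x[1]; cy <- sc$truth$condensates$y[1]
  lp3 <- line_profile(list(g = sc$image), from = c(cx - 30, cy),
                      to = c(cx + 30, cy))
  expect_equal(max(lp3$intensity), 500)
  expect_equal(min(lp3$intensity), 100)
  # plateau width ~ chord through the disk (diameter here)
  expect_equal(sum(lp3$intensity > 300), 2 * 10, tolerance = 0.15)

  expect_error(line_profile(list(a = img), from = c(3, 3), to = c(3, 3)),
               "zero-length")
  # channels must share a shape
  expect_error(line_profile(list(a = img, b = matrix(0, 5, 8)),
                            from = c(0, 0), to = c(3, 3)), "shape")
})
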