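# Synthetic fluorescence condensate images with known enrichment ground truth.

#' Specify a synthetic condensate scene
#'
#' A fluorescence field containing circular condensates whose interior mean
#' intensity is `enrichment` times the dilute-phase `background_level`. A 1-px
#' edge-smoothing band blends interior and background linearly; ground-truth
#' interior masks exclude this band so noise-free intensity ratios are exact.
#'
#' @param field_shape Image shape in pixels, `c(rows, cols)`.
#' @param n_condensates Number of condensates to place (non-overlapping).
#' @param radius_px Range (min, max) of condensate radii in pixels.
#' @param enrichment Ground-truth client partition coefficient E (>= 0);
#'   E = 1 means no enrichment.
#' @param background_level Dilute-phase intensity (counts).
#' @param noise_model One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_sd Gaussian noise SD (ignored for the other models).
#' @param seed Integer seed.
#' @return A `condensate_scene_spec` list.
#' @export
condensate_scene_spec <- function(field_shape = c(256, 256),
                                  n_condensates = 10,
                                  radius_px = c(6, 12),
                                  enrichment = 3,
                                  background_level = 100,
                                  noise_model = c("none", "gaussian", "poisson"),
                                  noise_sd = 5,
                                  seed = 1) {
  field_shape <- check_field_shape(field_shape)
  noise_model <- match.arg(noise_model)
  if (enrichment < 0) abort("`enrichment` must be >= 0 (E = 1: no enrichment).")
  if (n_condensates < 0) abort("`n_condensates` must be >= 0.")
  if (any(radius_px <= 0)) abort("`radius_px` must be > 0.")
  structure(
    list(field_shape = field_shape, n_condensates = as.integer(n_condensates),
         radius_px = as.numeric(radius_px), enrichment = enrichment,
         background_level = background_level, noise_model = noise_model,
         noise_sd = noise_sd, seed = seed),
    class = "condensate_scene_spec")
}

#' Generate a synthetic condensate image with ground truth
#'
#' With `noise_model = "none"` the mean intensity inside each ground-truth
#' interior mask equals `enrichment * background_level` exactly (the 1-px edge
#' band is excluded from the interior masks and recorded separately).
#'
#' @param spec A [condensate_scene_spec()].
#' @return A list with `image` (matrix), and `truth`, a list holding
#'   `condensates` (tibble: label, x, y, radius_px), `interior_mask` (label
#'   matrix excluding the edge band), `full_mask` (label matrix including the
#'   band), `enrichment`, and `background_level`.
#' @export
make_condensate_image <- function(spec) {
  stopifnot(inherits(spec, "condensate_scene_spec"))
  nr <- spec$field_shape[1]; nc <- spec$field_shape[2]
  E <- spec$enrichment; bg <- spec$background_level
  margin <- max(spec$radius_px) + 3

  cond <- with_seed(split_seed(spec$seed, 1)[1], {
    placed <- tibble(label = integer(), x = numeric(), y = numeric(),
                     radius_px = numeric())
    tries <- 0
    while (nrow(placed) < spec$n_condensates && tries < 20000) {
      tries <- tries + 1
      x <- runif(1, margin, nc - 1 - margin)
      y <- runif(1, margin, nr - 1 - margin)
      r <- runif(1, spec$radius_px[1], spec$radius_px[2])
      if (nrow(placed) == 0 ||
          all(sqrt((placed$x - x)^2 + (placed$y - y)^2) >
              placed$radius_px + r + 4)) {
        placed <- bind_rows(placed,
                            tibble(label = nrow(placed) + 1L, x = x, y = y,
                                   radius_px = r))
      }
    }
    if (nrow(placed) < spec$n_condensates) {
      abort("could not place all condensates without overlap; reduce counts or radii.")
    }
    placed
  })

  image <- matrix(bg, nr, nc)
  interior_mask <- matrix(0L, nr, nc)
  full_mask <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(cond))) {
    r <- pixel_radius(nr, nc, cond$x[k], cond$y[k])
    R <- cond$radius_px[k]
    alpha <- pmin(pmax(R + 0.5 - r, 0), 1)          # 1-px linear edge band
    image <- image + (E - 1) * bg * alpha
    interior_mask[r <= R - 1] <- cond$label[k]
    full_mask[r < R + 0.5] <- cond$label[k]
  }

  image <- switch(spec$noise_model,
    none = image,
    gaussian = image + with_seed(split_seed(spec$seed, 1, stream = 1L)[1],
                                 matrix(rnorm(nr * nc, sd = spec$noise_sd), nr)),
    poisson = with_seed(split_seed(spec$seed, 1, stream = 1L)[1],
                        matrix(rpois(nr * nc, lambda = pmax(image, 0)), nr)))

  list(image = image,
       truth = list(condensates = cond, interior_mask = interior_mask,
                    full_mask = full_mask, enrichment = E,
                    background_level = bg))
}
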