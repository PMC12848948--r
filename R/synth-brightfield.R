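# Synthetic brightfield fields of view with known droplet ground truth.
#
# Emulates defocused-brightfield droplet appearance: a dark interior disk with
# a bright ~2 px rim. The speckle background (smooth multiplicative texture
# from the optics) is a deterministic function of `speckle_seed` alone, so a
# sample and its non-phase-separating reference can share the same speckle.

#' Specify a synthetic brightfield scene
#'
#' Parameters of a set of brightfield fields of view containing in-focus
#' droplets (sharp rims), out-of-focus droplets (the same template blurred by
#' `defocus_sigma_px`), a fixed optical-speckle background, and additive
#' Gaussian camera noise.
#'
#' @param field_shape Image shape in pixels, `c(rows, cols)`.
#' @param n_fields Number of fields of view imaged for the sample.
#' @param n_droplets_in_focus,n_droplets_defocus Droplet counts per field.
#' @param droplet_radius_px Range (min, max) of droplet radii in pixels.
#' @param rim_contrast Rim brightness as a fraction of the background level;
#'   the interior is darkened by half this fraction.
#' @param defocus_sigma_px Gaussian blur applied to out-of-focus droplets.
#' @param speckle_amplitude Smooth-speckle standard deviation as a fraction
#'   of the background level.
#' @param n_speckle_dots Number of sharp speckle points (dust/deposit
#'   artifacts in the optics) in the fixed background; these give the
#'   non-phase-separating reference its nonzero edge fraction.
#' @param speckle_dot_amplitude Dot amplitude as a fraction of the background
#'   level.
#' @param noise_sd Additive Gaussian camera noise (intensity counts).
#' @param background_level Mean background intensity (counts).
#' @param seed Integer seed; all per-field randomness derives from it.
#' @param speckle_seed Separate seed for the speckle texture, so the same
#'   optics can be shared between a sample and its reference.
#' @return A `brightfield_scene_spec` list.
#' @export
brightfield_scene_spec <- function(field_shape = c(512, 512),
                                   n_fields = 5,
                                   n_droplets_in_focus = 0,
                                   n_droplets_defocus = 0,
                                   droplet_radius_px = c(2, 3.5),
                                   rim_contrast = 0.6,
                                   defocus_sigma_px = 5,
                                   speckle_amplitude = 0.02,
                                   n_speckle_dots = 40,
                                   speckle_dot_amplitude = 0.15,
                                   noise_sd = 1,
                                   background_level = 100,
                                   seed = 1,
                                   speckle_seed = 42) {
  field_shape <- check_field_shape(field_shape)
  if (n_fields < 1) abort("`n_fields` must be >= 1.")
  if (n_droplets_in_focus < 0 || n_droplets_defocus < 0) {
    abort("droplet counts must be >= 0.")
  }
  if (any(droplet_radius_px <= 0)) abort("`droplet_radius_px` must be > 0.")
  structure(
    list(field_shape = field_shape, n_fields = as.integer(n_fields),
         n_droplets_in_focus = as.integer(n_droplets_in_focus),
         n_droplets_defocus = as.integer(n_droplets_defocus),
         droplet_radius_px = as.numeric(droplet_radius_px),
         rim_contrast = rim_contrast, defocus_sigma_px = defocus_sigma_px,
         speckle_amplitude = speckle_amplitude,
         n_speckle_dots = as.integer(n_speckle_dots),
         speckle_dot_amplitude = speckle_dot_amplitude, noise_sd = noise_sd,
         background_level = background_level, seed = seed,
         speckle_seed = speckle_seed),
    class = "brightfield_scene_spec")
}

# Smooth speckle texture, unit SD, deterministic in speckle_seed only.
speckle_field <- function(field_shape, speckle_seed) {
  raw <- with_seed(speckle_seed,
                   matrix(rnorm(prod(field_shape)), field_shape[1]))
  sm <- gaussian_smooth(raw, 2.5)
  sm / sd(sm)
}

# Sharp speckle points (optics deposits), deterministic in speckle_seed only.
speckle_dots <- function(field_shape, speckle_seed, n_dots, amplitude) {
  nr <- field_shape[1]; nc <- field_shape[2]
  out <- matrix(0, nr, nc)
  if (n_dots < 1 || amplitude == 0) return(out)
  pts <- with_seed(speckle_seed + 1, {
    cbind(runif(n_dots, 2, nc - 3), runif(n_dots, 2, nr - 3))
  })
  for (d in seq_len(n_dots)) {
    out <- add_radial(out, pts[d, 1], pts[d, 2], 5,
                      function(r) amplitude * exp(-r^2 / (2 * 0.7^2)))
  }
  out
}

# Add one droplet's intensity delta (relative to flat background) onto a
# canvas: dark interior disk, bright ~2 px rim.
add_droplet_delta <- function(canvas, x0, y0, radius, rim_contrast,
                              background_level) {
  add_radial(canvas, x0, y0, radius + 3, function(r) {
    delta <- matrix(0, nrow(r), ncol(r))
    delta[r < (radius - 1.5)] <- -0.5 * rim_contrast * background_level
    delta[r >= (radius - 1.5) & r < (radius + 0.5)] <-
      rim_contrast * background_level
    delta
  })
}

#' Generate a synthetic brightfield image set with ground truth
#'
#' Renders `n_fields` fields of view from a [brightfield_scene_spec()]. The
#' returned ground truth lists every droplet; tests and benchmarks should use
#' it rather than re-deriving truth from the images.
#'
#' @param spec A [brightfield_scene_spec()].
#' @return A list with elements `images` (an [image_set()]), `truth` (a tibble
#'   with one row per droplet: field, x, y, radius_px, in_focus), and
#'   `templates` (the noise-free fields, list of matrices).
#' @export
make_brightfield_set <- function(spec) {
  stopifnot(inherits(spec, "brightfield_scene_spec"))
  nr <- spec$field_shape[1]; nc <- spec$field_shape[2]
  bg <- spec$background_level
  speckle <- bg * spec$speckle_amplitude *
    speckle_field(spec$field_shape, spec$speckle_seed) +
    bg * speckle_dots(spec$field_shape, spec$speckle_seed,
                      spec$n_speckle_dots, spec$speckle_dot_amplitude)
  field_seeds <- split_seed(spec$seed, spec$n_fields)

  images <- vector("list", spec$n_fields)
  templates <- vector("list", spec$n_fields)
  truth <- vector("list", spec$n_fields)
  margin <- max(spec$droplet_radius_px) + 2

  for (f in seq_len(spec$n_fields)) {
    n_in <- spec$n_droplets_in_focus
    n_out <- spec$n_droplets_defocus
    n_tot <- n_in + n_out
    drops <- with_seed(field_seeds[f], {
      if (n_tot > 0) {
        tibble(
          field = f,
          x = runif(n_tot, margin, nc - 1 - margin),
          y = runif(n_tot, margin, nr - 1 - margin),
          radius_px = runif(n_tot, spec$droplet_radius_px[1],
                            spec$droplet_radius_px[2]),
          in_focus = rep(c(TRUE, FALSE), c(n_in, n_out)))
      } else {
        tibble(field = integer(), x = numeric(), y = numeric(),
               radius_px = numeric(), in_focus = logical())
      }
    })
    tmpl <- matrix(bg, nr, nc) + speckle
    if (nrow(drops) > 0) {
      sharp <- matrix(0, nr, nc)
      soft <- matrix(0, nr, nc)
      for (d in seq_len(nrow(drops))) {
        if (drops$in_focus[d]) {
          sharp <- add_droplet_delta(sharp, drops$x[d], drops$y[d],
                                     drops$radius_px[d], spec$rim_contrast, bg)
        } else {
          soft <- add_droplet_delta(soft, drops$x[d], drops$y[d],
                                    drops$radius_px[d], spec$rim_contrast, bg)
        }
      }
      if (any(soft != 0)) soft <- gaussian_smooth(soft, spec$defocus_sigma_px)
      tmpl <- tmpl + sharp + soft
    }
    noise <- with_seed(field_seeds[f] + 1,
                       matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc))
    templates[[f]] <- tmpl
    images[[f]] <- tmpl + noise
    truth[[f]] <- drops
  }

  list(images = image_set(images),
       truth = bind_rows(truth),
       templates = templates)
}
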