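# Synthetic blinking movies for the localization pipeline.
#
# Blinking is memoryless: each binding site is ON in each frame independently
# with probability p_on. An ON event draws a Poisson photon count; each photon
# lands at a position drawn from the emitter's PSF Gaussian and is binned into
# the camera pixel grid (equivalent to a multinomial over pixel-integrated
# Gaussian weights), so the frame sum equals the drawn photon count up to PSF
# truncation at the field border. Camera baseline and Gaussian read noise are
# added afterwards.

#' Specify a synthetic blinking movie
#'
#' @param n_frames Number of camera frames.
#' @param p_on Per-frame independent ON probability per binding site, in
#'   \[0, 1\].
#' @param mean_photons Expected photons per ON event (Poisson).
#' @param psf_sigma_px PSF Gaussian width (pixels).
#' @param camera_baseline Constant camera offset (counts).
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param field_shape Frame shape `c(rows, cols)` in pixels.
#' @param pixel_size_nm Physical pixel size (nm).
#' @param seed Integer seed.
#' @return A `blink_movie_spec` list.
#' @export
blink_movie_spec <- function(n_frames = 100,
                             p_on = 0.05,
                             mean_photons = 1000,
                             psf_sigma_px = 1.2,
                             camera_baseline = 100,
                             read_noise_sd = 2,
                             field_shape = c(64, 64),
                             pixel_size_nm = 108,
                             seed = 1) {
  if (p_on < 0 || p_on > 1) abort("`p_on` must be in [0, 1].")
  if (psf_sigma_px <= 0) abort("`psf_sigma_px` must be > 0.")
  if (n_frames < 1) abort("`n_frames` must be >= 1.")
  structure(
    list(n_frames = as.integer(n_frames), p_on = p_on,
         mean_photons = mean_photons, psf_sigma_px = psf_sigma_px,
         camera_baseline = camera_baseline, read_noise_sd = read_noise_sd,
         field_shape = check_field_shape(field_shape),
         pixel_size_nm = pixel_size_nm, seed = seed),
    class = "blink_movie_spec")
}

# Expected (noise-free) pixel-integrated Gaussian spot: photons distributed
# over the pixel grid by the 2-D integral of the PSF over each pixel.
# (x0, y0) are 0-based pixel-center coordinates.
render_psf <- function(nr, nc, x0, y0, photons, sigma) {
  px <- function(centers, mu) {
    stats::pnorm(centers + 0.5, mu, sigma) - stats::pnorm(centers - 0.5, mu, sigma)
  }
  wy <- px(0:(nr - 1), y0)
  wx <- px(0:(nc - 1), x0)
  photons * outer(wy, wx)
}

#' Generate a blinking movie from emitter positions
#'
#' @param emitters A data frame with columns `x`, `y` (0-based pixel
#'   coordinates), e.g. built from generator ground truth, or the `truth`
#'   element of [make_filament_localizations()] output (its localization
#'   coordinates converted to pixels).
#' @param spec A [blink_movie_spec()].
#' @return A list with `movie` (list of frame matrices) and `events` (tibble:
#'   frame, emitter, x, y, photons_drawn, photons_recorded).
#' @export
make_blink_movie <- function(emitters, spec) {
  stopifnot(inherits(spec, "blink_movie_spec"))
  emitters <- as.data.frame(emitters)
  if (!all(c("x", "y") %in% names(emitters))) {
    abort("`emitters` must have columns `x` and `y` (pixels).")
  }
  nr <- spec$field_shape[1]; nc <- spec$field_shape[2]
  if (nrow(emitters) > 0 &&
      (any(emitters$x < 0 | emitters$x > nc - 1) ||
       any(emitters$y < 0 | emitters$y > nr - 1))) {
    abort("emitter positions must lie within the field.")
  }
  n_em <- nrow(emitters)
  seeds <- split_seed(spec$seed, spec$n_frames)
  movie <- vector("list", spec$n_frames)
  events <- vector("list", spec$n_frames)

  for (f in seq_len(spec$n_frames)) {
    res <- with_seed(seeds[f], {
      frame <- matrix(0, nr, nc)
      ev <- NULL
      if (n_em > 0 && spec$p_on > 0) {
        on <- which(runif(n_em) < spec$p_on)
        if (length(on)) {
          drawn <- rpois(length(on), spec$mean_photons)
          rec <- integer(length(on))
          for (e in seq_along(on)) {
            N <- drawn[e]
            if (N == 0) next
            xs <- rnorm(N, emitters$x[on[e]], spec$psf_sigma_px)
            ys <- rnorm(N, emitters$y[on[e]], spec$psf_sigma_px)
            jj <- round(xs); ii <- round(ys)
            keep <- ii >= 0 & ii <= nr - 1 & jj >= 0 & jj <= nc - 1
            rec[e] <- sum(keep)
            if (rec[e] > 0) {
              lin <- (jj[keep]) * nr + ii[keep] + 1
              counts <- tabulate(lin, nbins = nr * nc)
              frame <- frame + matrix(counts, nr, nc)
            }
          }
          ev <- tibble(frame = f, emitter = on,
                       x = emitters$x[on], y = emitters$y[on],
                       photons_drawn = drawn, photons_recorded = rec)
        }
      }
      noise <- if (spec$read_noise_sd > 0) {
        matrix(rnorm(nr * nc, sd = spec$read_noise_sd), nr, nc)
      } else 0
      list(frame = frame + spec$camera_baseline + noise, ev = ev)
    })
    movie[[f]] <- res$frame
    events[[f]] <- res$ev
  }

  ev <- bind_rows(events)
  if (nrow(ev) == 0) {
    ev <- tibble(frame = integer(), emitter = integer(), x = numeric(),
                 y = numeric(), photons_drawn = integer(),
                 photons_recorded = integer())
  }
  list(movie = movie, events = ev)
}
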