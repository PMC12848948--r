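# Synthetic AFM height-frame stacks: base topography + plane tilt + noise,
# with optional outlier frames carrying a large additive artifact.

#' Generate a synthetic AFM frame stack
#'
#' Each frame is `base_map + a*x + b*y + noise`; `outlier_frames` randomly
#' chosen frames additionally carry a large additive artifact (a tall disc at
#' a random position), recorded in the ground truth. The outlier count must
#' stay below half the stack so the median projection contract holds.
#'
#' @param base_map Numeric matrix of heights (nm), the true topography.
#' @param tilt Numeric `c(a, b)`: plane slope per pixel along x (columns) and
#'   y (rows).
#' @param n_frames Number of frames (>= 1).
#' @param outlier_frames Number of artifact frames (< `n_frames / 2`).
#' @param noise_sd Per-pixel Gaussian height noise (nm).
#' @param artifact_height Height of the outlier artifact (nm).
#' @param seed Integer seed.
#' @return A list with `stack` (rows x cols x n_frames array) and `truth`
#'   (list: base_map, tilt, outlier_frames indices).
#' @export
make_afm_stack <- function(base_map, tilt = c(0, 0), n_frames = 5,
                           outlier_frames = 0, noise_sd = 0,
                           artifact_height = 50, seed = 1) {
  assert_image(base_map, arg = "base_map")
  if (n_frames < 1) abort("`n_frames` must be >= 1.")
  if (outlier_frames >= n_frames / 2) {
    abort("`outlier_frames` must be < n_frames / 2 (median projection contract).")
  }
  nr <- nrow(base_map); nc <- ncol(base_map)
  xg <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  yg <- matrix(rep(0:(nr - 1), nc), nr, nc)
  plane <- tilt[1] * xg + tilt[2] * yg
  seeds <- split_seed(seed, n_frames + 1)

  which_out <- with_seed(seeds[n_frames + 1],
                         sort(sample.int(n_frames, outlier_frames)))
  stack <- array(0, c(nr, nc, n_frames))
  for (f in seq_len(n_frames)) {
    fr <- base_map + plane
    if (noise_sd > 0) {
      fr <- fr + with_seed(seeds[f], matrix(rnorm(nr * nc, sd = noise_sd), nr))
    }
    if (f %in% which_out) {
      art <- with_seed(seeds[f] + 3, {
        x0 <- runif(1, 0, nc - 1); y0 <- runif(1, 0, nr - 1)
        r <- pixel_radius(nr, nc, x0, y0)
        artifact_height * (r < max(4, min(nr, nc) / 6))
      })
      fr <- fr + art
    }
    stack[, , f] <- fr
  }
  list(stack = stack,
       truth = list(base_map = base_map, tilt = tilt,
                    outlier_frames = which_out))
}
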