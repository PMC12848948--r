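# Independent oracles and small helpers used across the test files.

# Naive O(n^2 k^2) correlation with a separable 5-tap pair and reflection
# padding; deliberately independent of the package's vectorized filter path.
conv5_oracle <- function(img, ky, kx) {
  k <- 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(k:1, 1:nr, nr:(nr - k + 1))
  ci <- c(k:1, 1:nc, nc:(nc - k + 1))
  p <- img[ri, ci]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in 1:5) {
        for (b in 1:5) {
          acc <- acc + ky[a] * kx[b] * p[i + a - 1, j + b - 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

farid_oracle_magnitude <- function(img) {
  p <- c(0.037659, 0.249153, 0.426375, 0.249153, 0.037659)
  d <- c(-0.109604, -0.276691, 0.000000, 0.276691, 0.109604)
  gx <- conv5_oracle(img, p, d)
  gy <- conv5_oracle(img, d, p)
  sqrt(gx^2 + gy^2)
}

# Best-label Jaccard overlap of each truth condensate with a predicted mask.
# `exclude_band` removes the 1-px edge-smoothing band from both masks before
# comparing (the band's pixel ownership is undefined by construction).
per_condensate_jaccard <- function(pred, truth, exclude_band = FALSE) {
  band <- truth$full_mask > 0 & truth$interior_mask == 0
  n_true <- max(truth$full_mask)
  vapply(seq_len(n_true), function(l) {
    tm <- if (exclude_band) truth$interior_mask == l else truth$full_mask == l
    best <- 0
    for (q in seq_len(max(1L, max(pred)))) {
      pm <- pred == q
      if (exclude_band) pm <- pm & !band
      best <- max(best, sum(tm & pm) / sum(tm | pm))
    }
    best
  }, numeric(1))
}

# Poisson-sampled pixel-integrated emitter in an n x n ROI (photon positions
# drawn and binned; the same physical model as the movie generator but coded
# independently of it).
sample_emitter_roi <- function(n, x0, y0, mean_photons, sigma) {
  tot <- rpois(1, mean_photons)
  xs <- rnorm(tot, x0, sigma)
  ys <- rnorm(tot, y0, sigma)
  jj <- round(xs); ii <- round(ys)
  keep <- ii >= 0 & ii <= n - 1 & jj >= 0 & jj <= n - 1
  matrix(tabulate(jj[keep] * n + ii[keep] + 1, n * n), n, n)
}
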