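# Low-level helpers shared across modules.
#
# Image convention: a field of view is a plain numeric matrix; rows index y,
# columns index x. Continuous coordinates are 0-based with pixel centers at
# integer positions, so pixel [i, j] (1-based matrix indices) covers
# x in [j - 1.5, j - 0.5), y in [i - 1.5, i - 0.5) around its center
# (x, y) = (j - 1, i - 1). Physical positions are nm via pixel_size_nm.

# Deterministic seed splitting: every generator call derives independent child
# seeds from its single `seed` argument through this arithmetic scheme, so
# identical (spec, seed) pairs reproduce bit-identical output without touching
# the caller's RNG state.
split_seed <- function(seed, n, stream = 0L) {
  seed <- as.double(seed)
  i <- seq_len(n)
  # LCG-style mixing mod the Mersenne prime 2^31 - 1; kept in double precision
  # (all intermediates < 2^53).
  ((seed %% 2147483647) * 48271 + stream * 69621 + i * 16807) %% 2147483647 + 1
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

check_field_shape <- function(field_shape) {
  if (length(field_shape) != 2 || any(!is.finite(field_shape)) ||
      any(field_shape < 1)) {
    abort("`field_shape` must be two positive integers (rows, cols).")
  }
  as.integer(field_shape)
}

#' @noRd
assert_image <- function(image, min_dim = 1L, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(image) < min_dim || ncol(image) < min_dim) {
    abort(sprintf("`%s` must be at least %d x %d pixels.", arg, min_dim, min_dim))
  }
  invisible(image)
}

# Reflection padding (edge row/column duplicated) by k pixels on every side.
reflect_pad <- function(m, k) {
  if (k == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (k > nr || k > nc) abort("padding exceeds image size")
  ri <- c(k:1, 1:nr, nr:(nr - k + 1))
  ci <- c(k:1, 1:nc, nc:(nc - k + 1))
  m[ri, ci, drop = FALSE]
}

# Separable correlation with 1-D kernels (odd length), reflection-padded.
# `ky` runs down columns (y direction), `kx` across rows (x direction).
# Applied as correlation: out[i,j] = sum_a sum_b ky[a] kx[b] m[i+a-c, j+b-c].
sep_filter <- function(m, ky, kx) {
  stopifnot(length(ky) %% 2 == 1, length(kx) %% 2 == 1)
  k <- max(length(ky), length(kx)) %/% 2
  p <- reflect_pad(m, k)
  nr <- nrow(m); nc <- ncol(m)
  # vertical pass
  cy <- (length(ky) - 1L) %/% 2L
  v <- matrix(0, nr, nc + 2L * k)
  for (a in seq_along(ky)) {
    if (ky[a] == 0) next
    v <- v + ky[a] * p[(a - cy - 1L + k) + seq_len(nr), , drop = FALSE]
  }
  cx <- (length(kx) - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (b in seq_along(kx)) {
    if (kx[b] == 0) next
    out <- out + kx[b] * v[, (b - cx - 1L + k) + seq_len(nc), drop = FALSE]
  }
  out
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with reflection boundary; exact on constants.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  sep_filter(m, k, k)
}

# Distance-to-center map for a disk at continuous (x0, y0) [0-based coords].
pixel_radius <- function(nr, nc, x0, y0) {
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  y <- matrix(rep(0:(nr - 1), nc), nr, nc)
  sqrt((x - x0)^2 + (y - y0)^2)
}

# Add f(r) of the distance to (x0, y0) into `canvas`, evaluated only inside a
# local window of half-size `rad` pixels (render speed-up for small objects).
add_radial <- function(canvas, x0, y0, rad, f) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  i0 <- max(1L, floor(y0 + 1 - rad)); i1 <- min(nr, ceiling(y0 + 1 + rad))
  j0 <- max(1L, floor(x0 + 1 - rad)); j1 <- min(nc, ceiling(x0 + 1 + rad))
  if (i0 > i1 || j0 > j1) return(canvas)
  ii <- i0:i1; jj <- j0:j1
  r <- sqrt(outer((ii - 1 - y0)^2, (jj - 1 - x0)^2, `+`))
  canvas[ii, jj] <- canvas[ii, jj] + f(r)
  canvas
}

# Bilinear interpolation of `image` at continuous 0-based (x, y) positions.
# Positions are clamped to the valid interpolation domain.
bilinear <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  j0 <- pmin(floor(x), nc - 2); i0 <- pmin(floor(y), nr - 2)
  fx <- x - j0; fy <- y - i0
  i0 <- i0 + 1; j0 <- j0 + 1  # back to 1-based matrix indices
  image[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    image[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    image[cbind(i0 + 1, j0)] * (1 - fx) * fy +
    image[cbind(i0 + 1, j0 + 1)] * fx * fy
}

# Connected-component labeling. 4-connectivity delegates to EBImage::bwlabel;
# 8-connectivity is done with igraph components on the foreground pixel graph.
label_components <- function(mask, connectivity = 8L) {
  storage.mode(mask) <- "integer"
  if (connectivity == 4L) {
    lab <- EBImage::bwlabel(mask)
    return(matrix(as.integer(lab), nrow(mask), ncol(mask)))
  }
  if (connectivity != 8L) abort("`connectivity` must be 4 or 8.")
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask != 0L)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(out)
  pos <- match(seq_len(nr * nc), idx)  # linear index -> vertex id (NA if bg)
  i <- ((idx - 1L) %% nr) + 1L
  j <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    i2 <- i + s[1]; j2 <- j + s[2]
    ok <- i2 >= 1L & i2 <= nr & j2 >= 1L & j2 <= nc
    if (!any(ok)) next
    nb <- (j2[ok] - 1L) * nr + i2[ok]
    v2 <- pos[nb]
    keep <- !is.na(v2)
    if (!any(keep)) next
    edges[[length(edges) + 1L]] <-
      cbind(which(ok)[keep], v2[keep])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership
  # relabel in first-encounter order so labels are deterministic and contiguous
  comp <- match(comp, unique(comp))
  out[idx] <- comp
  out
}

# Keep only components with at least `min_area` pixels; relabel 1..n.
filter_small_components <- function(labels, min_area) {
  if (max(labels) == 0L) return(labels)
  areas <- tabulate(labels)
  keep <- which(areas >= min_area)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0L] <- remap[labels[labels > 0L]]
  matrix(as.integer(out), nrow(labels), ncol(labels))
}

# Fill background holes smaller than `max_hole_px` that do not touch the
# image border (large enclosed regions, e.g. the inside of a ring, are kept).
fill_small_holes <- function(mask, max_hole_px = 25) {
  bg <- label_components((!mask) * 1L, connectivity = 4L)
  if (max(bg) == 0L) return(mask)
  areas <- tabulate(bg)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  fill <- setdiff(which(areas <= max_hole_px), border)
  out <- mask
  out[bg %in% fill] <- TRUE
  out
}

# Binary dilation by a disc of radius r (pixels); r = 0 is a no-op.
dilate_disc <- function(mask, r) {
  storage.mode(mask) <- "integer"
  if (r <= 0) return(mask != 0L)
  brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  EBImage::dilate(mask != 0L, brush) != 0
}
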