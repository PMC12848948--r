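# Condensate segmentation and partition-coefficient measurement.
#
# The partition coefficient (PC) of a client molecule is its mean fluorescence
# intensity inside a condensate divided by the mean intensity of the dilute
# phase; PC = 1 means no enrichment. Condensates are segmented either by a
# global automatic threshold or by a small supervised pixel classifier trained
# on sparse user annotations (the same feature family as interactive pixel
# classification tools: per-scale smoothed intensity, gradient magnitude and
# Laplacian-of-Gaussian).

#' Per-pixel feature stack for condensate segmentation
#'
#' For each Gaussian scale, computes the smoothed intensity, the gradient
#' magnitude of the smoothed image (central differences) and the
#' scale-normalized Laplacian-of-Gaussian response.
#'
#' @param image A numeric matrix.
#' @param scales Gaussian smoothing widths in pixels (all > 0).
#' @return A 3-D array `(rows, cols, 3 * length(scales))` with named feature
#'   slices (`s<scale>_intensity`, `s<scale>_gradmag`, `s<scale>_log`).
#' @export
pixel_features <- function(image, scales = c(1, 2, 4)) {
  assert_image(image)
  if (!length(scales) || any(scales <= 0)) {
    abort("`scales` must be a non-empty vector of positive widths.")
  }
  nr <- nrow(image); nc <- ncol(image)
  out <- array(0, c(nr, nc, 3L * length(scales)))
  nms <- character(3L * length(scales))
  d1 <- c(-0.5, 0, 0.5)
  lap <- c(1, -2, 1)
  for (i in seq_along(scales)) {
    s <- scales[i]
    sm <- gaussian_smooth(image, s)
    gx <- sep_filter(sm, c(0, 1, 0), d1)
    gy <- sep_filter(sm, d1, c(0, 1, 0))
    lg <- s^2 * (sep_filter(sm, lap, c(0, 1, 0)) +
                 sep_filter(sm, c(0, 1, 0), lap))
    out[, , 3 * i - 2] <- sm
    out[, , 3 * i - 1] <- sqrt(gx^2 + gy^2)
    out[, , 3 * i] <- lg
    nms[3 * i - (2:0)] <- paste0("s", s, c("_intensity", "_gradmag", "_log"))
  }
  dimnames(out) <- list(NULL, NULL, nms)
  out
}

#' Segment condensates in a fluorescence image
#'
#' `mode = "threshold"`: a global automatic threshold. Otsu's method on the
#' largest-scale smoothed intensity splits condensate from background pixels;
#' the final cut is the midpoint of the two class means, applied to the
#' smallest-scale smoothed image so the boundary sits at the half-intensity
#' contour (heavier smoothing would dilate it). Then connected components and
#' a minimum-area filter. `mode = "trained"`: a linear-discriminant pixel
#' classifier on the [pixel_features()] stack, fitted to sparse annotated
#' pixels (>= 20 per class), then the same post-processing. If no condensates
#' survive, an empty mask is returned with a warning.
#'
#' @param image A numeric matrix.
#' @param mode `"threshold"` or `"trained"`.
#' @param annotations For `"trained"`: data frame with columns `row`, `col`
#'   (1-based pixel indices) and `class` (1 = condensate, 0 = background).
#' @param scales Feature scales (pixels).
#' @param min_area_px Minimum condensate area (pixels).
#' @param connectivity Component connectivity, 4 or 8.
#' @return A `label_mask`: integer matrix (0 = background, 1..n = condensates)
#'   with attribute `provenance`.
#' @export
segment_condensates <- function(image,
                                mode = c("threshold", "trained"),
                                annotations = NULL,
                                scales = c(1, 2, 4),
                                min_area_px = 9,
                                connectivity = 8L) {
  assert_image(image)
  mode <- match.arg(mode)
  if (mode == "threshold") {
    sm_big <- gaussian_smooth(image, max(scales))
    rng <- range(sm_big)
    if (diff(rng) <= 1e-9 * max(abs(rng), 1)) {
      warn("image is constant: no condensates found.")
      return(new_label_mask(matrix(0L, nrow(image), ncol(image)), "threshold"))
    }
    u <- (sm_big - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(u))
    split_fg <- u > th
    sm_small <- gaussian_smooth(image, min(scales))
    cut <- (mean(sm_small[split_fg]) + mean(sm_small[!split_fg])) / 2
    fg <- sm_small > cut
  } else {
    if (is.null(annotations) ||
        !all(c("row", "col", "class") %in% names(annotations))) {
      abort("`annotations` must have columns row, col, class for trained mode.")
    }
    tab <- table(factor(annotations$class, levels = c(0, 1)))
    if (any(tab < 20)) {
      abort("trained mode needs >= 20 annotated pixels per class.")
    }
    feats <- pixel_features(image, scales)
    nfeat <- dim(feats)[3]
    idx <- cbind(annotations$row, annotations$col)
    X <- vapply(seq_len(nfeat), function(k) feats[, , k][idx],
                numeric(nrow(idx)))
    Xall <- vapply(seq_len(nfeat), function(k) as.vector(feats[, , k]),
                   numeric(nrow(image) * ncol(image)))
    fg <- matrix(nb_pixel_classifier(X, annotations$class, Xall),
                 nrow(image), ncol(image))
  }
  lab <- label_components(fg * 1L, connectivity = connectivity)
  lab <- filter_small_components(lab, min_area_px)
  if (max(lab) == 0L) warn("no condensates found: empty mask returned.")
  new_label_mask(lab, mode)
}

# Diagonal (feature-whitened nearest-centroid) pixel classifier: per-class
# feature means, pooled regularized per-feature variances, equal priors.
# Deliberately simple and stable for both noise-free (zero-variance) and
# photon-noise annotations, where full-covariance discriminants fitted to a
# few dozen pixels misplace the boundary.
nb_pixel_classifier <- function(X, y, Xnew) {
  y <- as.integer(y)
  mu0 <- colMeans(X[y == 0L, , drop = FALSE])
  mu1 <- colMeans(X[y == 1L, , drop = FALSE])
  v <- (apply(X[y == 0L, , drop = FALSE], 2, stats::var) +
        apply(X[y == 1L, , drop = FALSE], 2, stats::var)) / 2
  v <- v + 1e-4 * apply(X, 2, stats::var) + 1e-9 * (abs(mu0) + abs(mu1) + 1)^2
  d0 <- sweep(Xnew, 2, mu0)^2 %*% (1 / v)
  d1 <- sweep(Xnew, 2, mu1)^2 %*% (1 / v)
  as.vector(d1 < d0)
}

new_label_mask <- function(lab, provenance) {
  structure(lab, provenance = provenance, class = c("label_mask", "matrix", "array"))
}

#' Per-condensate partition coefficients
#'
#' For every labeled condensate, `PC_i` = mean intensity over the condensate
#' divided by the mean intensity of the dilute phase. The dilute phase is all
#' pixels outside every condensate after dilating the mask by
#' `exclusion_ring_px` (0 reproduces the literal whole-background reading).
#'
#' @param image A numeric matrix.
#' @param mask A label matrix aligned with `image` (e.g. from
#'   [segment_condensates()] or generator ground truth).
#' @param exclusion_ring_px Dilation radius excluded from the background.
#' @return A `partition_summary`: list with `per_condensate` (tibble: label,
#'   area_px, mean_intensity, pc), `mean`, `sd`, `n_condensates`,
#'   `background_intensity`.
#' @export
partition_coefficients <- function(image, mask, exclusion_ring_px = 3) {
  assert_image(image)
  if (!all(dim(mask) == dim(image))) abort("`mask` must match `image` shape.")
  m <- matrix(as.integer(mask), nrow(mask))
  bg_px <- !dilate_disc(m, exclusion_ring_px)
  if (!any(bg_px)) abort("no background pixels left after ring exclusion.")
  bg_mean <- mean(image[bg_px])
  if (bg_mean <= 0) abort("background mean intensity must be > 0.")
  labels <- sort(unique(m[m > 0L]))
  per <- purrr::map(labels, function(l) {
    px <- m == l
    tibble(label = l, area_px = sum(px),
           mean_intensity = mean(image[px]),
           pc = mean(image[px]) / bg_mean)
  })
  per <- bind_rows(per)
  structure(
    list(per_condensate = per,
         mean = if (nrow(per)) mean(per$pc) else NA_real_,
         sd = if (nrow(per) >= 2) sd(per$pc) else NA_real_,
         n_condensates = nrow(per),
         background_intensity = bg_mean),
    class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat(sprintf(
    "<partition_summary> %d condensate(s)\n  mean PC = %.4g, sd = %.4g, background = %.4g\n",
    x$n_condensates, x$mean, x$sd, x$background_intensity))
  invisible(x)
}

#' Multi-channel intensity profile along a line
#'
#' Samples every channel by bilinear interpolation at unit-pixel steps along
#' the segment from `from` to `to` (0-based x, y coordinates), averaging over
#' `width_px` perpendicular offsets.
#'
#' @param images A named list of numeric matrices (one per channel), all the
#'   same shape.
#' @param from,to Numeric `c(x, y)` endpoints (0-based pixel coordinates).
#' @param width_px Number of perpendicular 1-px-spaced offsets to average.
#' @param pixel_size_nm Pixel size for the `distance_nm` column.
#' @return A tibble: `distance_px`, `distance_nm`, `channel`, `intensity`.
#' @export
line_profile <- function(images, from, to, width_px = 1, pixel_size_nm = 108) {
  if (is.matrix(images)) images <- list(channel1 = images)
  if (is.null(names(images)) || any(names(images) == "")) {
    names(images) <- paste0("channel", seq_along(images))
  }
  shp <- dim(images[[1]])
  for (m in images) {
    assert_image(m)
    if (!all(dim(m) == shp)) abort("all channels must share one shape.")
  }
  v <- c(to[1] - from[1], to[2] - from[2])
  len <- sqrt(sum(v^2))
  if (len == 0) abort("zero-length segment.")
  u <- v / len
  perp <- c(-u[2], u[1])
  steps <- seq(0, len, by = 1)
  offs <- seq_len(width_px) - (width_px + 1) / 2
  prof <- purrr::imap(images, function(img, ch) {
    vals <- vapply(offs, function(o) {
      bilinear(img,
               from[1] + steps * u[1] + o * perp[1],
               from[2] + steps * u[2] + o * perp[2])
    }, numeric(length(steps)))
    vals <- matrix(vals, nrow = length(steps))
    tibble(distance_px = steps, distance_nm = steps * pixel_size_nm,
           channel = ch, intensity = rowMeans(vals))
  })
  bind_rows(prof)
}
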