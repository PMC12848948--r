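# Desk-scale single-molecule localization: detect blinking events, fit a
# pixel-integrated 2-D Gaussian PSF + constant background per event, and
# render super-resolution images from the resulting localization table.

#' Localization settings
#'
#' @param k_detect Detection threshold in robust noise SDs above background.
#' @param window_px Square fitting window side (odd, >= 7).
#' @param psf_sigma_px Initial PSF width guess for fitting.
#' @param pixel_size_nm Camera pixel size (nm).
#' @param min_photons Fits below this photon count are dropped.
#' @return A `localize_settings` list.
#' @export
localize_settings <- function(k_detect = 5, window_px = 9, psf_sigma_px = 1.2,
                              pixel_size_nm = 108, min_photons = 50) {
  if (window_px < 7 || window_px %% 2 == 0) {
    abort("`window_px` must be odd and >= 7.")
  }
  structure(list(k_detect = k_detect, window_px = as.integer(window_px),
                 psf_sigma_px = psf_sigma_px, pixel_size_nm = pixel_size_nm,
                 min_photons = min_photons),
            class = "localize_settings")
}

#' Detect candidate emitters in one frame
#'
#' Local maxima (3 x 3 neighborhood) exceeding `bg + k_detect` robust noise
#' SDs (1.4826 x MAD). Candidates closer than one fitting window are all
#' dropped (overlapping spots are not fit).
#'
#' @param frame A numeric matrix.
#' @param bg_estimate Background level; `NULL` = frame median.
#' @param k_detect Threshold in noise SDs.
#' @param window_px Minimum pairwise separation (one fitting window).
#' @return A tibble of integer candidate positions: `row`, `col` (1-based),
#'   `x`, `y` (0-based), `value`.
#' @export
detect_candidates <- function(frame, bg_estimate = NULL, k_detect = 5,
                              window_px = 9) {
  assert_image(frame, min_dim = 3L)
  bg <- bg_estimate %||% median(frame)
  noise <- mad(frame)
  thr <- bg + k_detect * noise
  nr <- nrow(frame); nc <- ncol(frame)
  p <- reflect_pad(frame, 1L)
  is_max <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- p[(1 + di) + seq_len(nr) - 1 + 1, (1 + dj) + seq_len(nc) - 1 + 1]
    is_max <- is_max & (frame >= nb)
  }
  sel <- which(is_max & frame > thr, arr.ind = TRUE)
  if (nrow(sel) == 0) {
    return(tibble(row = integer(), col = integer(), x = numeric(),
                  y = numeric(), value = numeric()))
  }
  # collapse plateaus: keep a single pixel per 8-connected plateau
  if (nrow(sel) > 1) {
    pm <- matrix(0L, nr, nc); pm[sel] <- 1L
    lab <- label_components(pm, connectivity = 8L)
    keep <- !duplicated(lab[sel])
    sel <- sel[keep, , drop = FALSE]
  }
  # enforce one-window separation: any pair closer than window_px drops both
  if (nrow(sel) > 1) {
    d <- as.matrix(stats::dist(sel))
    diag(d) <- Inf
    ok <- apply(d, 1, min) >= window_px
    sel <- sel[ok, , drop = FALSE]
  }
  tibble(row = as.integer(sel[, 1]), col = as.integer(sel[, 2]),
         x = as.numeric(sel[, 2] - 1), y = as.numeric(sel[, 1] - 1),
         value = frame[sel])
}

#' Fit a pixel-integrated Gaussian to one emitter ROI
#'
#' Weighted least-squares fit of `background + N * G(x0, y0, sx, sy)` where G
#' is the 2-D Gaussian integrated over each pixel (erf model), using
#' Levenberg-Marquardt with residuals scaled by the square root of the model
#' (the Gaussian approximation of the Poisson likelihood, near-efficient for
#' shot-noise-limited data). The localization precision is estimated with the
#' simple Thompson-style form `sigma_psf_nm / sqrt(N)`.
#'
#' @param roi A square numeric matrix (side >= 7).
#' @param init Optional named list with starting values (`x0`, `y0`,
#'   `photons`, `sx`, `sy`, `bg`), 0-based ROI coordinates.
#' @param pixel_size_nm Pixel size used for the precision estimate.
#' @return A list: `x0`, `y0` (0-based ROI coords), `photons`, `sx`, `sy`,
#'   `bg`, `precision_nm`, `converged`, `residual_norm`.
#' @export
fit_emitter <- function(roi, init = NULL, pixel_size_nm = 108) {
  assert_image(roi, min_dim = 7L, arg = "roi")
  if (nrow(roi) != ncol(roi)) abort("`roi` must be square.")
  n <- nrow(roi)
  bg0 <- init$bg %||% min(roi)
  mass <- pmax(roi - bg0, 0)
  tot <- sum(mass)
  cx <- if (tot > 0) sum(mass * matrix(rep(0:(n - 1), each = n), n)) / tot else
    (n - 1) / 2
  cy <- if (tot > 0) sum(mass * matrix(rep(0:(n - 1), n), n)) / tot else
    (n - 1) / 2
  start <- list(x0 = init$x0 %||% cx, y0 = init$y0 %||% cy,
                photons = init$photons %||% max(tot, 1),
                sx = init$sx %||% 1.2, sy = init$sy %||% 1.2,
                bg = bg0)
  resid_fn <- function(p) {
    model <- psf_integrated(n, p["x0"], p["y0"], p["photons"], p["sx"],
                            p["sy"]) + p["bg"]
    as.vector((roi - model) / sqrt(pmax(model, 1)))
  }
  p0 <- unlist(start)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      lower = c(x0 = -2, y0 = -2, photons = 0, sx = 0.3, sy = 0.3, bg = -Inf),
      upper = c(x0 = n + 1, y0 = n + 1, photons = Inf, sx = n, sy = n, bg = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(list(converged = FALSE))
  }
  p <- fit$par
  sigma_nm <- mean(c(p["sx"], p["sy"])) * pixel_size_nm
  list(x0 = unname(p["x0"]), y0 = unname(p["y0"]),
       photons = unname(p["photons"]),
       sx = unname(p["sx"]), sy = unname(p["sy"]), bg = unname(p["bg"]),
       precision_nm = unname(sigma_nm / sqrt(max(p["photons"], 1))),
       converged = TRUE,
       residual_norm = sqrt(sum(fit$fvec^2)))
}

# Pixel-integrated anisotropic Gaussian over an n x n ROI (0-based coords).
psf_integrated <- function(n, x0, y0, photons, sx, sy) {
  ix <- stats::pnorm(0:(n - 1) + 0.5, x0, sx) - stats::pnorm(0:(n - 1) - 0.5, x0, sx)
  iy <- stats::pnorm(0:(n - 1) + 0.5, y0, sy) - stats::pnorm(0:(n - 1) - 0.5, y0, sy)
  photons * outer(iy, ix)
}

#' Localize a blinking movie
#'
#' Runs [detect_candidates()] and [fit_emitter()] on every frame and
#' concatenates the kept fits into a localization table. A QC report
#' (candidates found, fits kept, fits dropped) is attached as attribute
#' `"qc"`.
#'
#' @param movie A list of frame matrices (or 3-D array rows x cols x frames).
#' @param settings A [localize_settings()].
#' @return A tibble: `frame`, `x`, `y` (0-based px), `x_nm`, `y_nm`,
#'   `photons`, `sx`, `sy`, `bg`, `precision_nm`.
#' @export
localize_movie <- function(movie, settings = localize_settings()) {
  if (is.array(movie) && length(dim(movie)) == 3) {
    movie <- lapply(seq_len(dim(movie)[3]), function(f) movie[, , f])
  }
  if (!length(movie)) abort("empty movie.")
  w <- settings$window_px
  half <- (w - 1L) %/% 2L
  rows <- list()
  n_cand <- 0L; n_kept <- 0L; n_drop <- 0L
  for (f in seq_along(movie)) {
    frame <- movie[[f]]
    cand <- detect_candidates(frame, k_detect = settings$k_detect,
                              window_px = w)
    n_cand <- n_cand + nrow(cand)
    if (!nrow(cand)) next
    for (ci in seq_len(nrow(cand))) {
      r0 <- cand$row[ci] - half; r1 <- cand$row[ci] + half
      c0 <- cand$col[ci] - half; c1 <- cand$col[ci] + half
      if (r0 < 1 || c0 < 1 || r1 > nrow(frame) || c1 > ncol(frame)) {
        n_drop <- n_drop + 1L
        next
      }
      roi <- frame[r0:r1, c0:c1]
      ft <- fit_emitter(roi, init = list(sx = settings$psf_sigma_px,
                                         sy = settings$psf_sigma_px),
                        pixel_size_nm = settings$pixel_size_nm)
      if (!isTRUE(ft$converged) || ft$photons < settings$min_photons ||
          ft$x0 < -1 || ft$x0 > w || ft$y0 < -1 || ft$y0 > w) {
        n_drop <- n_drop + 1L
        next
      }
      x <- ft$x0 + (c0 - 1)   # back to 0-based frame coordinates
      y <- ft$y0 + (r0 - 1)
      n_kept <- n_kept + 1L
      rows[[length(rows) + 1L]] <- tibble(
        frame = f, x = x, y = y,
        x_nm = x * settings$pixel_size_nm, y_nm = y * settings$pixel_size_nm,
        photons = ft$photons, sx = ft$sx, sy = ft$sy, bg = ft$bg,
        precision_nm = ft$precision_nm)
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(frame = integer(), x = numeric(), y = numeric(), x_nm = numeric(),
           y_nm = numeric(), photons = numeric(), sx = numeric(),
           sy = numeric(), bg = numeric(), precision_nm = numeric())
  attr(out, "qc") <- list(candidates = n_cand, kept = n_kept, dropped = n_drop)
  out
}

#' Render a super-resolution image from a localization table
#'
#' 2-D histogram of localizations on a grid of `sr_pixel_nm` pixels,
#' optionally blurred per localization. Blur kernels are renormalized after
#' truncation (including at image borders) so rendering conserves mass: the
#' image sum equals the number of localizations.
#'
#' @param table A localization tibble with `x_nm`, `y_nm` (or `x`, `y` in px
#'   plus `pixel_size_nm`).
#' @param sr_pixel_nm Rendered pixel size (nm).
#' @param blur `"none"`, `"precision"` (per-localization Gaussian of width
#'   `precision_nm`) or a fixed width in nm.
#' @param extent_nm Optional `c(xmin, xmax, ymin, ymax)` of the render grid;
#'   default spans the table with a margin.
#' @param pixel_size_nm Used to derive nm coordinates when only px are given.
#' @return A numeric matrix (rows = y) with attributes `sr_pixel_nm` and
#'   `origin_nm`.
#' @export
render_localizations <- function(table, sr_pixel_nm = 10, blur = "none",
                                 extent_nm = NULL, pixel_size_nm = 108) {
  if (sr_pixel_nm <= 0) abort("`sr_pixel_nm` must be > 0.")
  if (!nrow(table)) abort("cannot render an empty localization table.")
  if (!all(c("x_nm", "y_nm") %in% names(table))) {
    table$x_nm <- table$x * pixel_size_nm
    table$y_nm <- table$y * pixel_size_nm
  }
  ext <- extent_nm %||% c(min(table$x_nm) - 3 * sr_pixel_nm,
                          max(table$x_nm) + 3 * sr_pixel_nm,
                          min(table$y_nm) - 3 * sr_pixel_nm,
                          max(table$y_nm) + 3 * sr_pixel_nm)
  nc <- max(1L, ceiling((ext[2] - ext[1]) / sr_pixel_nm))
  nr <- max(1L, ceiling((ext[4] - ext[3]) / sr_pixel_nm))
  jj <- floor((table$x_nm - ext[1]) / sr_pixel_nm) + 1
  ii <- floor((table$y_nm - ext[3]) / sr_pixel_nm) + 1
  inside <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  img <- matrix(0, nr, nc)
  if (identical(blur, "none")) {
    lin <- (jj[inside] - 1) * nr + ii[inside]
    counts <- tabulate(lin, nbins = nr * nc)
    img <- matrix(counts, nr, nc)
  } else {
    widths_nm <- if (identical(blur, "precision")) {
      if (!"precision_nm" %in% names(table)) {
        abort("blur = \"precision\" needs a `precision_nm` column.")
      }
      table$precision_nm
    } else {
      rep(as.numeric(blur), nrow(table))
    }
    for (k in which(inside)) {
      s <- max(widths_nm[k] / sr_pixel_nm, 1e-6)
      rad <- ceiling(4 * s)
      ir <- max(1, ii[k] - rad):min(nr, ii[k] + rad)
      jr <- max(1, jj[k] - rad):min(nc, jj[k] + rad)
      cy <- (table$y_nm[k] - ext[3]) / sr_pixel_nm + 0.5
      cx <- (table$x_nm[k] - ext[1]) / sr_pixel_nm + 0.5
      ker <- outer(exp(-((ir - cy)^2) / (2 * s^2)),
                   exp(-((jr - cx)^2) / (2 * s^2)))
      img[ir, jr] <- img[ir, jr] + ker / sum(ker)
    }
  }
  structure(img, sr_pixel_nm = sr_pixel_nm, origin_nm = c(ext[1], ext[3]))
}
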