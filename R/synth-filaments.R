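# Synthetic nucleoprotein-filament localization data.
#
# A filament is a parametric curve in the sample plane (nm). Localizations are
# arc-length-uniform samples along the curve with isotropic Gaussian jitter
# (the localization precision). A tether of k units is one curve of total
# length = sum of the k unit lengths, with k - 1 junctions; an optional second
# channel carries a punctum of localizations at every junction.

#' Specify a synthetic filament localization scene
#'
#' @param geometry `"line"`, `"circle"` or `"curve"` (smooth wormlike curve).
#' @param unit_contour_length_nm Mean contour length of one filament unit.
#'   Default 2100 nm, the length scale of single RAD51-ssDNA nucleoprotein
#'   filaments.
#' @param unit_length_sd_nm SD of per-unit length variation (0 = exact).
#' @param n_units_tethered Number k >= 1 of units joined end to end; a tether
#'   carries k - 1 junctions.
#' @param bundle_multiplicity Number of filament copies fanned about the curve
#'   midpoint (crossing there), emulating lateral bundling; >= 1.
#' @param bundle_angle_deg Angular offset between bundle members.
#' @param localization_density Expected localizations per nm of contour.
#' @param localization_sigma_nm Isotropic Gaussian localization jitter.
#' @param puncta_at_junctions If `TRUE`, emit a second-channel punctum at each
#'   junction.
#' @param puncta_n_locs Localizations per junction punctum.
#' @param puncta_sigma_nm Punctum spread (nm).
#' @param n_filaments Number of filaments (or bundles) in the field.
#' @param field_extent_nm Side of the square field (nm); `NULL` = sized to fit
#'   the longest filament.
#' @param min_separation_nm Minimum distance between distinct filaments
#'   (bundle members excepted); emulates fields of well-separated single
#'   complexes.
#' @param persistence_nm Heading decorrelation length for `"curve"` geometry.
#' @param pixel_size_nm Camera pixel size used for the px columns.
#' @param seed Integer seed.
#' @return A `filament_scene_spec` list.
#' @export
filament_scene_spec <- function(geometry = c("line", "circle", "curve"),
                                unit_contour_length_nm = 2100,
                                unit_length_sd_nm = 0,
                                n_units_tethered = 1,
                                bundle_multiplicity = 1,
                                bundle_angle_deg = 12,
                                localization_density = 0.1,
                                localization_sigma_nm = 15,
                                puncta_at_junctions = FALSE,
                                puncta_n_locs = 30,
                                puncta_sigma_nm = 25,
                                n_filaments = 1,
                                field_extent_nm = NULL,
                                min_separation_nm = 500,
                                persistence_nm = 30000,
                                pixel_size_nm = 108,
                                seed = 1) {
  geometry <- match.arg(geometry)
  if (localization_density <= 0) abort("`localization_density` must be > 0.")
  if (n_units_tethered < 1) abort("`n_units_tethered` must be >= 1.")
  if (bundle_multiplicity < 1) abort("`bundle_multiplicity` must be >= 1.")
  if (unit_contour_length_nm <= 0) abort("`unit_contour_length_nm` must be > 0.")
  structure(
    list(geometry = geometry,
         unit_contour_length_nm = unit_contour_length_nm,
         unit_length_sd_nm = unit_length_sd_nm,
         n_units_tethered = as.integer(n_units_tethered),
         bundle_multiplicity = as.integer(bundle_multiplicity),
         bundle_angle_deg = bundle_angle_deg,
         localization_density = localization_density,
         localization_sigma_nm = localization_sigma_nm,
         puncta_at_junctions = isTRUE(puncta_at_junctions),
         puncta_n_locs = as.integer(puncta_n_locs),
         puncta_sigma_nm = puncta_sigma_nm,
         n_filaments = as.integer(n_filaments),
         field_extent_nm = field_extent_nm,
         min_separation_nm = min_separation_nm,
         persistence_nm = persistence_nm,
         pixel_size_nm = pixel_size_nm,
         seed = seed),
    class = "filament_scene_spec")
}

# Build one centered curve of given total length; returns list(points, cum,
# closed). Points are an n x 2 matrix (x, y) in nm, step ~5 nm.
build_curve <- function(geometry, total_length, persistence_nm, step = 5) {
  if (geometry == "circle") {
    R <- total_length / (2 * pi)
    n <- max(64, ceiling(total_length / step))
    th <- seq(0, 2 * pi, length.out = n + 1)
    pts <- cbind(R * cos(th), R * sin(th))
    closed <- TRUE
  } else if (geometry == "line") {
    n <- max(2, ceiling(total_length / step))
    s <- seq(0, total_length, length.out = n + 1)
    pts <- cbind(s - total_length / 2, rep(0, n + 1))
    closed <- FALSE
  } else {
    n <- max(2, ceiling(total_length / step))
    ds <- total_length / n
    dth <- rnorm(n, sd = sqrt(ds / persistence_nm))
    th <- cumsum(c(runif(1, 0, 2 * pi), dth))[seq_len(n)]
    pts <- rbind(c(0, 0), cbind(cumsum(ds * cos(th)), cumsum(ds * sin(th))))
    pts <- sweep(pts, 2, colMeans(pts))
    closed <- FALSE
  }
  seg <- sqrt(rowSums(diff(pts)^2))
  list(points = pts, cum = c(0, cumsum(seg)), closed = closed)
}

# Interpolate positions at arc lengths s along a curve.
curve_point_at <- function(curve, s) {
  cum <- curve$cum
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- pmax(findInterval(s, cum, rightmost.closed = TRUE), 1)
  f <- (s - cum[i]) / pmax(cum[i + 1] - cum[i], 1e-12)
  curve$points[i, , drop = FALSE] +
    (curve$points[i + 1, , drop = FALSE] - curve$points[i, , drop = FALSE]) * f
}

rotate_about <- function(pts, center, angle) {
  d <- sweep(pts, 2, center)
  cbind(center[1] + d[, 1] * cos(angle) - d[, 2] * sin(angle),
        center[2] + d[, 1] * sin(angle) + d[, 2] * cos(angle))
}

empty_loc_table <- function() {
  tibble(frame = integer(), x = numeric(), y = numeric(),
         x_nm = numeric(), y_nm = numeric(), photons = numeric(),
         sx = numeric(), sy = numeric(), precision_nm = numeric(),
         filament = integer())
}

#' Generate filament localization tables with ground truth
#'
#' Draws Poisson(`density` x arc length) localizations per filament, uniform
#' in arc length with isotropic Gaussian jitter, plus an optional junction
#' punctum channel. A tether of k units has exactly k - 1 junction puncta.
#'
#' @param spec A [filament_scene_spec()].
#' @return A list with `locs` (localization tibble), `puncta` (tibble, empty
#'   unless `puncta_at_junctions`), and `truth` (list: `filaments` tibble with
#'   id, closed flag, contour_length_nm, n_locs; `curves` list of polylines;
#'   `junctions` tibble of junction coordinates and arc positions;
#'   `field_extent_nm`, `pixel_size_nm`).
#' @export
make_filament_localizations <- function(spec) {
  stopifnot(inherits(spec, "filament_scene_spec"))
  k <- spec$n_units_tethered
  m <- spec$bundle_multiplicity
  sigma <- spec$localization_sigma_nm
  seeds <- split_seed(spec$seed, spec$n_filaments + 1)

  # expected size: longest plausible filament + margin
  exp_len <- k * (spec$unit_contour_length_nm + 3 * spec$unit_length_sd_nm)
  diam <- if (spec$geometry == "circle") exp_len / pi else exp_len
  extent <- spec$field_extent_nm %||% max(4000, 1.35 * diam + 1200)
  margin <- 0.08 * extent + 4 * sigma

  curves <- list(); fil_rows <- list(); junc_rows <- list()
  locs <- list(); punc <- list()
  fid <- 0L
  placed_samples <- list()  # coarse point samples of placed filaments

  for (i in seq_len(spec$n_filaments)) {
    made <- with_seed(seeds[i], {
      unit_lengths <- pmax(rnorm(k, spec$unit_contour_length_nm,
                                 spec$unit_length_sd_nm),
                           0.2 * spec$unit_contour_length_nm)
      total <- sum(unit_lengths)
      base <- build_curve(spec$geometry, total, spec$persistence_nm)
      # place: random rotation + center keeping the curve inside the field
      ok <- FALSE
      for (try in 1:500) {
        ang <- runif(1, 0, 2 * pi)
        pts <- rotate_about(base$points, c(0, 0), ang)
        span <- apply(pts, 2, range)
        lo <- margin - span[1, ]; hi <- (extent - margin) - span[2, ]
        if (!all(hi > lo)) next
        ctr <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
        pts <- sweep(pts, 2, ctr, `+`)
        sub <- pts[seq(1, nrow(pts), by = 10), , drop = FALSE]
        clash <- FALSE
        for (q in placed_samples) {
          d2 <- outer(sub[, 1], q[, 1], `-`)^2 + outer(sub[, 2], q[, 2], `-`)^2
          if (min(d2) < spec$min_separation_nm^2) {
            clash <- TRUE
            break
          }
        }
        if (!clash) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort("could not place all filaments; enlarge `field_extent_nm` or lower `min_separation_nm`.")
      }
      members <- lapply(seq_len(m), function(j) {
        if (m == 1) return(pts)
        a <- (j - (m + 1) / 2) * spec$bundle_angle_deg * pi / 180
        rotate_about(pts, colMeans(pts), a)
      })
      list(members = members, unit_lengths = unit_lengths, total = total,
           closed = base$closed)
    })
    placed_samples[[i]] <- do.call(rbind, lapply(made$members, function(p) {
      p[seq(1, nrow(p), by = 10), , drop = FALSE]
    }))

    for (j in seq_len(m)) {
      fid <- fid + 1L
      pts <- made$members[[j]]
      seg <- sqrt(rowSums(diff(pts)^2))
      curve <- list(points = pts, cum = c(0, cumsum(seg)), closed = made$closed)
      total <- curve$cum[length(curve$cum)]
      curves[[fid]] <- curve

      draw <- with_seed(seeds[i] + 7 * j, {
        n_loc <- rpois(1, spec$localization_density * total)
        s <- sort(runif(n_loc, 0, total))
        p <- curve_point_at(curve, s)
        p <- p + matrix(rnorm(2 * n_loc, sd = sigma), ncol = 2)
        ph <- rpois(n_loc, 1000)
        list(n_loc = n_loc, p = p, ph = ph)
      })
      n_loc <- draw$n_loc
      locs[[fid]] <- tibble(
        frame = seq_len(n_loc), x = draw$p[, 1] / spec$pixel_size_nm,
        y = draw$p[, 2] / spec$pixel_size_nm,
        x_nm = draw$p[, 1], y_nm = draw$p[, 2],
        photons = as.numeric(draw$ph), sx = 1.2, sy = 1.2,
        precision_nm = sigma, filament = fid)

      fil_rows[[fid]] <- tibble(
        id = fid, bundle = i, closed = made$closed,
        contour_length_nm = total, n_locs = n_loc)

      # junctions between consecutive units (k - 1 of them)
      if (k > 1) {
        s_j <- cumsum(made$unit_lengths)[seq_len(k - 1)] * (total / made$total)
        pj <- curve_point_at(curve, s_j)
        junc_rows[[length(junc_rows) + 1L]] <- tibble(
          filament = fid, junction = seq_len(k - 1),
          x_nm = pj[, 1], y_nm = pj[, 2], arc_nm = s_j)
        if (spec$puncta_at_junctions) {
          pp <- with_seed(seeds[i] + 1000 + j, {
            n <- spec$puncta_n_locs * (k - 1)
            ctr <- pj[rep(seq_len(k - 1), each = spec$puncta_n_locs), ,
                      drop = FALSE]
            ctr + matrix(rnorm(2 * n, sd = spec$puncta_sigma_nm), ncol = 2)
          })
          punc[[length(punc) + 1L]] <- tibble(
            frame = seq_len(nrow(pp)),
            x = pp[, 1] / spec$pixel_size_nm, y = pp[, 2] / spec$pixel_size_nm,
            x_nm = pp[, 1], y_nm = pp[, 2],
            photons = 1000, sx = 1.2, sy = 1.2,
            precision_nm = spec$puncta_sigma_nm, filament = fid)
        }
      }
    }
  }

  list(
    locs = if (length(locs)) bind_rows(locs) else empty_loc_table(),
    puncta = if (length(punc)) bind_rows(punc) else empty_loc_table(),
    truth = list(
      filaments = bind_rows(fil_rows),
      curves = curves,
      junctions = if (length(junc_rows)) bind_rows(junc_rows) else
        tibble(filament = integer(), junction = integer(), x_nm = numeric(),
               y_nm = numeric(), arc_nm = numeric()),
      field_extent_nm = extent,
      pixel_size_nm = spec$pixel_size_nm))
}
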