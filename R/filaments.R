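# Filament geometry from localization data: density mask -> skeleton ->
# traces with contour lengths, closed/open classification, clustering,
# inter-puncta spacing and two-channel colocalization.

#' Binary density mask from a localization table
#'
#' Renders the table at `sr_pixel_nm`, smooths with a Gaussian of width
#' `smooth_nm`, thresholds at `min_density` (smoothed counts per rendered
#' pixel), closes and hole-fills the binary mask (sampling fluctuations
#' otherwise punch holes that the skeleton would trace as spurious cycles),
#' and removes components smaller than `min_area_px`.
#'
#' @param table A localization tibble (needs `x_nm`, `y_nm`).
#' @param sr_pixel_nm Rendered pixel size (nm).
#' @param smooth_nm Gaussian smoothing width (nm).
#' @param min_density Threshold on the smoothed density.
#' @param min_area_px Minimum component area (rendered pixels).
#' @param extent_nm Optional render extent `c(xmin, xmax, ymin, ymax)`.
#' @return A logical matrix with attributes `sr_pixel_nm` and `origin_nm`.
#' @export
density_mask <- function(table, sr_pixel_nm = 10, smooth_nm = 30,
                         min_density = 0.012, min_area_px = 30,
                         extent_nm = NULL) {
  if (!nrow(table)) {
    out <- matrix(FALSE, 1, 1)
    attr(out, "sr_pixel_nm") <- sr_pixel_nm
    attr(out, "origin_nm") <- c(0, 0)
    return(out)
  }
  img <- render_localizations(table, sr_pixel_nm = sr_pixel_nm, blur = "none",
                              extent_nm = extent_nm)
  sm <- gaussian_smooth(img, smooth_nm / sr_pixel_nm)
  mask <- sm > min_density
  mask <- EBImage::closing(mask * 1L, EBImage::makeBrush(3, "box")) > 0
  mask <- fill_small_holes(mask)
  lab <- label_components(mask * 1L, connectivity = 8L)
  lab <- filter_small_components(lab, min_area_px)
  out <- lab > 0L
  attr(out, "sr_pixel_nm") <- sr_pixel_nm
  attr(out, "origin_nm") <- attr(img, "origin_nm")
  out
}

# Thinning retracts an open skeleton end by about the mask half-width, while
# density smoothing extends the mask past the true filament end by a little
# less; the true end lies between the skeleton end and the mask boundary.
# Extend each open end along its tangent to the midpoint of that bracket.
extend_trace_ends <- function(pts, mask, sr_pixel_nm, origin_nm,
                              max_steps = 40) {
  n <- nrow(pts)
  if (n < 5) return(pts)
  inside <- function(p) {
    i <- floor((p[2] - origin_nm[2]) / sr_pixel_nm) + 1
    j <- floor((p[1] - origin_nm[1]) / sr_pixel_nm) + 1
    i >= 1 && i <= nrow(mask) && j >= 1 && j <= ncol(mask) && mask[i, j]
  }
  extend_one <- function(pts, tip, ref) {
    tangent <- pts[tip, ] - pts[ref, ]
    len <- sqrt(sum(tangent^2))
    if (len == 0) return(pts)
    tangent <- tangent / len
    d <- 0
    for (t in seq_len(max_steps)) {
      if (!inside(pts[tip, ] + tangent * t * sr_pixel_nm)) break
      d <- t
    }
    if (d == 0) return(pts)
    new_pt <- pts[tip, ] + tangent * (d / 2) * sr_pixel_nm
    if (tip == 1) rbind(new_pt, pts) else rbind(pts, new_pt)
  }
  pts <- extend_one(pts, n, n - 4)
  extend_one(pts, 1, 5)
}

#' Trace filaments in a binary mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning), prunes spur branches shorter
#' than `prune_spur_nm`, and decomposes the skeleton graph into simple paths
#' and cycles (longest-path-first, deterministic). Each path becomes a
#' `FilamentTrace` row with its polyline (nm), closed flag and contour length
#' (Kulpa-corrected chain length; skeletonization slightly shortens open ends,
#' by roughly twice the effective localization spread).
#'
#' @param mask A logical matrix from [density_mask()] (or any binary mask;
#'   supply `sr_pixel_nm` / `origin_nm` if the attributes are absent).
#' @param prune_spur_nm Spur branches shorter than this are removed.
#' @param sr_pixel_nm,origin_nm Geometry of the mask grid; default taken from
#'   the mask attributes.
#' @return A `filament_traces` tibble: `trace_id`, `component`, `closed`,
#'   `length_nm`, `length_um`, `n_px`, plus list-columns `points_nm`
#'   (two-column matrix) and `arc_nm` (cumulative corrected arc length).
#'   Attribute `"components"` summarises each mask component (id, n_traces,
#'   max_degree).
#' @export
trace_filaments <- function(mask, prune_spur_nm = 100,
                            sr_pixel_nm = attr(mask, "sr_pixel_nm"),
                            origin_nm = attr(mask, "origin_nm")) {
  sr_pixel_nm <- sr_pixel_nm %||% 10
  origin_nm <- origin_nm %||% c(0, 0)
  empty <- tibble(trace_id = integer(), component = integer(),
                  closed = logical(), length_nm = numeric(),
                  length_um = numeric(), n_px = integer(),
                  points_nm = list(), arc_nm = list())
  if (!any(mask)) {
    return(structure(empty, class = c("filament_traces", class(empty)),
                     components = tibble(component = integer(),
                                         n_traces = integer(),
                                         max_degree = integer())))
  }
  comp_lab <- label_components(mask * 1L, connectivity = 8L)
  S <- thin_mask(mask)
  S <- prune_spurs(S, prune_px = prune_spur_nm / sr_pixel_nm)
  g <- skel_neighbors(S)
  if (!length(g$idx)) {
    return(structure(empty, class = c("filament_traces", class(empty)),
                     components = tibble(component = integer(),
                                         n_traces = integer(),
                                         max_degree = integer())))
  }
  deg <- lengths(g$nbr)
  arcs <- skel_arcs(g)
  # decompose per connected mask component so traces never bridge components
  arc_comp <- vapply(arcs, function(a) comp_lab[g$idx[a$pixels[1]]], integer(1))
  rows <- list(); comp_rows <- list()
  tid <- 0L
  for (cc in sort(unique(arc_comp))) {
    paths <- decompose_paths(g, arcs[arc_comp == cc])
    for (p in paths) {
      px <- p$pixels
      if (length(px) < 2) next
      pts <- cbind(x_nm = origin_nm[1] + (g$j[px] - 0.5) * sr_pixel_nm,
                   y_nm = origin_nm[2] + (g$i[px] - 0.5) * sr_pixel_nm)
      pts <- smooth_polyline(pts, closed = p$closed)
      if (!p$closed) {
        pts <- extend_trace_ends(pts, mask, sr_pixel_nm, origin_nm)
      }
      cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
      tid <- tid + 1L
      rows[[tid]] <- tibble(
        trace_id = tid, component = as.integer(cc), closed = p$closed,
        length_nm = cum[length(cum)],
        length_um = cum[length(cum)] / 1000,
        n_px = length(px),
        points_nm = list(pts),
        arc_nm = list(cum))
    }
    comp_px <- which(comp_lab[g$idx] == cc)
    comp_rows[[length(comp_rows) + 1L]] <- tibble(
      component = as.integer(cc),
      n_traces = sum(vapply(paths, function(p) length(p$pixels) >= 2,
                            logical(1))),
      max_degree = max(deg[comp_px], 0L))
  }
  out <- bind_rows(rows)
  structure(out, class = c("filament_traces", class(empty)),
            components = bind_rows(comp_rows))
}

#' @export
print.filament_traces <- function(x, ...) {
  cat(sprintf("<filament_traces> %d trace(s), %d closed\n",
              nrow(x), sum(x$closed)))
  if (nrow(x)) {
    print(as_tibble(x[, c("trace_id", "component", "closed", "length_um")]))
  }
  invisible(x)
}

#' Population statistics of filament lengths
#'
#' @param traces A `filament_traces` tibble (or any data frame with a
#'   `length_um` column).
#' @param threshold_um Length threshold for the "long filament" fraction.
#' @return A `population_stats` list: `lengths_um`, `mean_um`, `sd_um`,
#'   `fraction_above_threshold`, `threshold_um`, `n`.
#' @export
population_stats <- function(traces, threshold_um = 5) {
  if (!nrow(traces)) abort("no traces: population statistics undefined.")
  len <- traces$length_um
  structure(
    list(lengths_um = len, mean_um = mean(len),
         sd_um = if (length(len) >= 2) sd(len) else NA_real_,
         fraction_above_threshold = mean(len > threshold_um),
         threshold_um = threshold_um, n = length(len)),
    class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf(
    "<population_stats> n = %d: %.2f +/- %.2f um; %.0f%% above %g um\n",
    x$n, x$mean_um, x$sd_um, 100 * x$fraction_above_threshold,
    x$threshold_um))
  invisible(x)
}

#' Detect filament clusters
#'
#' A cluster is a connected mask component that contains at least two traces
#' or any skeleton junction (node of degree >= 3); isolated single filaments
#' (including closed circles, whose cycles carry no junction) are not
#' clusters.
#'
#' @param traces A `filament_traces` tibble from [trace_filaments()].
#' @return A tibble with one row per cluster: `cluster_id`, `component`,
#'   `n_traces`, `max_degree`, `trace_ids` (list-column).
#' @export
detect_clusters <- function(traces) {
  comps <- attr(traces, "components")
  if (is.null(comps)) abort("`traces` must come from trace_filaments().")
  cl <- filter(comps, .data$n_traces >= 2 | .data$max_degree >= 3)
  if (!nrow(cl)) {
    return(tibble(cluster_id = integer(), component = integer(),
                  n_traces = integer(), max_degree = integer(),
                  trace_ids = list()))
  }
  cl$cluster_id <- seq_len(nrow(cl))
  cl$trace_ids <- purrr::map(cl$component, function(cc) {
    traces$trace_id[traces$component == cc]
  })
  cl[, c("cluster_id", "component", "n_traces", "max_degree", "trace_ids")]
}

#' Inter-puncta spacing along a filament trace
#'
#' Clusters the second-channel localizations into puncta (single-linkage
#' within `cluster_radius_nm`), projects each punctum centroid onto the
#' nearest trace point, orders puncta by arc length and reports consecutive
#' spacings. Puncta farther than `assign_radius_nm` from the trace are
#' reported as unassigned.
#'
#' @param trace One trace: a row of a `filament_traces` tibble, or a
#'   two-column matrix of polyline points (nm).
#' @param puncta A localization tibble (`x_nm`, `y_nm`) for the punctum
#'   channel.
#' @param assign_radius_nm Maximum punctum-to-trace distance for assignment.
#' @param cluster_radius_nm Single-linkage cut distance when grouping
#'   localizations into puncta.
#' @return A `puncta_spacing_report`: list with `puncta` (tibble: punctum,
#'   x_nm, y_nm, n_locs, arc_nm, dist_nm, assigned), `spacings_nm`,
#'   `mean_nm`, `sd_nm`, `n_unassigned`.
#' @export
inter_puncta_spacing <- function(trace, puncta, assign_radius_nm = 150,
                                 cluster_radius_nm = 75) {
  if (is.data.frame(trace)) {
    if (nrow(trace) != 1) abort("pass a single trace (one row).")
    pts <- trace$points_nm[[1]]
    arc <- trace$arc_nm[[1]]
  } else {
    pts <- as.matrix(trace)
    seg <- sqrt(rowSums(diff(pts)^2))
    arc <- c(0, cumsum(seg))
  }
  if (nrow(pts) < 2) abort("degenerate trace.")
  if (!nrow(puncta)) {
    return(structure(list(
      puncta = tibble(punctum = integer(), x_nm = numeric(), y_nm = numeric(),
                      n_locs = integer(), arc_nm = numeric(),
                      dist_nm = numeric(), assigned = logical()),
      spacings_nm = numeric(), mean_nm = NA_real_, sd_nm = NA_real_,
      n_unassigned = 0L), class = "puncta_spacing_report"))
  }
  xy <- cbind(puncta$x_nm, puncta$y_nm)
  grp <- if (nrow(xy) == 1) 1L else {
    hc <- stats::hclust(stats::dist(xy), method = "single")
    stats::cutree(hc, h = cluster_radius_nm)
  }
  cent <- t(vapply(split(seq_len(nrow(xy)), grp), function(ix) {
    c(mean(xy[ix, 1]), mean(xy[ix, 2]), length(ix))
  }, numeric(3)))
  # nearest trace vertex per punctum centroid
  proj <- t(vapply(seq_len(nrow(cent)), function(k) {
    d2 <- (pts[, 1] - cent[k, 1])^2 + (pts[, 2] - cent[k, 2])^2
    i <- which.min(d2)
    c(arc[i], sqrt(d2[i]))
  }, numeric(2)))
  rep_tbl <- tibble(punctum = seq_len(nrow(cent)),
                    x_nm = cent[, 1], y_nm = cent[, 2],
                    n_locs = as.integer(cent[, 3]),
                    arc_nm = proj[, 1], dist_nm = proj[, 2],
                    assigned = proj[, 2] <= assign_radius_nm)
  asg <- arrange(filter(rep_tbl, .data$assigned), .data$arc_nm)
  spac <- if (nrow(asg) >= 2) diff(asg$arc_nm) else numeric()
  structure(list(
    puncta = rep_tbl, spacings_nm = spac,
    mean_nm = if (length(spac)) mean(spac) else NA_real_,
    sd_nm = if (length(spac) >= 2) sd(spac) else NA_real_,
    n_unassigned = sum(!rep_tbl$assigned)),
    class = "puncta_spacing_report")
}

#' @export
print.puncta_spacing_report <- function(x, ...) {
  cat(sprintf(
    "<puncta_spacing_report> %d punctum(a), %d spacing(s), mean = %.0f nm\n",
    nrow(x$puncta), length(x$spacings_nm), x$mean_nm))
  invisible(x)
}

#' Two-channel colocalization fraction
#'
#' Fraction of channel-A localizations with at least one channel-B
#' localization within `radius_nm`, and the symmetric B-near-A variant.
#'
#' @param locs_a,locs_b Localization tibbles with `x_nm`, `y_nm`.
#' @param radius_nm Search radius (> 0).
#' @return A one-row tibble: `fraction_ab`, `fraction_ba`, `radius_nm`.
#' @export
colocalization_fraction <- function(locs_a, locs_b, radius_nm) {
  if (radius_nm <= 0) abort("`radius_nm` must be > 0.")
  if (!nrow(locs_a) || !nrow(locs_b)) abort("both tables must be non-empty.")
  frac <- function(A, B) {
    # cell-list search on a grid of side radius_nm
    bx <- floor(B$x_nm / radius_nm); by <- floor(B$y_nm / radius_nm)
    key <- paste(bx, by)
    cells <- split(seq_len(nrow(B)), key)
    ax <- floor(A$x_nm / radius_nm); ay <- floor(A$y_nm / radius_nm)
    hit <- vapply(seq_len(nrow(A)), function(k) {
      for (dx in -1:1) for (dy in -1:1) {
        ix <- cells[[paste(ax[k] + dx, ay[k] + dy)]]
        if (!is.null(ix)) {
          d2 <- (B$x_nm[ix] - A$x_nm[k])^2 + (B$y_nm[ix] - A$y_nm[k])^2
          if (any(d2 <= radius_nm^2)) return(TRUE)
        }
      }
      FALSE
    }, logical(1))
    mean(hit)
  }
  tibble(fraction_ab = frac(locs_a, locs_b),
         fraction_ba = frac(locs_b, locs_a),
         radius_nm = radius_nm)
}
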