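# Droplet-edge quantification of phase separation from brightfield images.
#
# The degree of phase separation in a brightfield field of view is measured as
# the fraction of pixels whose intensity-gradient magnitude (5-tap
# Farid-Simoncelli derivative filter) exceeds k standard deviations of the
# gradient image. In-focus droplets contribute sharp rims; out-of-focus
# droplets and smooth optical speckle fall below the threshold. Sample values
# are averaged over the fields of view and normalized by a
# non-phase-separating reference imaged with the same optics.

# Farid-Simoncelli 5-tap optimal derivative pair: smoothing prefilter and
# antisymmetric derivative kernel, applied separably as correlation.
farid_p <- c(0.037659, 0.249153, 0.426375, 0.249153, 0.037659)
farid_d <- c(-0.109604, -0.276691, 0.000000, 0.276691, 0.109604)

#' Farid derivative-filter gradient magnitude
#'
#' Per-pixel gradient magnitude `sqrt(gx^2 + gy^2)` from the 5-tap
#' Farid-Simoncelli separable derivative estimates (derivative along one axis,
#' matched smoothing prefilter along the other). Borders are handled by
#' reflection padding.
#'
#' @param image A numeric matrix, at least 5 x 5 pixels.
#' @return A matrix of gradient magnitudes, same shape as `image`.
#' @export
farid_gradient <- function(image) {
  assert_image(image, min_dim = 5L)
  gx <- sep_filter(image, farid_p, farid_d)
  gy <- sep_filter(image, farid_d, farid_p)
  sqrt(gx^2 + gy^2)
}

#' Droplet-edge fractional area of one field of view
#'
#' Computes the Farid gradient-magnitude map, its standard deviation sigma
#' over all pixels, and returns the fraction of pixels strictly exceeding
#' `k_sd * sigma`. A constant field (sigma = 0) returns 0.
#'
#' @param image A numeric matrix (one field of view).
#' @param k_sd Threshold multiplier (default 10 standard deviations).
#' @return A dimensionless fraction in \[0, 1\].
#' @export
edge_fraction <- function(image, k_sd = 10) {
  g <- farid_gradient(image)
  s <- sd(g)
  if (!is.finite(s) || s == 0) return(0)
  mean(g > k_sd * s)
}

#' Summarize the edge-fraction statistic over a sample's fields of view
#'
#' Applies [edge_fraction()] to every field and reports the per-field values,
#' their mean and sample standard deviation. With a single field the mean is
#' returned and the SD flagged undefined (`NA`).
#'
#' @param images An [image_set()] (or list of matrices).
#' @param k_sd Threshold multiplier passed to [edge_fraction()].
#' @return An `edge_fraction_measurement`: list with `per_field` (tibble:
#'   field, fraction), `mean`, `sd`, `k_sd`, `n_fields`.
#' @export
summarize_sample <- function(images, k_sd = 10) {
  if (is.matrix(images)) images <- list(images)
  fr <- vapply(images, edge_fraction, numeric(1), k_sd = k_sd)
  if (length(fr) < 2) {
    warn("single field of view: sample SD is undefined (NA).")
  }
  structure(
    list(per_field = tibble(field = seq_along(fr), fraction = fr),
         mean = mean(fr),
         sd = if (length(fr) >= 2) sd(fr) else NA_real_,
         k_sd = k_sd, n_fields = length(fr)),
    class = "edge_fraction_measurement")
}

#' @export
print.edge_fraction_measurement <- function(x, ...) {
  cat(sprintf(
    "<edge_fraction_measurement> %d field(s), k_sd = %g\n  mean = %.4g, sd = %.4g\n",
    x$n_fields, x$k_sd, x$mean, x$sd))
  invisible(x)
}

#' Normalize an edge-fraction measurement to a reference sample
#'
#' Divides the sample mean by the mean of a non-phase-separating reference
#' imaged with the same optics, removing the speckle contribution; the
#' reported error is the sample SD over the reference mean. A reference
#' normalized against itself yields exactly 1.
#'
#' @param sample,reference `edge_fraction_measurement` objects from
#'   [summarize_sample()].
#' @return A `normalized_phase_separation`: list with `value` and `error`.
#' @export
normalize_to_reference <- function(sample, reference) {
  stopifnot(inherits(sample, "edge_fraction_measurement"),
            inherits(reference, "edge_fraction_measurement"))
  if (!is.finite(reference$mean) || reference$mean <= 0) {
    abort(paste(
      "reference mean edge fraction is 0: the reference must contain the",
      "shared optical background (speckle); include it in the reference",
      "sample or generator."))
  }
  structure(list(value = sample$mean / reference$mean,
                 error = if (is.na(sample$sd)) NA_real_ else
                   sample$sd / reference$mean),
            class = "normalized_phase_separation")
}

#' @export
print.normalized_phase_separation <- function(x, ...) {
  cat(sprintf("<normalized_phase_separation> value = %.4g +/- %.4g\n",
              x$value, x$error))
  invisible(x)
}

#' Assemble a phase-separation state diagram
#'
#' Computes the reference-normalized edge-fraction statistic for every
#' condition in a grid (e.g. crowder concentration x protein concentration)
#' and returns a tidy diagram table.
#'
#' @param conditions A data frame with one row per condition: one or more
#'   axis columns (e.g. `peg_pct`, `protein_uM`) and a list-column `images`
#'   of [image_set()]s (or lists of matrices).
#' @param reference An [image_set()] for the non-phase-separating reference.
#' @param k_sd Threshold multiplier.
#' @return A `state_diagram` tibble: the axis columns plus `value`, `error`,
#'   `mean_fraction`, `sd_fraction`.
#' @export
build_state_diagram <- function(conditions, reference, k_sd = 10) {
  if (!is.data.frame(conditions) || !"images" %in% names(conditions)) {
    abort("`conditions` must be a data frame with a list-column `images`.")
  }
  axes <- setdiff(names(conditions), "images")
  if (!length(axes)) abort("`conditions` needs at least one axis column.")
  if (anyDuplicated(conditions[axes])) {
    abort("duplicate grid coordinates in `conditions`.")
  }
  shp <- dim(conditions$images[[1]][[1]])
  for (s in conditions$images) {
    if (!identical(dim(s[[1]]), shp)) {
      abort("all image sets must share one field shape.")
    }
  }
  ref <- summarize_sample(reference, k_sd = k_sd)
  rows <- purrr::map(seq_len(nrow(conditions)), function(i) {
    meas <- summarize_sample(conditions$images[[i]], k_sd = k_sd)
    nrm <- normalize_to_reference(meas, ref)
    tibble(value = nrm$value, error = nrm$error,
           mean_fraction = meas$mean, sd_fraction = meas$sd)
  })
  out <- dplyr::bind_cols(conditions[axes], bind_rows(rows))
  out <- arrange(out, across(all_of(axes)))
  class(out) <- c("state_diagram", class(out))
  attr(out, "axes") <- axes
  attr(out, "k_sd") <- k_sd
  out
}

#' Write a state diagram to CSV
#'
#' @param x A `state_diagram` from [build_state_diagram()].
#' @param path Output CSV path (axes as leading columns).
#' @return `path`, invisibly.
#' @export
write_state_diagram <- function(x, path) {
  stopifnot(inherits(x, "state_diagram"))
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}
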