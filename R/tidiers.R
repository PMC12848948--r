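# broom-style tidiers so every measurement object drops into a dplyr
# pipeline: tidy() gives the per-unit table, glance() the one-row summary.

#' @export
tidy.edge_fraction_measurement <- function(x, ...) {
  x$per_field
}

#' @export
glance.edge_fraction_measurement <- function(x, ...) {
  tibble(mean_fraction = x$mean, sd_fraction = x$sd,
         n_fields = x$n_fields, k_sd = x$k_sd)
}

#' @export
glance.normalized_phase_separation <- function(x, ...) {
  tibble(value = x$value, error = x$error)
}

#' @export
tidy.partition_summary <- function(x, ...) {
  x$per_condensate
}

#' @export
glance.partition_summary <- function(x, ...) {
  tibble(mean_pc = x$mean, sd_pc = x$sd, n_condensates = x$n_condensates,
         background_intensity = x$background_intensity)
}

#' @export
tidy.filament_traces <- function(x, ...) {
  as_tibble(x[, c("trace_id", "component", "closed", "length_nm",
                  "length_um", "n_px")])
}

#' @export
glance.population_stats <- function(x, ...) {
  tibble(mean_um = x$mean_um, sd_um = x$sd_um,
         fraction_above_threshold = x$fraction_above_threshold,
         threshold_um = x$threshold_um, n = x$n)
}

#' @export
tidy.population_stats <- function(x, ...) {
  tibble(length_um = x$lengths_um)
}

#' @export
tidy.puncta_spacing_report <- function(x, ...) {
  x$puncta
}

#' @export
glance.puncta_spacing_report <- function(x, ...) {
  tibble(mean_spacing_nm = x$mean_nm, sd_spacing_nm = x$sd_nm,
         n_spacings = length(x$spacings_nm), n_unassigned = x$n_unassigned)
}
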