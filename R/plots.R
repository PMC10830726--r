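# ggplot2 displays for the main result types.

#' @describeIn calibrate_threshold Replicate-pair distance distributions
#'   per class, with the proposed threshold as a dashed line.
#' @param object The object to plot.
#' @export
autoplot.calibration <- function(object, ...) {
  ggplot2::ggplot(object$pair_distances,
                  ggplot2::aes(x = .data$replicate_class, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$proposed_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "replicate class",
                  y = sprintf("%s distance", object$metric),
                  title = sprintf("Replicate distances (proposed threshold %g)",
                                  object$proposed_threshold)) +
    ggplot2::theme_minimal()
}

#' @describeIn threshold_sweep MLG, distinct and redundant counts against
#'   the threshold.
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("n_mlgs", "n_single", "n_redundant"),
                        names_to = "series", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$count,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance threshold", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn collapse_mlg MLG size distribution as a bar chart.
#' @param object An `mlg_partition`.
#' @export
autoplot.mlg_partition <- function(object, ...) {
  sd <- attr(object, "size_distribution")
  ggplot2::ggplot(sd, ggplot2::aes(x = factor(.data$size), y = .data$n_mlgs)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "MLG size (accessions)", y = "number of MLGs") +
    ggplot2::theme_minimal()
}

#' @describeIn region_summary Stacked per-region composition of MLG size
#'   categories.
#' @param object A `region_summary`.
#' @param ... Unused.
#' @export
autoplot.region_summary <- function(object, ...) {
  long <- as_tibble(object) |>
    dplyr::select("region", "C1", "C2", "C3-C5", "C6+") |>
    tidyr::pivot_longer(-"region", names_to = "category", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$n,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "accessions", fill = "MLG size") +
    ggplot2::theme_minimal()
}
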