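#' Plot per-sample key metrics on a log scale
#'
#' One point per sample showing tumor load with its detection and
#' quantification limits, per assay, samples ordered by tumor load.
#' Horizontal dashed lines mark the supplied MRD cut-offs. Samples with a
#' zero tumor load (no clone detected) are drawn at the bottom of the axis
#' as open triangles.
#'
#' @param measurements Measurement table.
#' @param cutoffs Cut-off values to mark. Default [mrd_cutoffs()].
#' @param constants An [assay_constants()] object.
#' @return A ggplot object.
#' @export
plot_key_metrics <- function(measurements, cutoffs = mrd_cutoffs()$value,
                             constants = assay_constants()) {
  require_ggplot()
  metrics <- mrd_key_metrics(measurements, constants) |>
    dplyr::arrange(.data$assay, .data$tl) |>
    dplyr::mutate(idx = dplyr::row_number(), .by = "assay")
  floor_tl <- min(c(metrics$lod, metrics$tl[metrics$tl > 0])) / 10
  long <- metrics |>
    dplyr::mutate(tl_plot = pmax(.data$tl, floor_tl),
                  detected = .data$tl > 0) |>
    tidyr::pivot_longer(c("tl_plot", "lod", "loq"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$idx, y = .data$value,
                                     colour = .data$metric,
                                     shape = .data$detected)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = cutoffs, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 2),
                                guide = "none") +
    ggplot2::facet_wrap(~assay, scales = "free_x") +
    ggplot2::labs(x = "sample (ordered by tumor load)",
                  y = "fraction of assayed cells", colour = NULL)
}

#' Plot the MRD cut-off sweep as stacked status bars
#'
#' @param sweep Result of [sweep_cutoffs()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  require_ggplot()
  long <- sweep |>
    tidyr::pivot_longer(dplyr::all_of(.mrd_statuses), names_to = "status",
                        values_to = "count") |>
    dplyr::mutate(status = factor(.data$status, levels = .mrd_statuses),
                  cutoff = factor(format(.data$cutoff, scientific = TRUE),
                                  levels = format(sort(unique(.data$cutoff),
                                                       decreasing = TRUE),
                                                  scientific = TRUE)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$count,
                                     fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~assay) +
    ggplot2::labs(x = "MRD cut-off", y = "samples", fill = NULL)
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}
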