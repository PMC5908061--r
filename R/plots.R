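#' Plot a windowed diversity scan
#'
#' Per-bp diversity and Tajima's D along the region.
#'
#' @param object A `window_scan` tibble from [windowed_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_scan
#' @export
autoplot.window_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, mid = (.data$start + .data$end) / 2),
    c("pi_per_bp", "tajimas_d"), names_to = "statistic"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$mid, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL)
}

#' Plot standardized iHS scores
#'
#' Extreme scores (|iHS| > 2) highlighted.
#'
#' @param object An `ihs_scan` tibble from [standardize_ihs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ihs_scan
#' @export
autoplot.ihs_scan <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$ihs))
  ggplot2::ggplot(d, ggplot2::aes(.data$pos, .data$ihs,
                                  colour = .data$extreme)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "position (bp)", y = "iHS", colour = "|iHS| > 2")
}

#' Plot an EHH decay curve
#'
#' @param object An `ehh_curve` from [ehh()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ehh_curve
#' @export
autoplot.ehh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$offset, .data$ehh)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance from core (bp)", y = "EHH") +
    ggplot2::ylim(0, 1)
}

#' Plot a compound CLR + omega track
#'
#' Both statistics per bin with common outliers marked.
#'
#' @param object A `compound_track` from [compound_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot compound_track
#' @export
autoplot.compound_track <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, mid = (.data$bin_start + .data$bin_end) / 2),
    c("clr", "omega"), names_to = "statistic"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$mid, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(data = dplyr::filter(long, .data$common_outlier),
                        colour = "red", na.rm = TRUE) +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL)
}
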