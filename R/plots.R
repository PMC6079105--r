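#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rank-abundance plot of a classified library
#'
#' @param object An `abundance_tbl`.
#' @param top Show the `top` most abundant designs.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abundance_tbl
#' @export
autoplot.abundance_tbl <- function(object, top = 30, ...) {
  df <- dplyr::slice_max(tibble::as_tibble(object), .data$frequency,
                         n = top, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$design, -.data$frequency),
    y = .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "frequency among assigned reads",
                  title = unique(df$library_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Pre/post enrichment scatter
#'
#' Each point is a design; the dashed line marks the abundance threshold on
#' the post-enrichment frequency.
#'
#' @param object An `enrichment_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_report
#' @export
autoplot.enrichment_report <- function(object, ...) {
  theta <- attr(object, "theta")
  pseudo <- attr(object, "pseudo")
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$freq_pre + pseudo, y = .data$freq_post + pseudo,
    colour = .data$passes_abundance_threshold)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = theta, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency before selection", y = "frequency after selection",
                  colour = sprintf("post ≥ %.2g", theta)) +
    ggplot2::theme_minimal()
}

#' Enrichment trajectories across sorting rounds
#'
#' @param object An `enrichment_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_sim
#' @export
autoplot.enrichment_sim <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$round, y = .data$frequency, group = .data$design)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "sorting round", y = "design frequency") +
    ggplot2::theme_minimal()
}

#' Assembly-class composition of a design manifest
#'
#' @param designs Tibble from [enumerate_chimeras()].
#' @return A ggplot of design counts per eLCR class.
#' @export
plot_class_distribution <- function(designs) {
  ggplot2::ggplot(dplyr::count(designs, .data$assembly_class),
                  ggplot2::aes(x = .data$assembly_class, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "eLCR assembly class", y = "designs") +
    ggplot2::theme_minimal()
}
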