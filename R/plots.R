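# ggplot2 presentation methods.

#' Plot segregation estimates
#'
#' Dot-and-interval display of an `exposeg_estimate` tibble (one dot per
#' stratum/method, CI whiskers when present).
#'
#' @param object An `exposeg_estimate` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exposeg_estimate <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       label = ifelse(is.na(.data$stratum) |
                                        .data$stratum == "overall",
                                      .data$method,
                                      paste(.data$method, .data$stratum)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "exposure segregation (correlation)", y = NULL) +
    ggplot2::xlim(min(0, min(dat$estimate, na.rm = TRUE)), 1) +
    ggplot2::theme_minimal()
}

#' Plot a bridging-index decomposition
#'
#' Cluster sizes against within-cluster diversity, with the region-wide
#' diversity as a reference line.
#'
#' @param object An `exposeg_bridging` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exposeg_bridging <- function(object, ...) {
  ggplot2::ggplot(object$clusters,
                  ggplot2::aes(x = .data$size, y = .data$diversity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$overall_diversity,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "cluster size (residents)",
      y = paste0("within-cluster diversity (", object$measure, ")"),
      title = sprintf("bridging index = %.3f", object$index)) +
    ggplot2::theme_minimal()
}

#' Map a synthetic city
#'
#' Tract boundaries, homes coloured by SES, POIs and hub outlines.
#'
#' @param object An `exposeg_city`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exposeg_city <- function(object, ...) {
  ring_df <- function(layer) {
    purrr::map_dfr(seq_len(nrow(layer)), function(i) {
      g <- layer$geometry[[i]]
      tibble::tibble(id = layer$id[i], lon = c(g[, 1], g[1, 1]),
                     lat = c(g[, 2], g[1, 2]))
    })
  }
  ggplot2::ggplot() +
    ggplot2::geom_path(data = ring_df(object$tract_layer),
                       ggplot2::aes(.data$lon, .data$lat,
                                    group = .data$id),
                       colour = "grey75", linewidth = 0.3) +
    ggplot2::geom_point(data = object$individuals,
                        ggplot2::aes(.data$true_lon, .data$true_lat,
                                     colour = log(.data$true_ses)),
                        size = 0.5, alpha = 0.7) +
    ggplot2::geom_path(data = ring_df(object$hub_layer),
                       ggplot2::aes(.data$lon, .data$lat,
                                    group = .data$id),
                       colour = "black", linewidth = 0.5) +
    ggplot2::scale_colour_viridis_c(name = "log rent") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
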