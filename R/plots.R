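#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' the annual PFC series with the benchmark bands, the ACF/PACF
#' correlogram with its 95% significance bounds, the AICc ranking, and the
#' simulated population trajectory.
#'
#' @param object A `pfc_series`, `pfc_correlogram`, `pfc_ranking` or
#'   `pfc_sim` object.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name pfc-autoplot
NULL

#' @rdname pfc-autoplot
#' @export
autoplot.pfc_series <- function(object, ...) {
  bands <- benchmark_bands()
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$pfc)) +
    ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE,
      ggplot2::aes(
        xmin = -Inf, xmax = Inf, ymin = .data$lower, ymax = .data$upper,
        fill = .data$label
      ), alpha = 0.15
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", name = "benchmark") +
    ggplot2::labs(x = "year", y = "proportion of females calving") +
    ggplot2::theme_minimal()
}

#' @rdname pfc-autoplot
#' @export
autoplot.pfc_correlogram <- function(object, ...) {
  bound <- attr(object, "bound")
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("acf", "pacf"),
    names_to = "kind", values_to = "value"
  )
  long <- long[!(long$kind == "pacf" & long$lag == 0), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_hline(
      yintercept = c(-bound, bound),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::facet_wrap(~kind, ncol = 1, labeller = ggplot2::labeller(
      kind = c(acf = "ACF", pacf = "partial ACF")
    )) +
    ggplot2::labs(x = "lag (years)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname pfc-autoplot
#' @export
autoplot.pfc_ranking <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$model <- factor(d$model, levels = rev(d$model))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$delta, y = .data$model,
    colour = .data$in_confidence_set
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "grey60"),
      name = "confidence set"
    ) +
    ggplot2::labs(x = expression(Delta * AICc), y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname pfc-autoplot
#' @export
autoplot.pfc_sim <- function(object, ...) {
  cen <- object$census
  d <- tibble::tibble(year = cen$year, total = cen$total)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$total)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(shape = 1) +
    ggplot2::labs(x = "year", y = "population size") +
    ggplot2::theme_minimal()
  if (!is.null(object$pfc)) {
    scale <- max(d$total)
    p <- p +
      ggplot2::geom_line(
        data = object$pfc,
        ggplot2::aes(y = .data$pfc * scale), colour = "black"
      ) +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / scale, name = "PFC")
      )
  }
  p
}
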