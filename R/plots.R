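#' Histogram of sampled v100 outcomes
#'
#' One facet per tissue: the sampled v100 histogram with the nominal
#' outcome marked by a vertical line. Bin widths follow Freedman-Diaconis
#' on each tissue's pooled sample.
#'
#' @param object An `outcome_distribution`.
#' @param bins Optional fixed bin count overriding Freedman-Diaconis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.outcome_distribution <- function(object, bins = NULL, ...) {
  samples <- object$samples
  nominal <- object$nominal
  if (is.null(bins)) {
    # Freedman-Diaconis per tissue; facets share a bin count, so take the
    # largest requirement (capped to a sane range)
    nb <- dplyr::summarise(
      dplyr::group_by(samples, .data$tissue),
      n = diff(range(.data$v100)) / fd_binwidth(.data$v100),
      .groups = "drop"
    )
    bins <- min(60, max(10, ceiling(max(nb$n, na.rm = TRUE))))
  }
  p <- ggplot2::ggplot(samples, ggplot2::aes(x = .data$v100)) +
    ggplot2::facet_wrap(~tissue, scales = "free") +
    ggplot2::geom_vline(
      data = nominal, ggplot2::aes(xintercept = .data$v100),
      colour = "red"
    ) +
    ggplot2::labs(
      x = "v100 (tumour: % volume; OAR: mm³)", y = "samples",
      title = sprintf("%s position-uncertainty outcomes", object$mode)
    )
  p + ggplot2::geom_histogram(bins = bins)
}

fd_binwidth <- function(v) {
  iqr <- stats::IQR(v)
  if (iqr <= 0) {
    return(max(diff(range(v)) / 10, 1e-6))
  }
  2 * iqr / length(v)^(1 / 3)
}

#' Axial fluence slice plot
#'
#' Tile map of the fluence field on the element layer closest to a given
#' height, with region boundaries drawn from the labels.
#'
#' @param model A `tissue_model`.
#' @param field Per-element fluence vector.
#' @param z Slice height, mm (default: domain centre).
#' @return A ggplot object.
#' @export
plot_fluence_slice <- function(model, field, z = NULL) {
  el <- dplyr::mutate(model$elements, phi = field)
  z <- z %||% (model$grid$domain[3] / 2)
  zs <- unique(el$z)
  znear <- zs[which.min(abs(zs - z))]
  sl <- dplyr::filter(el, abs(.data$z - znear) < 1e-9)
  ggplot2::ggplot(sl, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(pmax(.data$phi, 1e-12)))) +
    ggplot2::geom_point(
      data = dplyr::filter(sl, .data$region == "tumour"),
      shape = ".", colour = "white"
    ) +
    ggplot2::scale_fill_viridis_c(name = "log10 fluence") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)",
      title = sprintf("fluence slice near z = %.1f mm", znear)
    )
}

#' Annealing trace plot
#'
#' Best-so-far and proposed costs against iteration, with temperature
#' stages shaded.
#'
#' @param object An `sa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sa_result <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$cost, colour = .data$accepted),
      alpha = 0.4, size = 0.8, na.rm = TRUE
    ) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_cost), linewidth = 0.7) +
    ggplot2::labs(
      x = "proposal", y = "cost",
      title = "simulated-annealing placement optimization"
    )
}
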