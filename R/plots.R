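# ggplot2 views of the three assay result types.

#' Plot an MFI panel grouped by MICA type
#'
#' @param panel Long tibble with columns `allele`, `mfi` (replicates are
#'   averaged per allele) and optionally `reagent`.
#' @param calls Type calls from [classify_alleles()].
#' @return A ggplot object: per-allele points over per-type boxplots,
#'   facetted by reagent when present.
#' @export
plot_mfi_panel <- function(panel, calls) {
  has_reagent <- "reagent" %in% names(panel)
  grp <- if (has_reagent) c("allele", "reagent") else "allele"
  avg <- panel |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(mfi = mean(.data$mfi), .groups = "drop") |>
    dplyr::left_join(calls[, c("allele", "type")], by = "allele")
  p <- ggplot2::ggplot(avg, ggplot2::aes(x = .data$type, y = .data$mfi)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "MFI")
  if (has_reagent) {
    p <- p + ggplot2::facet_wrap(~reagent, scales = "free_y")
  }
  p
}

#' @rdname fit_sigmoid
#' @param object A `sigmoid_fit`.
#' @param ... Ignored.
#' @importFrom ggplot2 autoplot
#' @method autoplot sigmoid_fit
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  rng <- range(object$data$dose)
  grid <- tibble::tibble(
    dose = exp(seq(log(rng[1]), log(rng[2]), length.out = 200))
  )
  grid$response <- predict(object, grid)
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (µg/mL)", y = "%GFP+ reporter cells")
  if (!is.na(object$ec50)) {
    p <- p + ggplot2::geom_vline(xintercept = object$ec50, linetype = "dotted")
  }
  p
}

#' @export
ggplot2::autoplot

#' Plot killing curves across E:T ratios
#'
#' @param curves One or more curves from [build_killing_curve()]
#'   (rows may cover several targets).
#' @return A ggplot object: mean efficiency vs E:T ratio with SD ribbons,
#'   one line per target.
#' @export
plot_killing_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$ratio, y = .data$mean_efficiency,
    colour = .data$target, group = .data$target
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_efficiency - .data$sd_efficiency,
      ymax = .data$mean_efficiency + .data$sd_efficiency,
      fill = .data$target
    ), alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "E:T ratio", y = "killing efficiency (%)")
}
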