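# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a knockout screen
#'
#' Growth ratio per gene, coloured by the essentiality call.
#'
#' @param object A `knockout_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.knockout_screen <- function(object, ...) {
  df <- object$results
  df$gene <- stats::reorder(df$gene, df$ratio)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$ratio,
                                   fill = .data$essential)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "knockout / wild-type growth",
                  fill = "essential",
                  title = paste0("Knockout screen (", object$method, ")")) +
    ggplot2::theme_minimal()
}

#' Plot measured against fitted fluxes
#'
#' @param comparison The `comparison` tibble from [compare_flux_fits()].
#' @return A ggplot object.
#' @export
plot_flux_fit <- function(comparison) {
  long <- rbind(
    data.frame(reaction_id = comparison$reaction_id,
               measured = comparison$measured,
               fitted = comparison$fba_fit, model = "FBA"),
    data.frame(reaction_id = comparison$reaction_id,
               measured = comparison$measured,
               fitted = comparison$ramp_fit, model = "RAMP"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measured, y = .data$fitted,
                                     colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "measured flux (mmol/gDW/h)",
                  y = "fitted flux (mmol/gDW/h)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
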