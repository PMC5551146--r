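# ggplot2 output for each result type.

#' Egg plot of classified compounds
#'
#' Draws the classical egg representation: the intestinal-absorption region
#' in grey ("white" of the egg), the brain-permeation region in yellow
#' ("yolk"), and one point per compound in (tPSA, WLogP) space.
#'
#' @param predictions output of [classify_permeation()].
#' @param model the `egg_model` used for classification.
#' @param label_points label points by `id` (sensible for small sets only).
#' @return a ggplot object.
#' @export
plot_boiled_egg <- function(predictions, model = boiled_egg_model(),
                            label_points = FALSE) {
  pd <- egg_plot_data(predictions, model)
  white <- pd$outlines[pd$outlines$region == "intestinal", ]
  yolk <- pd$outlines[pd$outlines$region == "brain", ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = white,
                          ggplot2::aes(x = .data$tpsa, y = .data$wlogp),
                          fill = "grey85", colour = "grey55") +
    ggplot2::geom_polygon(data = yolk,
                          ggplot2::aes(x = .data$tpsa, y = .data$wlogp),
                          fill = "#F7D21E", colour = "#C8A800",
                          alpha = 0.9) +
    ggplot2::geom_point(data = pd$points,
                        ggplot2::aes(x = .data$tpsa, y = .data$wlogp),
                        size = 1.4, colour = "black") +
    ggplot2::coord_cartesian(xlim = pd$xlim, ylim = pd$ylim) +
    ggplot2::labs(x = expression(tPSA ~ (ring(A)^2)), y = "WLogP") +
    ggplot2::theme_classic()
  if (label_points && "id" %in% names(pd$points)) {
    p <- p + ggplot2::geom_text(
      data = pd$points,
      ggplot2::aes(x = .data$tpsa, y = .data$wlogp, label = .data$id),
      size = 2.6, vjust = -0.8)
  }
  p
}

#' @rdname plot_boiled_egg
#' @param object an `egg_model`.
#' @param ... forwarded; `predictions` may be passed through.
#' @method autoplot egg_model
#' @export
autoplot.egg_model <- function(object, ...) {
  dots <- list(...)
  preds <- dots$predictions
  if (is.null(preds)) {
    # no compounds: draw the empty egg, anchored on the ellipse centers
    preds <- tibble::tibble(
      tpsa = c(object$intestinal$center_tpsa, object$brain$center_tpsa),
      wlogp = c(object$intestinal$center_wlogp, object$brain$center_wlogp))
  }
  plot_boiled_egg(preds, model = object)
}

#' Bar chart of class-level permeant percentages
#'
#' @param summary output of [summarize_by_class()].
#' @param drop_all drop the overall `"all"` row (default `TRUE`).
#' @return a ggplot object.
#' @export
plot_class_summary <- function(summary, drop_all = TRUE) {
  stopifnot(is.data.frame(summary),
            all(c("chem_class", "pct_gi_high", "pct_bbb_yes") %in%
                  names(summary)))
  df <- summary
  if (drop_all) df <- df[df$chem_class != "all", ]
  long <- tidyr::pivot_longer(
    df[, c("chem_class", "pct_gi_high", "pct_bbb_yes")],
    cols = c("pct_gi_high", "pct_bbb_yes"),
    names_to = "barrier", values_to = "pct")
  long$barrier <- factor(long$barrier, c("pct_gi_high", "pct_bbb_yes"),
                         c("intestine-permeant", "brain-permeant"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chem_class, y = .data$pct,
                                     fill = .data$barrier)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("grey60", "#F7D21E")) +
    ggplot2::labs(x = NULL, y = "% of class predicted permeant",
                  fill = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
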