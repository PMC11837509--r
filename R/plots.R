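# ggplot2 autoplot methods for the main result types.

#' Plot a diversity summary
#'
#' Mean Hill diversity per treatment and week with two-standard-deviation
#' error bars, faceted by Hill order.
#'
#' @param object A `diversity_summary` from [diversity_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diversity_summary
#' @export
autoplot.diversity_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$week, y = .data$mean_D,
                                       colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_D - 2 * .data$sd_D,
                                          ymax = .data$mean_D + 2 * .data$sd_D)) +
    ggplot2::facet_wrap(~q, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "week", y = "Hill diversity (effective phylotypes)") +
    ggplot2::theme_minimal()
}

#' Plot an NMDS ordination
#'
#' @param object An `nmds_result` from [nmds_ordination()].
#' @param groups Optional group label per sample (colour).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nmds_result
#' @export
autoplot.nmds_result <- function(object, groups = NULL, ...) {
  pts <- object$points
  if (!is.null(groups)) pts$group <- groups
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::labs(caption = sprintf("stress = %.4f", object$stress)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}

#' Plot a buffering curve
#'
#' Mean pathway retention against the fraction of taxa removed, with
#' one-standard-deviation ribbons over knockout replicates.
#'
#' @param object A `buffering_curve` from [buffering_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot buffering_curve
#' @export
autoplot.buffering_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction,
                                       y = .data$mean_retention)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$mean_retention - .data$sd_retention),
      ymax = pmin(1, .data$mean_retention + .data$sd_retention)),
      alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of taxa removed",
                  y = "pathway retention",
                  title = unique(object$strategy)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a fate matrix
#'
#' Family-by-pathway tile map of pathway fates between the baseline and end
#' windows, in the conventional colours: tan = retained, white = never,
#' red = gained, black = lost.
#'
#' @param object A `fate_matrix` from [fate_classification()].
#' @param level "family" (default, requires incidence-based cells) or
#'   "pathway".
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fate_matrix
#' @export
autoplot.fate_matrix <- function(object, level = c("family", "pathway"), ...) {
  level <- match.arg(level)
  cols <- c(retained = "tan", never = "white", gained = "red", lost = "black")
  if (level == "family" && nrow(object$family) > 0) {
    dat <- object$family
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pathway, y = .data$taxon,
                                           fill = .data$fate))
  } else {
    dat <- object$pathway |> mutate(level = "pathway")
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pathway, y = .data$level,
                                           fill = .data$fate))
  }
  p + ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
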