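#' Plot the incremental-feature-selection curve
#'
#' Mean cross-validated MCC against the number of top-ranked features, with
#' the chosen dimension marked.
#'
#' @param object A `carb_ifs` from [ifs_select()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.carb_ifs <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$mcc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$chosen_dimension, linetype = 2, colour = "red") +
    ggplot2::labs(
      x = "number of top-ranked features", y = "mean CV MCC",
      title = sprintf("IFS curve (chosen dimension %d)", object$chosen_dimension)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of an evaluation
#'
#' @param object A `carb_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.carb_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC (AUC = %.4f)", object$metrics$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a position-composition enrichment table
#'
#' Signed composition differences for significant (position, residue) cells,
#' in the style of a two-sample logo summary.
#'
#' @param composition Output of [position_composition_test()].
#' @return A ggplot object.
#' @export
plot_position_composition <- function(composition) {
  sig <- dplyr::filter(composition, .data$significant)
  ggplot2::ggplot(sig, ggplot2::aes(
    x = .data$offset, y = .data$diff, label = .data$residue, colour = .data$direction
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_text(size = 3) +
    ggplot2::scale_colour_manual(values = c(enriched = "firebrick", depleted = "navy")) +
    ggplot2::labs(
      x = "position relative to site", y = "composition difference (pos - neg)",
      title = "Significant position-specific composition differences"
    ) +
    ggplot2::theme_minimal()
}

#' Plot class-wise hydrophobicity profiles
#'
#' @param profile Output of [hydrophobicity_profile()].
#' @return A ggplot object.
#' @export
plot_hydrophobicity_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$offset, y = .data$mean_hydrophobicity, colour = .data$class
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "position relative to site", y = "mean normalized hydrophobicity",
      title = "Hydrophobicity environment around candidate sites"
    ) +
    ggplot2::theme_minimal()
}
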