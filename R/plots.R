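#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot stratified attention profiles
#'
#' One panel per maturity group, one curve per yield range: mean attention
#' weight across the growing-season time-steps with the inter-quartile
#' band.
#'
#' @param object An [stratify_profiles()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot attention_summary
#' @export
autoplot.attention_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$step, y = .data$mean_alpha,
    colour = .data$yield_range, fill = .data$yield_range)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~mg, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time-step", y = "attention weight",
                  colour = "yield range", fill = "yield range") +
    ggplot2::theme_minimal()
}

#' Plot a training-loss history
#'
#' @param object A fitted `gxe_fit`.
#' @param ... Unused.
#' @return A ggplot object with train (and validation) MSE per epoch.
#' @method autoplot gxe_fit
#' @export
autoplot.gxe_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "set", values_to = "mse")
  h <- h[!is.na(h$mse), ]
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$mse,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "MSE (scaled yield)") +
    ggplot2::theme_minimal()
}

#' Elbow plot of K-means inertia against cluster count
#'
#' @param curve An [inertia_curve()] tibble.
#' @return A ggplot object.
#' @export
plot_inertia <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$k, .data$inertia)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters K",
                  y = "inertia (within-cluster SS)") +
    ggplot2::theme_minimal()
}
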