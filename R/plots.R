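#' Bland-Altman plot of volumetric agreement
#'
#' @param x a [volume_agreement()] result.
#' @param units axis label for the volume units.
#' @return A ggplot object: per-lesion differences against means with the
#'   mean difference (solid) and 95% limits of agreement (dashed).
#' @export
plot_bland_altman <- function(x, units = "cm^3") {
  stopifnot(inherits(x, "volume_agreement"))
  df <- data.frame(mean = x$means, difference = x$differences)
  ba <- x$bland_altman
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$mean_difference) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high), linetype = "dashed") +
    ggplot2::labs(x = sprintf("mean volume (%s)", units),
                  y = sprintf("prediction - ground truth (%s)", units),
                  title = "Bland-Altman volumetric agreement") +
    ggplot2::theme_minimal()
}

#' Training-loss curve
#'
#' @param log the `log` tibble from [train_network()].
#' @return A ggplot object of the composite loss per optimizer step, with
#'   validation loss overlaid where recorded.
#' @export
plot_training_log <- function(log) {
  p <- ggplot2::ggplot(log, ggplot2::aes(x = step, y = loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "optimizer step", y = "composite loss") +
    ggplot2::theme_minimal()
  if ("val_loss" %in% names(log) && any(is.finite(log$val_loss)))
    p <- p + ggplot2::geom_point(data = log[is.finite(log$val_loss), ],
                                 ggplot2::aes(y = val_loss), colour = "red")
  p
}
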