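#' Scatter panels of thermodynamic features versus expression level
#'
#' The standard diagnostic panel set: light- and dense-phase values,
#' partition coefficient, free energy of transfer, and volume/mole
#' fractions, each against the mean ROI concentration (or intensity), one
#' point per ROI. Optionally colored by a condition column.
#'
#' @param thermo tibble from [compute_thermodynamics()].
#' @param condition optional name of a grouping column in `thermo` used for
#'   color.
#' @return A ggplot object.
#' @export
plot_thermo_panels <- function(thermo, condition = NULL) {
  long <- tidyr::pivot_longer(
    thermo,
    cols = c("lp", "dp", "kp", "dg_tr", "f_vol", "f_mol"),
    names_to = "feature", values_to = "value")
  long$feature <- factor(long$feature,
                         levels = c("lp", "dp", "kp", "dg_tr", "f_vol", "f_mol"),
                         labels = c("LP", "DP", "K[p]", "Delta*G[Tr]",
                                    "F[vol]", "F[mol]"))
  aes <- if (is.null(condition)) {
    ggplot2::aes(x = .data$roi_concentration_uM, y = .data$value)
  } else {
    ggplot2::aes(x = .data$roi_concentration_uM, y = .data$value,
                 colour = .data[[condition]])
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~feature, scales = "free_y",
                        labeller = ggplot2::label_parsed) +
    ggplot2::labs(x = "mean ROI concentration (uM or intensity)",
                  y = NULL) +
    ggplot2::theme_bw()
}

#' Forest plot of pairwise condition contrasts
#'
#' @param object a `condition_comparison` from [compare_conditions()].
#' @param ... unused.
#' @return A ggplot object showing each pairwise estimate with its Wald
#'   confidence interval.
#' @export
autoplot.condition_comparison <- function(object, ...) {
  ct <- object$contrasts
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$estimate, y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = if (object$model_kind == "poisson-log-link-mixed") {
        "log rate ratio"
      } else "estimated difference",
      y = NULL,
      title = sprintf("Condition contrasts (%s model)", object$model_kind)) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Maximum-intensity projection of a channel with optional mask outline
#'
#' Quick visual check of segmentation quality: the z maximum-intensity
#' projection of one channel, with labeled object footprints overlaid.
#'
#' @param stack a [multichannel_stack()].
#' @param channel zero-based channel index or name.
#' @param labels optional [label_volume()] to overlay.
#' @return A ggplot object.
#' @export
plot_projection <- function(stack, channel = 0, labels = NULL) {
  vol <- channel_volume(stack, channel)
  proj <- apply(vol, c(2, 3), max)
  df <- data.frame(
    y = rep(seq_len(nrow(proj)), ncol(proj)),
    x = rep(seq_len(ncol(proj)), each = nrow(proj)),
    intensity = as.vector(proj))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(labels)) {
    lab <- if (inherits(labels, "label_volume")) labels$labels else labels
    lproj <- apply(lab, c(2, 3), max)
    on <- which(lproj > 0, arr.ind = TRUE)
    if (nrow(on) > 0) {
      df2 <- data.frame(y = on[, 1], x = on[, 2],
                        label = factor(lproj[on]))
      g <- g + ggplot2::geom_tile(data = df2,
                                  ggplot2::aes(colour = .data$label),
                                  fill = NA, linewidth = 0.1,
                                  show.legend = FALSE)
    }
  }
  g
}
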