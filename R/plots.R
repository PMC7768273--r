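# ggplot2 visualisations for the main result types.

#' State-space plot of a trajectory with boundaries and NRt space
#'
#' @param traj Trajectory tibble.
#' @param bounds Optional `state_boundaries`.
#' @param nrt_space Optional `nrt_space`.
#' @param hypnogram Optional hypnogram used to colour epochs.
#' @return A ggplot object.
#' @export
plot_state_space <- function(traj, bounds = NULL, nrt_space = NULL,
                             hypnogram = NULL) {
  df <- traj[is.finite(traj$x) & is.finite(traj$y), ]
  if (!is.null(hypnogram))
    df$label <- hypnogram$label[match(df$epoch_index, hypnogram$epoch_index)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(alpha = 0.25, colour = "grey50")
  p <- if (is.null(hypnogram)) p + ggplot2::geom_point(size = 0.6)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 0.6)
  close_poly <- function(poly) poly[c(seq_len(nrow(poly)), 1L), ]
  if (!is.null(nrt_space) && nrow(nrt_space$hull) >= 3)
    p <- p + ggplot2::geom_polygon(data = close_poly(nrt_space$hull),
                                   fill = "orange", alpha = 0.15, colour = NA)
  if (!is.null(bounds)) {
    for (s in c("N", "R"))
      p <- p + ggplot2::geom_path(data = close_poly(bounds[[s]]$polygon),
                                  colour = if (s == "N") "steelblue" else "firebrick")
  }
  p + ggplot2::labs(x = "log10 theta ratio (7-9 / 1-9 Hz)",
                    y = "log10 power (1-19 Hz)", colour = "stage") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_state_space autoplot method for `state_boundaries`.
#' @param object,... autoplot arguments.
#' @export
autoplot.state_boundaries <- function(object, ...) {
  df <- tidy(object)
  df <- df[order(df$state, df$vertex), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$state,
                                   colour = .data$state)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::labs(x = "log10 theta ratio", y = "log10 power") +
    ggplot2::theme_minimal()
}

#' Rate traces and scored states of a flip-flop simulation
#'
#' @param object `flipflop_sim`.
#' @param thr_n,thr_r Optional scoring thresholds drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flipflop_sim <- function(object, thr_n = NULL, thr_r = NULL, ...) {
  long <- tidyr::pivot_longer(object$rates, c("rate_r", "rate_n", "rate_diff"),
                              names_to = "series")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch (20 iterations)", y = "spikes / neuron / epoch") +
    ggplot2::theme_minimal()
  for (th in c(thr_n, thr_r))
    p <- p + ggplot2::geom_hline(yintercept = th, linetype = 2, colour = "grey40")
  p
}

#' Radial concentration / PSI profile of a diffusion result
#'
#' @param object `diffusion_result`.
#' @param psi_threshold_pct Reference PSI threshold line (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diffusion_result <- function(object, psi_threshold_pct = 1, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$distance_voxels, y = .data$psi_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = psi_threshold_pct, linetype = 2,
                        colour = "firebrick") +
    ggplot2::scale_y_continuous(trans = "sqrt") +
    ggplot2::labs(x = "distance from source (voxels)",
                  y = "percent spike inhibition",
                  title = sprintf("%s, %d iterations",
                                  object$schedule$scenario,
                                  object$schedule$total_iterations)) +
    ggplot2::theme_minimal()
}

#' Minimal estimation plot for a paired effect
#'
#' Point estimate with its BCa interval, in the spirit of a Cumming plot's
#' lower panel.
#'
#' @param object `effect_estimate`.
#' @param label Axis label for the comparison.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_estimate <- function(object, label = "paired difference", ...) {
  df <- tidy(object)
  df$what <- label
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "paired mean difference") +
    ggplot2::theme_minimal()
}
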