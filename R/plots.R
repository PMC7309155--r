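#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an IMU recording
#'
#' Faceted trace of the six channels over a chosen time window; the
#' vertical angular velocity panel shows the regularly spaced turnaround
#' bursts of a back-and-forth walking track.
#'
#' @param object An [imu_series()].
#' @param channels Channels to show (default all six).
#' @param from,to Time window, seconds (defaults to the full recording).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.imu_series <- function(object, channels = imu_channels(),
                                from = 0, to = Inf, ...) {
  dat <- tibble::as_tibble(object) %>%
    filter(.data$t >= from, .data$t <= to) %>%
    tidyr::pivot_longer(tidyr::all_of(channels), names_to = "channel",
                        values_to = "value") %>%
    mutate(channel = factor(.data$channel, levels = imu_channels()))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y",
                        strip.position = "right") +
    ggplot2::labs(x = "time (s)",
                  y = "acceleration (m/s²) / angular velocity (°/s)") +
    ggplot2::theme_minimal()
}

#' Compare an index between fallers and nonfallers
#'
#' Jittered dot plot of one variability index (or the TUG time) by group,
#' with group medians - the visual counterpart of the Mann-Whitney group
#' comparison.
#'
#' @param indices Cohort index table from [cohort_indices()].
#' @param index Column to plot (default `sd_a_ap`).
#' @return A ggplot.
#' @export
plot_index_by_group <- function(indices, index = "sd_a_ap") {
  stopifnot(index %in% names(indices))
  dat <- indices %>%
    mutate(group = factor(ifelse(.data$faller == 1, "faller", "nonfaller"),
                          levels = c("nonfaller", "faller")))
  med <- dat %>%
    group_by(.data$group) %>%
    summarise(m = median(.data[[index]]), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data[[index]])) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.6) +
    ggplot2::geom_crossbar(data = med,
                           ggplot2::aes(y = .data$m, ymin = .data$m,
                                        ymax = .data$m),
                           width = 0.4, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = index) +
    ggplot2::theme_minimal()
}

#' Plot CNN training history
#'
#' @param object A `gait_cnn` model.
#' @param ... Ignored.
#' @return A ggplot of training and validation loss per epoch.
#' @export
autoplot.gait_cnn <- function(object, ...) {
  dat <- object$history %>%
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "set",
                        values_to = "loss")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                    colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
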