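# ggplot2 displays of the standard result tables.

#' Plot group-by-block mean RT curves
#'
#' Line plot of group mean RT (+/- 1 SE across participants) over blocks,
#' the standard learning-curve display of SRT experiments.
#'
#' @param bm A [block_means()] tibble including a `group` column.
#' @return A ggplot object.
#' @export
plot_block_means <- function(bm) {
  gm <- bm |>
    dplyr::group_by(.data$group, .data$block) |>
    dplyr::summarise(
      se = sd(.data$mean_rt, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$mean_rt))),
      mean_rt = mean(.data$mean_rt, na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(gm, ggplot2::aes(
    .data$block, .data$mean_rt,
    colour = .data$group, group = .data$group
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_rt - .data$se,
        ymax = .data$mean_rt + .data$se
      ),
      width = 0.15
    ) +
    ggplot2::scale_x_continuous(breaks = unique(gm$block)) +
    ggplot2::labs(
      x = "Block", y = "Mean RT (ms)", colour = NULL,
      title = "Mean reaction time by block"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the online/offline learning decomposition by group
#'
#' Bar chart of group mean online, offline and corrected offline learning
#' (+/- 1 SE across participants), all in ms of improvement.
#'
#' @param summary A [learning_summary()] tibble including a `group` column.
#' @return A ggplot object.
#' @export
plot_learning_components <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(
      dplyr::all_of(c("online", "offline", "corrected_offline")),
      names_to = "component", values_to = "value"
    ) |>
    dplyr::group_by(.data$group, .data$component) |>
    dplyr::summarise(
      se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      value = mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  long$component <- factor(
    long$component,
    levels = c("online", "offline", "corrected_offline")
  )
  ggplot2::ggplot(long, ggplot2::aes(
    .data$group, .data$value,
    fill = .data$component
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$value - .data$se,
        ymax = .data$value + .data$se
      ),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = NULL, y = "Learning (ms, improvement positive)", fill = NULL,
      title = "Online and offline learning by group"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a cohort shows the group-by-block RT curves of its
#' (trimmed or untrimmed) trials.
#'
#' @param object An `srt_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srt_cohort <- function(object, ...) {
  plot_block_means(block_means(object$trials))
}
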