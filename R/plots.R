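## Quick-look figures for sweeps, parameter trajectories and combination
## tables. All return ggplot objects.

#' Plot amplitude-frequency sweeps
#'
#' @param cohort A cohort (or single-sweep) data frame.
#' @param subjects Optional subject subset.
#' @param times_h Optional time subset (hours).
#' @return A ggplot of amplitude vs frequency (MHz), coloured by time,
#'   facetted by subject when several are shown.
#' @export
plot_sweeps <- function(cohort, subjects = NULL, times_h = NULL) {
  df <- as_tibble(cohort)
  if (!is.null(subjects)) df <- df[df$subject %in% subjects, ]
  if (!is.null(times_h)) df <- df[df$time_h %in% times_h, ]
  p <- ggplot2::ggplot(
    df, ggplot2::aes(x = .data$freq_hz / 1e6, y = .data$amp_db,
                     colour = factor(.data$time_h),
                     group = .data$time_h)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Frequency (MHz)", y = "|S21| (dB)",
                  colour = "time (h)") +
    ggplot2::theme_minimal()
  if ("subject" %in% names(df) && length(unique(df$subject)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$subject))
  }
  p
}

#' Plot characteristic-parameter trajectories
#'
#' @param params Parameter table from [extract_series()].
#' @return A ggplot: each parameter over time, one line per subject,
#'   coloured by group, facetted by parameter.
#' @export
plot_parameters <- function(params) {
  long <- tidyr::pivot_longer(as_tibble(params),
                              dplyr::all_of(abcpe_parameters()),
                              names_to = "parameter",
                              values_to = "value")
  long$parameter <- factor(long$parameter, levels = abcpe_parameters())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value,
                                     group = .data$subject,
                                     colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = "Time since baseline (h)", y = "Parameter value",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot a combination table as an AUC dot chart
#'
#' @param tbl Combination table from [evaluate_all_combinations()].
#' @return A ggplot ranking the 31 combinations by AUC, grouped by size.
#' @export
plot_combinations <- function(tbl) {
  tbl <- as_tibble(tbl)
  tbl$combination <- stats::reorder(tbl$combination, tbl$auc)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$auc, y = .data$combination,
                                    colour = factor(.data$size))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "AUC", y = NULL, colour = "size") +
    ggplot2::theme_minimal()
}
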