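#' Plot an ethogram as an event raster
#'
#' @param object A `cm_ethogram` from [classify_behaviors()].
#' @param ... Unused.
#' @return A ggplot: one lane per mouse, events as colored segments.
#' @exportS3Method ggplot2::autoplot
autoplot.cm_ethogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$start_s, xend = .data$start_s + .data$duration_s,
    y = .data$actor, yend = .data$actor, colour = .data$label)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "behavior",
                  title = attr(object, "bout_id")) +
    ggplot2::theme_minimal()
}

#' Plot a normalized photometry trace
#'
#' @param object A `dff_trace`.
#' @param ... Unused.
#' @return A ggplot of dF/F over time.
#' @exportS3Method ggplot2::autoplot
autoplot.dff_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time_s, .data$dff)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F),
                  subtitle = paste0("method: ", attr(object, "method"))) +
    ggplot2::theme_minimal()
}

#' Plot group-average event-locked traces
#'
#' Pointwise mean with a standard-error ribbon across included events.
#'
#' @param object An `event_locked_set`.
#' @param by Optional metadata column to group traces by.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.event_locked_set <- function(object, by = NULL, ...) {
  df <- event_locked_mean(object, by = by)
  ggplot2::ggplot(df, ggplot2::aes(.data$rel_time_s, .data$mean_dff,
                                   colour = .data$group, fill = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_dff - .data$sem_dff,
                                      ymax = .data$mean_dff + .data$sem_dff),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from event onset (s)",
                  y = expression(Delta * F / F)) +
    ggplot2::theme_minimal()
}

#' Plot social-avoidance scores
#'
#' Composite score per animal, colored by classification.
#'
#' @param object An `avoidance_result` from [social_avoidance_scores()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.avoidance_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$composite), ]
  df$animal <- factor(df$animal, levels = df$animal[order(df$composite)])
  ggplot2::ggplot(df, ggplot2::aes(.data$animal, .data$composite,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(susceptible = "#d7301f",
                                          resilient = "#2b8cbe")) +
    ggplot2::labs(x = NULL, y = "social avoidance score", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
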