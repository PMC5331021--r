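#' Plot canonical discriminant scores with group centroids
#'
#' Scatter of the cases in the plane of the first two discriminant functions
#' (or a strip plot when the model has a single function), with group
#' centroids marked.
#'
#' @param object A fitted `"dfa"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dfa <- function(object, ...) {
  s <- ncol(object$scores)
  d <- tibble::as_tibble(object$scores)
  d$group <- object$groups
  cen <- tibble::as_tibble(object$centroids)
  cen$group <- factor(object$levels, levels = object$levels)
  if (s >= 2) {
    ggplot2::ggplot(d, ggplot2::aes(.data$function_1, .data$function_2,
                                    colour = .data$group)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::geom_point(data = cen, shape = 15, size = 4) +
      ggplot2::labs(x = "Function 1", y = "Function 2", colour = "Phase",
                    title = "Canonical discriminant functions",
                    subtitle = "squares mark group centroids") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data$function_1, .data$group,
                                    colour = .data$group)) +
      ggplot2::geom_jitter(height = 0.1, alpha = 0.8) +
      ggplot2::geom_point(data = cen, shape = 15, size = 4) +
      ggplot2::labs(x = "Function 1", y = NULL, colour = "Phase") +
      ggplot2::theme_minimal()
  }
}

#' Plot a classification table as a heat map
#'
#' @param object A `"classification_table"`.
#' @param ... Unused.
#' @return A ggplot object with original groups on rows, predictions on
#'   columns, tiles shaded by the within-group proportion.
#' @export
autoplot.classification_table <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$original,
                                  fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(
      x = "Predicted group", y = "Original group", fill = "Row prop.",
      title = sprintf("Classification (%s): %.1f%% correct",
                      object$mode, object$overall_accuracy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot minute-level activity with extracted segments highlighted
#'
#' @param activity Validated activity tibble (one or more subjects).
#' @param segments Optional segments tibble from [extract_segments()]; when
#'   supplied, the extracted 64-min windows are shaded.
#' @param subjects Optional character vector restricting which subjects are
#'   shown (default: first 4).
#' @return A ggplot object faceted by subject.
#' @export
plot_activity <- function(activity, segments = NULL, subjects = NULL) {
  activity <- validate_activity(activity)
  if (is.null(subjects)) subjects <- head(unique(activity$subject_id), 4)
  d <- activity[activity$subject_id %in% subjects, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$timestamp, .data$activity_count)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~subject_id, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Activity (counts/min)") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    seg_len <- length(segments$counts[[1]])
    sh <- segments[segments$subject_id %in% subjects, ]
    sh <- dplyr::mutate(sh, end_time = .data$start_time + 60 * seg_len)
    p <- p + ggplot2::geom_rect(
      data = sh,
      ggplot2::aes(xmin = .data$start_time, xmax = .data$end_time,
                   ymin = -Inf, ymax = Inf, fill = .data$window),
      alpha = 0.25, inherit.aes = FALSE
    ) + ggplot2::labs(fill = "Active period")
  }
  p
}
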