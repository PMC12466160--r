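#' @import ggplot2
NULL

#' Plot a diversity series
#'
#' Shannon index over day of life, optionally coloured by segmentation
#' period.
#'
#' @param series A diversity series tibble ([diversity_series()]).
#' @param fit Optional `cbs_fit` whose periods colour the points.
#' @return A ggplot object.
#' @export
plot_diversity_series <- function(series, fit = NULL) {
  df <- series
  if (!is.null(fit)) {
    df <- df |>
      left_join(period_labels(fit) |> select("sample_id", "period_id"),
                by = "sample_id") |>
      mutate(period = factor(.data$period_id))
    p <- ggplot(df, aes(x = .data$day_of_life, y = .data$shannon,
                        colour = .data$period))
  } else {
    p <- ggplot(df, aes(x = .data$day_of_life, y = .data$shannon))
  }
  p + geom_point(size = 0.8) +
    labs(x = "day of life", y = "Shannon index",
         colour = "HMD period") +
    theme_minimal()
}

#' Autoplot a segmentation fit
#'
#' The segmented series with horizontal mean-level bars per period.
#'
#' @param object A `cbs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbs_fit <- function(object, ...) {
  pts <- period_labels(object)
  xvar <- if ("day_of_life" %in% names(pts)) "day_of_life" else "index"
  seg <- object$segments
  if (all(is.na(seg$start_day))) {
    seg$start_day <- seg$start_index
    seg$end_day <- seg$end_index
  }
  ggplot(pts, aes(x = .data[[xvar]], y = .data$value)) +
    geom_point(size = 0.7, colour = "grey40") +
    geom_segment(data = seg,
                 aes(x = .data$start_day, xend = .data$end_day,
                     y = .data$mean_level, yend = .data$mean_level),
                 colour = "firebrick", linewidth = 1) +
    labs(x = xvar, y = "value",
         title = sprintf("%d homogeneous periods", nrow(seg))) +
    theme_minimal()
}

#' Autoplot an event-test table
#'
#' Per-feature q-values on a log scale against the significance gate.
#'
#' @param object An `event_test_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.event_test_tbl <- function(object, ...) {
  thr <- attr(object, "fdr_threshold") %||% 0.1
  df <- tidy(object) |> arrange(.data$q_bh) |>
    mutate(taxon = factor(.data$taxon, levels = .data$taxon))
  ggplot(df, aes(x = .data$taxon, y = .data$q_bh,
                 fill = .data$significant)) +
    geom_col() +
    geom_hline(yintercept = thr, linetype = 2) +
    scale_y_log10() +
    labs(x = NULL, y = "BH q-value") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1,
                                     size = 6))
}

#' Plot detection frequencies across subsample runs
#'
#' Per-feature weekly detection counts in each run against the
#' full-resolution reference, with the 3- and 5-week reference thresholds.
#'
#' @param freq A detection-frequency tibble ([detection_frequency()]).
#' @return A ggplot object.
#' @export
plot_detection_frequency <- function(freq) {
  ord <- freq |> group_by(.data$taxon) |>
    summarise(ref = dplyr::first(.data$reference_weeks), .groups = "drop") |>
    arrange(.data$ref)
  df <- freq |> mutate(taxon = factor(.data$taxon, levels = ord$taxon))
  ggplot(df, aes(x = .data$taxon, y = .data$weeks_detected)) +
    geom_boxplot(outlier.size = 0.5) +
    geom_point(aes(y = .data$reference_weeks), colour = "red", size = 0.8) +
    geom_hline(yintercept = c(3, 5), linetype = 3) +
    labs(x = NULL, y = "weeks detected") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1,
                                     size = 6))
  }
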