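#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a segmentation fit
#'
#' @param x A `cbs_fit` ([cbs_segment()]).
#' @param ... Unused.
#' @return The segments tibble: one row per homogeneous-diversity period
#'   with its index range, day range, marker count and mean level.
#' @export
tidy.cbs_fit <- function(x, ...) {
  as_tibble(x$segments)
}

#' @rdname tidy.cbs_fit
#' @return For `glance`: a one-row tibble with `n_points, n_breakpoints,
#'   n_periods, alpha, min_width, n_permutations, seed`.
#' @export
glance.cbs_fit <- function(x, ...) {
  tibble(n_points = length(x$x),
         n_breakpoints = length(x$breakpoints),
         n_periods = nrow(x$segments),
         alpha = x$alpha,
         min_width = x$min_width,
         n_permutations = x$n_permutations,
         seed = x$seed)
}

#' Tidy a PERMANOVA fit
#'
#' @param x A `permanova_fit` ([permanova()]).
#' @param ... Unused.
#' @return A one-row tibble `(statistic, p_value, method, n_permutations)`.
#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         method = x$method, n_permutations = x$n_permutations)
}

#' @rdname tidy.permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_samples = x$n_samples, n_groups = x$n_groups,
         n_permutations = x$n_permutations, method = x$method)
}

#' Tidy an event-test table
#'
#' @param x An `event_test_tbl` ([run_event_tests()]).
#' @param ... Unused.
#' @return The per-feature outcomes without list-columns.
#' @export
tidy.event_test_tbl <- function(x, ...) {
  as_tibble(x)[, c("taxon", "statistic", "p_raw", "q_bh", "significant")]
}

#' @rdname tidy.event_test_tbl
#' @export
glance.event_test_tbl <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_significant = sum(x$significant),
         fdr_threshold = attr(x, "fdr_threshold"),
         test_kind = attr(attr(x, "design"), "test_kind"))
}
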