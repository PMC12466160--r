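#' Shannon diversity index of one sample
#'
#' `H = -sum p_i ln p_i` over features with count > 0, with
#' `p_i = count_i / total`. Natural logarithm, so a community of k equally
#' abundant taxa has `H = ln k`, and `H = 0` whenever a single taxon is
#' present. Scale-invariant in the counts.
#'
#' @param counts Numeric vector of one sample's counts (total > 0).
#' @return Shannon index, a real >= 0.
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) abort("cannot compute Shannon index of a zero-total sample")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Time-ordered diversity series
#'
#' One record per non-empty sample with its Shannon index and richness
#' (number of features with count > 0), ordered by day of life (ties broken
#' by sample id). Zero-total samples — e.g. a sterile meconium — are
#' excluded and listed in the `exclusions` attribute.
#'
#' @param table A wide count tibble.
#' @param meta Metadata tibble covering every sample.
#' @return A tibble `(sample_id, day_of_life, week_of_life, matrix_type,
#'   shannon, richness)` with attribute `exclusions`.
#' @export
diversity_series <- function(table, meta) {
  m <- count_matrix(table)
  missing_meta <- setdiff(colnames(m), meta$sample_id)
  if (length(missing_meta) > 0) {
    abort(sprintf("samples without metadata: %s",
                  paste(missing_meta, collapse = ", ")))
  }
  totals <- colSums(m)
  empty <- colnames(m)[totals == 0]
  if (length(empty) == ncol(m)) abort("no non-empty samples in the table")
  if (length(empty) > 0) {
    inform(sprintf("diversity series: excluding %d zero-total sample(s)",
                   length(empty)))
  }
  keep <- totals > 0
  ser <- tibble(
    sample_id = colnames(m)[keep],
    shannon = unname(apply(m[, keep, drop = FALSE], 2, shannon_index)),
    richness = unname(colSums(m[, keep, drop = FALSE] > 0))
  ) |>
    left_join(meta |> select("sample_id", "day_of_life", "week_of_life",
                             "matrix_type"),
              by = "sample_id") |>
    arrange(.data$day_of_life, .data$sample_id) |>
    select("sample_id", "day_of_life", "week_of_life", "matrix_type",
           "shannon", "richness")
  attr(ser, "exclusions") <- empty
  ser
}

cv_percent <- function(x) {
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Weekly coefficient-of-variation profile
#'
#' For every week of life: the number of samples, the CV (percent,
#' sample standard deviation over mean) of the Shannon index and of
#' richness across that week's samples, and the per-feature CV of within-week
#' relative abundances summarised across features by median and quartiles.
#' Weeks with fewer than two samples, and features whose within-week mean
#' abundance is zero, are flagged undefined (`NA`) rather than fatal.
#'
#' @param series A diversity series ([diversity_series()]).
#' @param table The wide count tibble the series came from.
#' @param meta Metadata tibble.
#' @return A tibble per week with columns `week_of_life, n_samples,
#'   cv_shannon, cv_richness, cv_genus_median, cv_genus_q1, cv_genus_q3`
#'   and a list-column `feature_cv` of per-feature CV tibbles.
#' @export
weekly_cv <- function(series, table, meta) {
  m <- count_matrix(table)
  rel <- t(t(m) / pmax(colSums(m), 1))   # relative abundances per sample
  weeks <- sort(unique(series$week_of_life))
  rows <- purrr::map(weeks, function(w) {
    sids <- series$sample_id[series$week_of_life == w]
    sh <- series$shannon[series$week_of_life == w]
    rc <- series$richness[series$week_of_life == w]
    sub <- rel[, sids, drop = FALSE]
    fcv <- tibble(
      taxon = rownames(sub),
      cv = unname(apply(sub, 1, cv_percent))
    )
    defined <- fcv$cv[!is.na(fcv$cv)]
    tibble(
      week_of_life = w,
      n_samples = length(sids),
      cv_shannon = cv_percent(sh),
      cv_richness = cv_percent(rc),
      cv_genus_median = if (length(defined)) stats::median(defined) else NA_real_,
      cv_genus_q1 = if (length(defined)) unname(stats::quantile(defined, 0.25)) else NA_real_,
      cv_genus_q3 = if (length(defined)) unname(stats::quantile(defined, 0.75)) else NA_real_,
      feature_cv = list(fcv)
    )
  })
  bind_rows(rows)
}
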