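#' Prevalence/abundance feature filter
#'
#' Retains exactly the features detected with at least `min_reads` reads in
#' at least `ceiling(min_prevalence * n_samples)` samples (a joint
#' condition: a sample counts toward prevalence only when the feature
#' reaches `min_reads` in it). With the defaults this is the 2 %/10-read
#' filter used to trim sparse genera before any compositional step. The
#' sample set is never changed.
#'
#' @param table A wide count tibble ([read_count_table()]).
#' @param min_prevalence Fraction of samples in (0, 1].
#' @param min_reads Minimum read count, >= 1.
#' @return The filtered count tibble.
#' @export
filter_features <- function(table, min_prevalence = 0.02, min_reads = 10) {
  if (min_prevalence <= 0 || min_prevalence > 1) {
    abort("min_prevalence must lie in (0, 1]")
  }
  if (min_reads < 1) abort("min_reads must be >= 1")
  m <- count_matrix(table)
  need <- ceiling(min_prevalence * ncol(m))
  keep <- rowSums(m >= min_reads) >= need
  if (!any(keep)) {
    abort("feature filter removed every feature; relax min_prevalence/min_reads")
  }
  table[keep, , drop = FALSE]
}

#' Count-zero-multiplicative zero replacement
#'
#' Converts counts to proportions while replacing zeros multiplicatively:
#' for a sample with total count n and z zero cells, each zero becomes
#' `delta = fraction / n` (a fraction of the detection limit 1/n) and each
#' non-zero proportion p is rescaled to `p * (1 - z * delta)`. Ratios
#' between originally non-zero parts are preserved exactly and each row
#' sums to 1.
#'
#' @param table A wide count tibble; every sample must have total count > 0
#'   (drop zero-total samples, e.g. sterile meconium, first).
#' @param fraction Fraction of the detection limit used for zeros
#'   (default 0.65, the established default of the method).
#' @return A tibble with `sample_id` in rows and one strictly positive
#'   numeric column per feature (samples-by-features orientation, the
#'   substrate of all downstream tests).
#' @export
czm_replace <- function(table, fraction = 0.65) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must lie in (0, 1)")
  m <- count_matrix(table)            # features x samples
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf(
      "zero-total sample(s) must be excluded before zero replacement: %s",
      paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  p <- t(m) / totals                  # samples x features
  delta <- fraction / totals          # per-sample imputed proportion
  z <- rowSums(p == 0)
  shrink <- 1 - z * delta
  if (any(shrink <= 0)) {
    abort("too many zeros for sequencing depth: 1 - z * delta <= 0")
  }
  out <- p * shrink
  zero_idx <- which(p == 0, arr.ind = TRUE)   # delta varies by sample (row)
  out[zero_idx] <- delta[zero_idx[, 1]]
  tibble(sample_id = rownames(p)) |>
    dplyr::bind_cols(as_tibble(out, .name_repair = "minimal"))
}

comp_matrix <- function(comp) {
  stopifnot(is.data.frame(comp), "sample_id" %in% names(comp))
  m <- as.matrix(comp[setdiff(names(comp), "sample_id")])
  rownames(m) <- comp$sample_id
  m
}

#' Centered log-ratio transformation
#'
#' Per sample, `clr_j = ln(x_j) - mean_k ln(x_k)`: compositions are mapped
#' to an unconstrained space whose Euclidean geometry is the Aitchison
#' geometry. Rows sum to 0 and the transform is invariant to sample-wise
#' rescaling. Natural logarithm throughout.
#'
#' @param comp A samples-by-features composition tibble ([czm_replace()]);
#'   all values must be strictly positive.
#' @return A tibble of the same shape with CLR values.
#' @export
clr_transform <- function(comp) {
  m <- comp_matrix(comp)
  if (any(m <= 0)) {
    idx <- which(m <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("non-positive composition value at sample '%s', feature '%s'",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  lm <- log(m)
  clr <- lm - rowMeans(lm)
  tibble(sample_id = rownames(m)) |>
    dplyr::bind_cols(as_tibble(clr, .name_repair = "minimal"))
}

#' Counts to CLR in one call
#'
#' Convenience composition of [filter_features()], [czm_replace()] and
#' [clr_transform()], in that order (filter, then zero replacement, then
#' CLR), excluding zero-total samples with a notice.
#'
#' @param table A wide count tibble.
#' @param config An [analysis_config()].
#' @param filter Apply the prevalence/abundance filter first?
#' @return A samples-by-features CLR tibble.
#' @export
counts_to_clr <- function(table, config = analysis_config(), filter = TRUE) {
  m <- count_matrix(table)
  empty <- colnames(m)[colSums(m) == 0]
  if (length(empty) > 0) {
    inform(sprintf("excluding %d zero-total sample(s): %s",
                   length(empty), paste(empty, collapse = ", ")))
    table <- table[, !(names(table) %in% empty), drop = FALSE]
  }
  if (filter) {
    table <- filter_features(table, config$filter_min_prevalence,
                             config$filter_min_reads)
  }
  czm_replace(table, config$czm_fraction) |> clr_transform()
}

#' Aitchison distance matrix
#'
#' Pairwise Euclidean distances between CLR rows — the Aitchison distance
#' between the underlying compositions.
#'
#' @param clr A samples-by-features CLR tibble ([clr_transform()]).
#' @return A symmetric matrix of class `matrix` with zero diagonal, sample
#'   ids as dimnames.
#' @export
aitchison_distance_matrix <- function(clr) {
  m <- comp_matrix(clr)
  if (nrow(m) < 2) abort("need >= 2 samples for a distance matrix")
  as.matrix(stats::dist(m, method = "euclidean"))
}
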