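#' @importFrom rlang .data abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Column name reserved for taxon labels in wide count tables.
.taxon_col <- "taxon"

#' Week of life from day of life
#'
#' Maps a day of life (birth = day 0) onto a birth-anchored week grid:
#' `week = floor((day - 1) / 7) + 1` for day >= 1, and day 0 is assigned to
#' week 1. Days 1-7 form week 1, days 8-14 week 2, and so on, so the first
#' year (days 1-364) spans exactly 52 weeks.
#'
#' @param day_of_life Integer vector of days of life (>= 0).
#' @return Integer vector of weeks of life (>= 1).
#' @examples
#' week_of_life(c(0, 1, 7, 8, 364))
#' @export
week_of_life <- function(day_of_life) {
  if (any(day_of_life < 0, na.rm = TRUE)) {
    abort("day_of_life must be >= 0 (birth = day 0)")
  }
  wk <- floor((day_of_life - 1) / 7) + 1L
  wk[day_of_life == 0] <- 1L
  as.integer(wk)
}

#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline with their defaults: the
#' 2 %/10-read feature filter, the segmentation level alpha = 0.01 with
#' minimum segment width 2, the FDR <= 0.1 significance gate, 999 PERMANOVA
#' permutations, 5 weekly-downsampling runs, and the 0.65 multiplicative
#' zero-replacement fraction.
#'
#' @param filter_min_prevalence Minimum fraction of samples in which a
#'   feature must reach `filter_min_reads` to be retained.
#' @param filter_min_reads Minimum read count that counts as "detected" for
#'   the prevalence filter.
#' @param cbs_alpha Significance level for accepting a changepoint.
#' @param cbs_min_width Minimum number of markers for a changed segment.
#' @param cbs_n_permutations Permutations for the segmentation null.
#' @param fdr_threshold Benjamini-Hochberg q-value significance gate.
#' @param permanova_n_permutations Label permutations for PERMANOVA.
#' @param downsample_n_runs Number of weekly subsample runs.
#' @param czm_fraction Fraction of the per-sample detection limit used to
#'   replace zeros.
#' @param rng_seed Integer seed recorded in run manifests.
#' @return A list with class `"gut_config"`.
#' @export
analysis_config <- function(filter_min_prevalence = 0.02,
                            filter_min_reads = 10,
                            cbs_alpha = 0.01,
                            cbs_min_width = 2,
                            cbs_n_permutations = 1000,
                            fdr_threshold = 0.1,
                            permanova_n_permutations = 999,
                            downsample_n_runs = 5,
                            czm_fraction = 0.65,
                            rng_seed = 1L) {
  cfg <- list(
    filter_min_prevalence = filter_min_prevalence,
    filter_min_reads = as.integer(filter_min_reads),
    cbs_alpha = cbs_alpha,
    cbs_min_width = as.integer(cbs_min_width),
    cbs_n_permutations = as.integer(cbs_n_permutations),
    fdr_threshold = fdr_threshold,
    permanova_n_permutations = as.integer(permanova_n_permutations),
    downsample_n_runs = as.integer(downsample_n_runs),
    czm_fraction = czm_fraction,
    rng_seed = as.integer(rng_seed)
  )
  probs <- c("filter_min_prevalence", "cbs_alpha", "fdr_threshold",
             "czm_fraction")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(sprintf("config field '%s' must lie in [0, 1]", p))
    }
  }
  if (cfg$cbs_alpha <= 0 || cfg$cbs_alpha >= 1) {
    abort("cbs_alpha must lie strictly in (0, 1)")
  }
  counts <- c("filter_min_reads", "cbs_min_width", "cbs_n_permutations",
              "permanova_n_permutations", "downsample_n_runs")
  for (p in counts) {
    if (cfg[[p]] < 1) abort(sprintf("config field '%s' must be >= 1", p))
  }
  structure(cfg, class = "gut_config")
}

# ---- internal wide-table helpers -------------------------------------------

# wide count tibble (taxon + sample columns) -> integer matrix features x samples
count_matrix <- function(table) {
  stopifnot(is.data.frame(table), .taxon_col %in% names(table))
  m <- as.matrix(table[setdiff(names(table), .taxon_col)])
  storage.mode(m) <- "double"
  rownames(m) <- table[[.taxon_col]]
  m
}

matrix_to_count_tbl <- function(m) {
  tibble(taxon = rownames(m)) |>
    dplyr::bind_cols(as_tibble(m, .name_repair = "minimal"))
}

sample_ids <- function(table) setdiff(names(table), .taxon_col)

#' Read a genus-level count table
#'
#' Reads a tab-separated features-by-samples table in the common QIIME-style
#' layout: first column holds the taxon label, the header row holds sample
#' ids, and every cell is a non-negative integer read count. The result is a
#' wide tibble with a `taxon` column followed by one numeric column per
#' sample.
#'
#' @param path Path to a TSV file.
#' @return A tibble (features in rows) validated by [validate_count_table()].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("count table not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("count table is empty: %s", path))
  tbl <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tbl) < 2) {
    abort("malformed count table: need a taxon column plus >= 1 sample column")
  }
  names(tbl)[1] <- .taxon_col
  tbl <- as_tibble(tbl)
  validate_count_table(tbl)
  tbl
}

#' Validate a count table
#'
#' Checks the count-table invariants: unique taxon labels, unique sample
#' ids, and integer counts >= 0 in every cell. Offending rows/columns are
#' named in the error. Zero-total samples (e.g. a sterile meconium sample)
#' are legal and merely reported by [validate_dataset()].
#'
#' @param table A wide count tibble as returned by [read_count_table()].
#' @return The table, invisibly, if valid.
#' @export
validate_count_table <- function(table) {
  if (!is.data.frame(table) || !(.taxon_col %in% names(table))) {
    abort("count table must be a data frame with a 'taxon' column")
  }
  taxa <- table[[.taxon_col]]
  if (anyDuplicated(taxa)) {
    abort(sprintf("duplicated taxon label(s): %s",
                  paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  sids <- sample_ids(table)
  if (length(sids) == 0) abort("count table has no sample columns")
  if (anyDuplicated(sids)) {
    abort(sprintf("duplicated sample id(s): %s",
                  paste(unique(sids[duplicated(sids)]), collapse = ", ")))
  }
  m <- count_matrix(table)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("missing count at taxon '%s', sample '%s'",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("negative or non-integer count at taxon '%s', sample '%s'",
                  rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  invisible(table)
}

#' Read per-sample metadata
#'
#' Reads a CSV with header `sample_id,subject_id,day_of_life,matrix_type`
#' and derives `week_of_life` via [week_of_life()]. `matrix_type` must be
#' one of meconium, stool, oral, vaginal.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("metadata file not found: %s", path))
  meta <- utils::read.csv(path, stringsAsFactors = FALSE) |> as_tibble()
  validate_metadata(meta)
}

#' @rdname read_metadata
#' @param meta A metadata data frame to validate in memory.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "subject_id", "day_of_life", "matrix_type")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("metadata missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("metadata contains duplicated sample_id values")
  }
  ok_types <- c("meconium", "stool", "oral", "vaginal")
  bad <- setdiff(unique(meta$matrix_type), ok_types)
  if (length(bad) > 0) {
    abort(sprintf("unknown matrix_type value(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(meta$day_of_life < 0)) abort("day_of_life must be >= 0")
  meta |>
    mutate(day_of_life = as.integer(.data$day_of_life),
           week_of_life = week_of_life(.data$day_of_life)) |>
    as_tibble()
}

#' Read an event diary
#'
#' Reads a CSV with header `subject_id,event_type,start_day,end_day,label`.
#' Point events have `end_day == start_day`; events for one subject may
#' overlap. `event_type` must be one of vaccination, probiotic, solid_food,
#' medication, other.
#'
#' @param path Path to a CSV file.
#' @return A tibble of event records.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("event diary not found: %s", path))
  ev <- utils::read.csv(path, stringsAsFactors = FALSE) |> as_tibble()
  validate_events(ev)
}

#' @rdname read_events
#' @param events An event data frame to validate in memory.
#' @export
validate_events <- function(events) {
  need <- c("subject_id", "event_type", "start_day", "end_day")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols) > 0) {
    abort(sprintf("event diary missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"label" %in% names(events)) events$label <- NA_character_
  ok <- c("vaccination", "probiotic", "solid_food", "medication", "other")
  bad <- setdiff(unique(events$event_type), ok)
  if (length(bad) > 0) {
    abort(sprintf("unknown event_type value(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(events$end_day < events$start_day)) {
    i <- which(events$end_day < events$start_day)[1]
    abort(sprintf("event row %d has end_day < start_day", i))
  }
  events |>
    mutate(start_day = as.integer(.data$start_day),
           end_day = as.integer(.data$end_day)) |>
    as_tibble()
}

#' Cross-validate a count table against its metadata
#'
#' Report-only consistency check: lists zero-total samples, samples missing
#' metadata records, metadata rows without a sample, and whether sample
#' columns are in day order. Inputs are never modified.
#'
#' @param table A wide count tibble.
#' @param meta A metadata tibble ([read_metadata()]).
#' @return A tibble with columns `check`, `sample_id`, `detail`; zero rows
#'   when the dataset is fully consistent.
#' @export
validate_dataset <- function(table, meta) {
  validate_count_table(table)
  m <- count_matrix(table)
  sids <- colnames(m)
  report <- list()
  empty <- sids[colSums(m) == 0]
  if (length(empty) > 0) {
    report$empty <- tibble(check = "zero_total_sample", sample_id = empty,
                           detail = "total count 0; excluded from compositional steps")
  }
  no_meta <- setdiff(sids, meta$sample_id)
  if (length(no_meta) > 0) {
    report$no_meta <- tibble(check = "missing_metadata", sample_id = no_meta,
                             detail = "sample has no metadata record")
  }
  extra <- setdiff(meta$sample_id, sids)
  if (length(extra) > 0) {
    report$extra <- tibble(check = "metadata_without_sample", sample_id = extra,
                           detail = "metadata row has no count column")
  }
  days <- meta$day_of_life[match(sids, meta$sample_id)]
  if (!anyNA(days) && is.unsorted(days)) {
    report$order <- tibble(check = "non_monotone_day_order",
                           sample_id = NA_character_,
                           detail = "sample columns are not in day-of-life order")
  }
  if (length(report) == 0) {
    return(tibble(check = character(), sample_id = character(),
                  detail = character()))
  }
  bind_rows(report)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]: counts are written as integers so a
#' write/read round trip reproduces the table exactly.
#'
#' @param table A wide count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  validate_count_table(table)
  out <- table
  for (s in sample_ids(out)) out[[s]] <- as.integer(out[[s]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
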