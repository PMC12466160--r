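#' Weekly subsampling of a dense series
#'
#' Simulates weekly sampling: per run, one uniformly chosen sample from
#' every populated week of life. Across runs a per-week
#' without-replacement scheme is used — each week's samples are drawn in a
#' seeded random order until exhausted, after which further runs redraw
#' with replacement — so selections within a week are pairwise distinct
#' whenever the week holds at least `n_runs` samples ("different samples
#' for each iteration when possible"). Deterministic given `seed`.
#'
#' @param meta Metadata tibble for one subject (stool samples of the dense
#'   series).
#' @param n_runs Number of subsample runs (default 5).
#' @param seed Integer seed.
#' @return A tibble `(run, week_of_life, sample_id)` of class
#'   `subsample_runs`.
#' @export
weekly_subsample <- function(meta, n_runs = 5, seed = 1L) {
  if (n_runs < 1) abort("n_runs must be >= 1")
  if (length(unique(meta$subject_id)) > 1) {
    abort("weekly_subsample expects metadata of a single subject")
  }
  weeks <- sort(unique(meta$week_of_life))
  sel <- with_seed(seed, {
    purrr::map(weeks, function(w) {
      sids <- sort(meta$sample_id[meta$week_of_life == w])
      m <- length(sids)
      order1 <- sids[sample.int(m)]
      picks <- if (n_runs <= m) {
        order1[seq_len(n_runs)]
      } else {
        c(order1, sids[sample.int(m, n_runs - m, replace = TRUE)])
      }
      tibble(run = seq_len(n_runs), week_of_life = w, sample_id = picks)
    })
  })
  out <- bind_rows(sel) |> arrange(.data$run, .data$week_of_life)
  structure(out, class = c("subsample_runs", class(out)), seed = seed)
}

#' Per-genus detection frequency under weekly subsampling
#'
#' For every feature: the reference number of weeks with at least one
#' positive sample in the full data, and per run the number of weeks whose
#' selected sample is positive. Features falling below the 3- and 5-week
#' reference thresholds are flagged per run.
#'
#' @param table Wide count tibble of the dense series.
#' @param meta Metadata tibble matching `table`.
#' @param runs A `subsample_runs` tibble ([weekly_subsample()]).
#' @return A tibble `(taxon, run, weeks_detected, reference_weeks,
#'   below_3, below_5)`.
#' @export
detection_frequency <- function(table, meta, runs) {
  m <- count_matrix(table)
  meta <- meta |> filter(.data$sample_id %in% colnames(m))
  ref_status <- weekly_detection(table, meta,
                                 weeks = sort(unique(meta$week_of_life)))
  reference <- rowSums(ref_status == "detected")
  per_run <- runs |>
    group_by(.data$run) |>
    group_map(function(g, key) {
      sub <- m[, g$sample_id, drop = FALSE]
      tibble(taxon = rownames(m),
             run = key$run,
             weeks_detected = rowSums(sub > 0))
    }) |>
    bind_rows()
  per_run |>
    mutate(reference_weeks = reference[.data$taxon],
           below_3 = .data$weeks_detected < 3,
           below_5 = .data$weeks_detected < 5)
}

#' Event tests on weekly subsampled data
#'
#' Re-runs the event battery on each run's selected samples. The probiotic
#' design is applied unchanged (30-day windows, Kruskal-Wallis). The
#' vaccination design is widened to a rank-sum comparison of the three
#' weekly samples nearest before versus the three nearest after the
#' vaccination week (the 7-day point windows hold too few weekly samples);
#' a run with fewer than three samples on either side is skipped with a
#' notice. Within each run, p-values are Benjamini-Hochberg adjusted
#' across features.
#'
#' @param clr Samples-by-features CLR tibble of the dense series (tests
#'   subset it to each run's samples).
#' @param meta Metadata tibble.
#' @param runs A `subsample_runs` tibble.
#' @param events Event tibble; rows with `event_type` `"probiotic"` or
#'   `"vaccination"` are tested.
#' @param fdr_threshold Significance gate (default 0.1).
#' @return A tibble `(event_type, run, taxon, statistic, p_raw, q_bh,
#'   significant, skipped)`.
#' @export
downsampled_event_tests <- function(clr, meta, runs, events,
                                    fdr_threshold = 0.1) {
  events <- events |> filter(.data$event_type %in% c("probiotic", "vaccination"))
  out <- list()
  for (r in unique(runs$run)) {
    run_ids <- runs$sample_id[runs$run == r]
    run_clr <- clr |> filter(.data$sample_id %in% run_ids)
    run_meta <- meta |> filter(.data$sample_id %in% run_ids)
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (ev$event_type == "probiotic") {
        design <- build_event_windows(ev, "probiotic")
        res <- tryCatch(
          run_event_tests(run_clr, run_meta, design,
                          fdr_threshold = fdr_threshold,
                          min_per_window = 1L),
          error = function(e) NULL)
        if (is.null(res)) {
          inform(sprintf("run %d: probiotic test skipped (window too sparse)", r))
          out[[length(out) + 1]] <- tibble(
            event_type = "probiotic", run = r, taxon = NA_character_,
            statistic = NA_real_, p_raw = NA_real_, q_bh = NA_real_,
            significant = NA, skipped = TRUE)
        } else {
          out[[length(out) + 1]] <- tibble(
            event_type = "probiotic", run = r, taxon = res$taxon,
            statistic = res$statistic, p_raw = res$p_raw, q_bh = res$q_bh,
            significant = res$significant, skipped = FALSE)
        }
      } else {
        res <- vaccination_weekly_test(run_clr, run_meta, ev$start_day,
                                       fdr_threshold)
        if (is.null(res)) {
          inform(sprintf(
            "run %d: vaccination test skipped (< 3 weekly samples on a side)", r))
          out[[length(out) + 1]] <- tibble(
            event_type = "vaccination", run = r, taxon = NA_character_,
            statistic = NA_real_, p_raw = NA_real_, q_bh = NA_real_,
            significant = NA, skipped = TRUE)
        } else {
          out[[length(out) + 1]] <- res |> mutate(event_type = "vaccination",
                                                  run = r, skipped = FALSE)
        }
      }
    }
  }
  bind_rows(out) |>
    select("event_type", "run", "taxon", "statistic", "p_raw", "q_bh",
           "significant", "skipped")
}

# three weekly samples nearest before vs three nearest after the
# vaccination week (ties broken toward earlier weeks); NULL when either
# side is short
vaccination_weekly_test <- function(run_clr, run_meta, vac_day,
                                    fdr_threshold = 0.1) {
  vac_week <- week_of_life(vac_day)
  pre_weeks <- sort(run_meta$week_of_life[run_meta$week_of_life < vac_week])
  post_weeks <- sort(run_meta$week_of_life[run_meta$week_of_life > vac_week])
  if (length(pre_weeks) < 3 || length(post_weeks) < 3) return(NULL)
  pre_sel <- utils::tail(pre_weeks, 3)
  post_sel <- utils::head(post_weeks, 3)
  pre_ids <- run_meta$sample_id[run_meta$week_of_life %in% pre_sel]
  post_ids <- run_meta$sample_id[run_meta$week_of_life %in% post_sel]
  feat <- setdiff(names(run_clr), "sample_id")
  pre_clr <- run_clr |> filter(.data$sample_id %in% pre_ids)
  post_clr <- run_clr |> filter(.data$sample_id %in% post_ids)
  rows <- purrr::map(feat, function(f) {
    mt <- mann_whitney_u(pre_clr[[f]], post_clr[[f]])
    tibble(taxon = f, statistic = mt$statistic, p_raw = mt$p_value)
  })
  out <- bind_rows(rows)
  out$q_bh <- bh_adjust(out$p_raw)
  out$significant <- out$q_bh <= fdr_threshold
  out
}

#' Significance retention across subsample runs
#'
#' For every feature: was it significant in the full-resolution reference,
#' and in how many of the runs (k of n) did it stay significant. The
#' summary counts features at each retention level k.
#'
#' @param reference An `event_test_tbl` from the dense data.
#' @param per_run Per-run outcomes ([downsampled_event_tests()]) for one
#'   event type.
#' @return A list with `retention` (tibble `taxon,
#'   significant_in_reference, k_significant, n_runs`) and `summary`
#'   (tibble `k_significant, n_features`).
#' @export
significance_retention <- function(reference, per_run) {
  per_run <- per_run |> filter(!.data$skipped)
  n_runs <- length(unique(per_run$run))
  if (n_runs == 0) abort("no non-skipped runs to summarise")
  if (!setequal(reference$taxon, unique(per_run$taxon))) {
    abort("reference and per-run outcomes cover different feature sets")
  }
  k_tab <- per_run |>
    group_by(.data$taxon) |>
    summarise(k_significant = sum(.data$significant), .groups = "drop")
  retention <- reference |>
    as_tibble() |>
    select("taxon", significant_in_reference = "significant") |>
    left_join(k_tab, by = "taxon") |>
    mutate(n_runs = n_runs)
  summary <- retention |>
    count(.data$k_significant, name = "n_features")
  list(retention = retention, summary = summary)
}
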