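test_that("weekly subsampling selects one sample per populated week", {
  days <- c(1:21, 29:35)                       # weeks 1-3 and 5; week 4 empty
  meta <- make_meta(sprintf("s%02d", seq_along(days)), as.integer(days))
  runs <- weekly_subsample(meta, n_runs = 5, seed = 2)
  per_run <- split(runs, runs$run)
  for (r in per_run) {
    expect_setequal(r$week_of_life, c(1, 2, 3, 5))
    # every selected sample belongs to its week
    sel_weeks <- meta$week_of_life[match(r$sample_id, meta$sample_id)]
    expect_equal(sel_weeks, r$week_of_life)
  }
})

test_that("selections are distinct across runs until a week is exhausted", {
  days <- c(1:7, 8L, 15:17)    # week 1: 7 samples, week 2: 1, week 3: 3
  meta <- make_meta(sprintf("s%02d", seq_along(days)), as.integer(days))
  runs <- weekly_subsample(meta, n_runs = 5, seed = 9)
  w1 <- runs$sample_id[runs$week_of_life == 1]
  expect_equal(length(unique(w1)), 5)          # 7 >= 5 runs: all distinct
  w2 <- runs$sample_id[runs$week_of_life == 2]
  expect_equal(unique(w2), "s08")              # forced single sample
  # 3 samples, 5 runs: first 3 runs exhaust the week, then redraw
  for (s in 1:20) {
    runs_s <- weekly_subsample(meta, n_runs = 5, seed = s)
    w3 <- runs_s$sample_id[runs_s$week_of_life == 3]
    expect_setequal(w3[1:3], sprintf("s%02d", 9:11))
    expect_true(all(w3[4:5] %in% sprintf("s%02d", 9:11)))
  }
  expect_identical(weekly_subsample(meta, 5, seed = 9),
                   weekly_subsample(meta, 5, seed = 9))
  expect_error(weekly_subsample(meta, 0), "n_runs")
})

test_that("single-sample weeks reproduce the analytic selection rate", {
  # one positive sample among 7 in the week: selection hits it w.p. 1/7
  counts <- matrix(0L, nrow = 1, ncol = 7)
  counts[1, 4] <- 25L
  tb <- make_counts(counts)
  meta <- make_meta(sprintf("s%02d", 1:7), 1:7)
  hits <- vapply(1:700, function(s) {
    runs <- weekly_subsample(meta, n_runs = 1, seed = s)
    detection_frequency(tb, meta, runs)$weeks_detected
  }, numeric(1))
  expect_equal(mean(hits), 1 / 7, tolerance = 0.04 * 7)
})

test_that("per-run detection never exceeds the reference", {
  dat <- default_infant()
  filt <- filter_features(drop_empty_samples(dat$table))
  stool <- dplyr::filter(dat$meta, matrix_type == "stool")
  runs <- weekly_subsample(stool, n_runs = 3, seed = 5)
  freq <- detection_frequency(filt, dat$meta, runs)
  expect_true(all(freq$weeks_detected <= freq$reference_weeks))
  expect_true(all(freq$below_3 == (freq$weeks_detected < 3)))
})

test_that("significance retention counts runs and partitions features", {
  ref <- structure(tibble(taxon = c("a", "b", "c"),
                          statistic = 1:3, p_raw = c(0.01, 0.5, 0.02),
                          q_bh = c(0.03, 0.6, 0.04),
                          significant = c(TRUE, FALSE, TRUE)),
                   class = c("event_test_tbl", "tbl_df", "tbl", "data.frame"))
  per_run <- tidyr::expand_grid(run = 1:5, taxon = c("a", "b", "c")) |>
    mutate(significant = (taxon == "a" & run %in% c(2, 5)),
           skipped = FALSE)
  ret <- significance_retention(ref, per_run)
  expect_equal(ret$retention$k_significant[ret$retention$taxon == "a"], 2L)
  expect_equal(ret$retention$k_significant[ret$retention$taxon == "b"], 0L)
  expect_false(ret$retention$significant_in_reference[
    ret$retention$taxon == "b"])
  expect_equal(sum(ret$summary$n_features), 3)
  bad <- per_run |> dplyr::filter(taxon != "c")
  expect_error(significance_retention(ref, bad), "different feature sets")
})

test_that("weekly runs lose transient colonizers but keep early ones", {
  dat <- default_infant()
  filt <- filter_features(drop_empty_samples(dat$table))
  stool <- dplyr::filter(dat$meta, matrix_type == "stool")
  tr <- dat$truth$features
  losses <- purrr::map_dfr(1:12, function(s) {
    runs <- weekly_subsample(stool, n_runs = 1, seed = 400 + s)
    detection_frequency(filt, dat$meta, runs) |>
      dplyr::inner_join(tr, by = c(taxon = "feature")) |>
      dplyr::group_by(archetype) |>
      dplyr::summarise(loss = mean((reference_weeks - weeks_detected) /
                                     pmax(reference_weeks, 1)),
                       .groups = "drop")
  }) |>
    dplyr::group_by(archetype) |>
    dplyr::summarise(loss = mean(loss), .groups = "drop")
  l <- setNames(losses$loss, losses$archetype)
  expect_lt(l[["early_life"]], 0.05)
  expect_gt(l[["later"]], l[["early_life"]])
  expect_gt(l[["re_appearing"]], l[["early_life"]])
})
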