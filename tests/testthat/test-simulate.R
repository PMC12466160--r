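test_that("the simulator is deterministic and respects depths", {
  cfg <- sim_config(rng_seed = 11)
  a <- simulate_infant(cfg)
  b <- simulate_infant(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$meta, b$meta)
  m <- as.matrix(a$table[-1])
  expect_true(all(m >= 0 & m == floor(m)))
  # meconium day 0 is all zero; every other sample carries reads
  expect_equal(sum(m[, 1]), 0)
  expect_true(all(colSums(m[, -1]) > 0))
  expect_equal(a$meta$matrix_type[1], "meconium")
  # one sample per requested day
  expect_equal(ncol(m), length(unique(a$meta$day_of_life)))
})

test_that("custom sampling emits exactly the requested days", {
  days <- c(3L, 10L, 50L, 200L)
  dat <- simulate_infant(sim_config(sampling = days, rng_seed = 2))
  expect_equal(dat$meta$day_of_life, c(0L, days))
})

test_that("later colonizers are silent before onset when noise is off", {
  cfg <- sim_config(n_features = 2,
                    archetypes = c(early_life = 1, re_appearing = 0,
                                   later = 1, transient_maternal = 0),
                    noise_sd_early = 0, noise_sd_late = 0,
                    dominant_steps = list(day = 1, level = 5),
                    n_probiotic_targets = 0, n_vaccination_onset = 0,
                    rng_seed = 3)
  dat <- simulate_infant(cfg)
  m <- as.matrix(dat$table[-1])
  onset <- dat$truth$features$onset_day[dat$truth$features$archetype == "later"]
  pre <- dat$meta$day_of_life < onset - 6 & dat$meta$day_of_life > 0
  expect_true(all(m[2, pre] == 0))
  expect_gt(sum(m[2, dat$meta$day_of_life > onset + 10]), 0)
})

test_that("the default table passes the 2 percent / 10 read filter widely", {
  dat <- default_infant()
  filt <- filter_features(drop_empty_samples(dat$table), 0.02, 10)
  expect_gte(nrow(filt), 50)
})

test_that("doubling the probiotic effect does not weaken the signal", {
  stat_for <- function(effect, seed) {
    dat <- simulate_infant(sim_config(probiotic_effect = effect,
                                      rng_seed = seed))
    filt <- filter_features(drop_empty_samples(dat$table))
    clr <- czm_replace(filt) |> clr_transform()
    des <- build_event_windows(
      dat$events[dat$events$event_type == "probiotic", ], "probiotic")
    res <- run_event_tests(clr, dat$meta, des)
    mean(res$statistic[res$taxon %in% dat$truth$probiotic_targets])
  }
  seeds <- 1:6
  weak <- vapply(seeds, function(s) stat_for(2, s), numeric(1))
  strong <- vapply(seeds, function(s) stat_for(4, s), numeric(1))
  expect_gt(mean(strong), mean(weak))
})

test_that("weekly cohorts vary by subject and separate in PERMANOVA", {
  coh <- simulate_cohort(n_subjects = 4, seed = 7)
  expect_length(coh$subjects, 4)
  sizes <- vapply(coh$subjects, function(s) nrow(s$meta) - 1L, integer(1))
  expect_true(all(sizes >= 40 & sizes <= 52))   # 52 weeks, 10 % missing
  # identical seeds reproduce the cohort
  coh2 <- simulate_cohort(n_subjects = 4, seed = 7)
  expect_identical(coh$subjects[[1]]$table, coh2$subjects[[1]]$table)
  # strong planted subject effects floor the permutation p at 1/(n+1)
  tabs <- purrr::map(coh$subjects, function(s) drop_empty_samples(s$table))
  clrs <- purrr::map(tabs, function(tb) czm_replace(tb) |> clr_transform())
  clr <- dplyr::bind_rows(clrs)
  d <- aitchison_distance_matrix(clr)
  subj <- coh$meta$subject_id[match(clr$sample_id, coh$meta$sample_id)]
  fit <- permanova(d, subj, n_permutations = 999, seed = 3)
  expect_equal(fit$p_value, 0.001)
})

test_that("truth report scores perfect and shuffled inference sensibly", {
  dat <- default_infant()
  perfect <- dat$truth$features |>
    dplyr::transmute(feature, label = expected_label)
  rep <- truth_report(dat$truth, labels = perfect)
  expect_true(all(rep$label_recovery$rate == 1))
  set.seed(61)
  shuffled <- perfect |> dplyr::mutate(label = sample(label))
  rep2 <- truth_report(dat$truth, labels = shuffled)
  overall <- rep2$label_recovery$rate[rep2$label_recovery$archetype == "overall"]
  expect_lt(overall, 0.8)
  expect_true(all(rep2$label_recovery$rate >= 0 &
                    rep2$label_recovery$rate <= 1))
  bp <- truth_report(dat$truth, breakpoint_days = c(14, 113, 133, 209))
  expect_true(all(bp$breakpoints$distance <= 1))
})
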