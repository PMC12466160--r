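test_that("detection trajectories separate absent from unobserved", {
  # weeks 1..4 sampled on days 1, 8, 22 (week 3 unobserved)
  counts <- matrix(c(2L, 0L, 0L,   0L, 0L, 4L), nrow = 2, byrow = TRUE)
  tb <- make_counts(counts)
  meta <- make_meta(c("s01", "s02", "s03"), c(1L, 8L, 22L))
  tr <- detection_trajectory(tb, meta, "g01", weeks = 1:4)
  expect_equal(unname(tr$status), c("detected", "absent", "unobserved", "absent"))
  expect_equal(tr$first_detection_week, 1L)
  # the unobserved week 3 does not extend the observed gap (weeks 2, 4)
  expect_equal(tr$longest_gap, 2L)
  tr2 <- detection_trajectory(tb, meta, "g02", weeks = 1:4)
  expect_equal(tr2$first_detection_week, 4L)
  expect_equal(tr2$n_weeks_detected, 1L)
  expect_error(detection_trajectory(tb, meta, "nope"), "unknown feature")
})

test_that("colonizer rules match the narrative archetypes", {
  mk <- function(status) trajectory_stats_for_test(status)
  full <- classify_colonizer(mk(rep("detected", 52)))
  expect_equal(full$label, "early_life")
  re <- classify_colonizer(mk(c(rep("detected", 2), rep("absent", 18),
                                rep("detected", 32))))
  expect_equal(re$label, "re_appearing")
  late <- classify_colonizer(mk(c(rep("absent", 29), rep("detected", 23))))
  expect_equal(late$label, "later")
  never <- classify_colonizer(mk(rep("absent", 52)))
  expect_equal(never$label, "unclassified")
  # early pulse with a short gap and high persistence stays early_life
  short_gap <- classify_colonizer(mk(c("detected", "detected",
                                       rep("absent", 4), rep("detected", 46))))
  expect_equal(short_gap$label, "early_life")
})

test_that("labels are exhaustive and mutually exclusive over random tracks", {
  set.seed(53)
  labs <- c("early_life", "re_appearing", "later", "unclassified")
  for (rep in 1:200) {
    status <- sample(c("detected", "absent", "unobserved"), 52,
                     replace = TRUE, prob = c(0.4, 0.4, 0.2))
    out <- classify_colonizer(trajectory_stats_for_test(status))
    expect_equal(nrow(out), 1)
    expect_true(out$label %in% labs)
    # purity: same trajectory always gets the same label
    out2 <- classify_colonizer(trajectory_stats_for_test(status))
    expect_identical(out$label, out2$label)
  }
})

test_that("ward clustering of trajectories is deterministic and sane", {
  clr <- tibble(sample_id = c("s1", "s2", "s3"),
                a = c(1, 2, 3), b = c(1, 2, 3),
                c = c(-2, -4, -6), d = c(-2.1, -4, -6),
                e = c(9, 0, 9), f = c(9.2, 0.1, 9))
  hc <- cluster_genera(clr)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height[1], 0)          # identical a and b merge at 0
  merged_first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(merged_first, c("a", "b"))
  # three well-separated pairs at k = 3
  grp <- cutree(hc, k = 3)
  expect_equal(unname(grp[c("a", "b")]), rep(grp[["a"]], 2))
  expect_equal(unname(grp[c("c", "d")]), rep(grp[["c"]], 2))
  expect_equal(unname(grp[c("e", "f")]), rep(grp[["e"]], 2))
  hc2 <- cluster_genera(clr)
  expect_identical(hc$merge, hc2$merge)
  expect_identical(hc$order, hc2$order)
  nwk <- cluster_newick(hc)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("maternal overlap applies the 3-read / consistent-1-read rules", {
  infant <- make_counts(matrix(c(3L, 0L, 0L,   1L, 1L, 1L,   2L, 0L, 0L,
                                 0L, 0L, 5L), nrow = 4, byrow = TRUE),
                        taxa = c("strong_once", "weak_consistent",
                                 "weak_once", "late_strong"))
  mat <- list(stool = make_counts(matrix(c(3L, 2L, 0L, 3L), ncol = 1),
                                  taxa = c("strong_once", "weak_consistent",
                                           "weak_once", "late_strong")))
  ov <- maternal_overlap(mat, infant)
  expect_setequal(ov$infant_features,
                  c("strong_once", "weak_consistent", "late_strong"))
  expect_setequal(ov$maternal$stool, c("strong_once", "late_strong"))
  expect_setequal(ov$shared_any, c("strong_once", "late_strong"))
  # partition: shared + infant-only = infant set
  inf_row <- ov$summary[ov$summary$source == "infant", ]
  expect_equal(inf_row$n_shared_with_infant + inf_row$n_source_only,
               length(ov$infant_features))
  expect_error(maternal_overlap(mat, infant[, 1:3]), "three infant samples")
})

test_that("planted archetypes are recovered on the default simulation", {
  dat <- default_infant()
  filt <- filter_features(drop_empty_samples(dat$table))
  labels <- classify_colonizers(filt, dat$meta)
  rep <- truth_report(dat$truth, labels = labels)
  overall <- rep$label_recovery[rep$label_recovery$archetype == "overall", ]
  expect_gte(overall$rate, 0.9)
})
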