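test_that("event windows follow the study's conventions", {
  ev <- function(type, s, e) tibble(subject_id = "infantA", event_type = type,
                                    start_day = s, end_day = e, label = "")
  point <- build_event_windows(ev("vaccination", 112L, 112L), "point")
  expect_equal(point$start_day, c(105L, 113L))
  expect_equal(point$end_day, c(111L, 119L))
  expect_equal(attr(point, "test_kind"), "mann_whitney")
  diet <- build_event_windows(ev("solid_food", 133L, 133L), "diet")
  expect_equal(diet$start_day, c(105L, 133L, 161L, 189L, 217L))
  expect_equal(diet$end_day, c(132L, 160L, 188L, 216L, 244L))
  pro <- build_event_windows(ev("probiotic", 12L, 60L), "probiotic")
  expect_equal(pro$start_day, c(0L, 12L, 61L))   # pre window clipped at birth
  expect_equal(pro$end_day, c(11L, 60L, 90L))
  cohort <- build_event_windows(ev("vaccination", 112L, 112L),
                                "cohort_vaccination")
  expect_equal(cohort$window, c("week_before", "event_week", "week_after"))
  expect_equal(cohort$start_day, c(99L, 106L, 113L))  # weeks 15-17
  expect_equal(attr(cohort, "pooling"), "average_per_subject_per_window")
})

test_that("mann-whitney agrees with enumeration and handles ties", {
  got <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 0.1)
  expect_equal(got$p_value, oracle_mwu(c(1, 2, 3), c(4, 5, 6)))
  set.seed(11)
  for (rep in 1:10) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mwu(x, y),
                 tolerance = 1e-12)
    expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value)
  }
  expect_equal(mann_whitney_u(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("kruskal-wallis matches the hand value and the exact oracle", {
  got <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(got$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21,
               tolerance = 1e-12)
  expect_equal(got$statistic, 4.571, tolerance = 1e-3)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))$statistic, 0)
  # monotone-transform invariance of the rank statistic
  g <- list(c(0.3, 1.2, 0.9), c(2.2, 0.1), c(5, 0.7))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, exp))$statistic)
  # exact path vs an oracle that evaluates stats::kruskal.test per labeling
  set.seed(19)
  for (rep in 1:5) {
    g <- list(rnorm(3), rnorm(3), rnorm(2))
    got <- kruskal_wallis(g, exact = TRUE)
    vals <- unlist(g)
    h_of <- function(lab) unname(kruskal.test(vals, factor(lab))$statistic)
    h_obs <- h_of(rep(1:3, lengths(g)))
    combos <- utils::combn(8, 3, simplify = FALSE)
    ps <- 0; tot <- 0
    for (a in combos) {
      rest <- setdiff(1:8, a)
      for (b in utils::combn(rest, 3, simplify = FALSE)) {
        lab <- integer(8); lab[a] <- 1; lab[b] <- 2; lab[setdiff(rest, b)] <- 3
        tot <- tot + 1
        if (h_of(lab) >= h_obs - 1e-12) ps <- ps + 1
      }
    }
    expect_equal(got$p_value, ps / tot, tolerance = 1e-12)
    expect_equal(got$statistic, h_obs, tolerance = 1e-12)
  }
})

test_that("dunn post hoc is antisymmetric with the largest gap extreme", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  d <- dunn_posthoc(g)
  expect_equal(nrow(d), 3)
  pair13 <- d[d$group1 == 1 & d$group2 == 3, ]
  expect_equal(max(abs(d$z)), abs(pair13$z))
  # antisymmetry via reversed group order
  d_rev <- dunn_posthoc(rev(g))
  expect_equal(d_rev$z[d_rev$group1 == 1 & d_rev$group2 == 3], -pair13$z)
  same <- dunn_posthoc(list(c(1, 2), c(1, 2)))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

test_that("friedman matches the hand value and stats::friedman.test", {
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(1, 5, 9))   # identical orderings
  got <- friedman_rank_test(m)
  expect_equal(got$statistic, 6, tolerance = 1e-12)
  expect_equal(got$df, 2)
  all_equal <- matrix(3, nrow = 4, ncol = 3)
  expect_equal(friedman_rank_test(all_equal)$statistic, 0)
  expect_equal(friedman_rank_test(all_equal)$p_value, 1)
  # tie-free random blocks agree with the base-R implementation
  set.seed(23)
  for (rep in 1:8) {
    mm <- matrix(rnorm(15), nrow = 5)
    base <- stats::friedman.test(mm)
    got <- friedman_rank_test(mm)
    expect_equal(got$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, base$p.value, tolerance = 1e-12)
    # within-block monotone transform invariance
    expect_equal(friedman_rank_test(exp(mm))$statistic, got$statistic)
  }
  expect_error(friedman_rank_test(matrix(c(1, NA, 2, 3), 2)), "ncomplete")
})

test_that("conover post hoc ranks pairs by rank-sum gaps", {
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(1, 5, 9))
  co <- conover_posthoc(m)
  p13 <- co$p_value[co$group1 == 1 & co$group2 == 3]
  expect_true(all(p13 <= co$p_value))
  # noisy blocks: smallest p still for the extreme pair, and equal rank sums
  # give p = 1
  m2 <- rbind(c(1, 2, 3), c(2, 1, 3), c(1, 2, 3), c(2, 1, 3))
  co2 <- conover_posthoc(m2)
  expect_equal(co2$p_value[co2$group1 == 1 & co2$group2 == 2], 1)
  expect_equal(co2$statistic[co2$group1 == 1 & co2$group2 == 2], 0)
  set.seed(29)
  m3 <- matrix(rnorm(20), nrow = 5) + matrix(rep(c(0, 0.5, 1, 3), each = 5), nrow = 5)
  co3 <- conover_posthoc(m3)
  expect_equal(which.min(co3$p_value),
               which(co3$group1 == 1 & co3$group2 == 4))
})

test_that("benjamini-hochberg matches the step-up construction", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bh_adjust(p)
    expect_true(all(q <= 1))
    # monotone in the p ordering
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    # selection at q <= 0.1 equals the classic step-up rule
    m <- length(p)
    ps <- sort(p)
    kmax <- suppressWarnings(max(which(ps <= 0.1 * seq_len(m) / m)))
    classic <- if (is.finite(kmax)) p <= ps[kmax] else rep(FALSE, m)
    expect_equal(q <= 0.1, classic)
  }
})

test_that("profile averaging is per subject per window and stays closed", {
  clr <- tibble(sample_id = c("a1", "a2", "b1"),
                x = c(1, 3, 0), y = c(-2, 1, 1), z = c(1, -4, -1))
  meta <- make_meta(c("a1", "a2", "b1"), c(5L, 6L, 5L),
                    subject = c("A", "A", "B"))
  ev <- tibble(subject_id = "A", event_type = "other", start_day = 10L,
               end_day = 10L, label = "")
  design <- build_event_windows(ev, "point")
  prof <- average_profiles_per_window(clr, meta, design)
  a_pre <- prof[prof$subject_id == "A" & prof$window == "pre", ]
  expect_equal(a_pre$n_samples, 2L)
  expect_equal(a_pre$x, 2)                      # mean of 1 and 3
  expect_equal(a_pre$x + a_pre$y + a_pre$z, 0)  # closure is linear
})

test_that("event battery flags planted effects and permutes consistently", {
  # 40 null features + 5 with a window-2 shift; two windows, MWU design
  set.seed(37)
  n <- 24
  days <- 1:24
  meta <- make_meta(sprintf("s%02d", days), days)
  ev <- tibble(subject_id = "infantA", event_type = "medication",
               start_day = 12L, end_day = 12L, label = "")
  design <- build_event_windows(ev, "point")
  feat <- sprintf("f%02d", 1:45)
  vals <- matrix(rnorm(n * 45, sd = 0.5), nrow = n)
  shifted <- meta$day_of_life >= 13
  vals[shifted, 41:45] <- vals[shifted, 41:45] + 4
  clr <- tibble(sample_id = meta$sample_id) |>
    bind_cols(as_tibble(`colnames<-`(vals, feat), .name_repair = "minimal"))
  res <- run_event_tests(clr, meta, design)
  expect_s3_class(res, "event_test_tbl")
  expect_true(all(res$significant[res$taxon %in% feat[41:45]]))
  expect_lt(sum(res$significant[res$taxon %in% feat[1:40]]), 5)
  # permuting feature order permutes outcomes identically
  res2 <- run_event_tests(clr[, c("sample_id", rev(feat))], meta, design)
  expect_equal(tidy(res2)[match(feat, res2$taxon), ], tidy(res),
               ignore_attr = TRUE)
  expect_equal(glance(res)$n_features, 45)
})

test_that("permanova matches oracle and vegan on small problems", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(5, 5), c(5.1, 5), c(5, 5.1))
  d <- as.matrix(dist(pts))
  labels <- rep(c("a", "b"), each = 3)
  fit <- permanova(d, labels, method = "exact")
  expect_equal(fit$p_value, 0.1)    # 2 of the 20 labelings reach F_obs
  expect_equal(fit$statistic, oracle_permanova_f(d, labels), tolerance = 1e-12)
  # vegan as an independent cross-check of the pseudo-F
  if (requireNamespace("vegan", quietly = TRUE)) {
    av <- vegan::adonis2(as.dist(d) ~ g, data = data.frame(g = labels),
                         permutations = 99)
    expect_equal(fit$statistic, av$F[1], tolerance = 1e-8)
  }
  # relabeling symmetry and sampled path determinism
  fit_swap <- permanova(d, rep(c("b", "a"), each = 3), method = "exact")
  expect_equal(fit_swap$statistic, fit$statistic)
  s1 <- permanova(d, labels, n_permutations = 199, seed = 4)
  s2 <- permanova(d, labels, n_permutations = 199, seed = 4)
  expect_equal(s1$p_value, s2$p_value)
  expect_error(permanova(d, c("a", "a", "a", "a", "a", "b")), ">= 2 samples")
  expect_error(permanova(matrix(0, 4, 4), rep(c("a", "b"), 2)), "constant")
})

test_that("permanova p-values are roughly uniform under the null", {
  set.seed(43)
  ps <- replicate(60, {
    pts <- matrix(rnorm(16), ncol = 2)
    d <- as.matrix(dist(pts))
    permanova(d, rep(c("a", "b"), each = 4), n_permutations = 99,
              seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
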