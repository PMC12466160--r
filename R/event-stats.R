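#' Build the analysis windows around an early-life event
#'
#' Encodes the window conventions of the analysis:
#' \describe{
#'   \item{point}{(e.g. a vaccination dose with a known day) the 7-day
#'     period before and after the event: `[d-7, d-1]` and `[d+1, d+7]`;
#'     tested with the Mann-Whitney U test.}
#'   \item{diet}{five 28-day intervals — the final month before solid-food
#'     introduction and four subsequent monthly intervals; Kruskal-Wallis
#'     with Dunn post hoc.}
#'   \item{probiotic}{up to 30 days before, the exposure itself, and 30
#'     days after: `[start-30, start-1]`, `[start, end]`, `[end+1,
#'     end+30]`; Kruskal-Wallis with Dunn post hoc.}
#'   \item{cohort_vaccination}{the week prior, the vaccination week and the
#'     week after (the exact day is often unrecorded in diaries); Friedman
#'     with Conover post hoc on per-subject window averages.}
#' }
#' Pre-event windows are clipped at birth (day `clip_min_day`).
#'
#' @param event A one-row event tibble (`subject_id, event_type, start_day,
#'   end_day, label`).
#' @param design_kind One of `"point"`, `"diet"`, `"probiotic"`,
#'   `"cohort_vaccination"`.
#' @param clip_min_day Earliest admissible day (default 0 = birth).
#' @return A tibble `(window, start_day, end_day)` of class `event_design`
#'   with attributes `test_kind`, `pooling` and `event`.
#' @export
build_event_windows <- function(event,
                                design_kind = c("point", "diet", "probiotic",
                                                "cohort_vaccination"),
                                clip_min_day = 0L) {
  design_kind <- match.arg(design_kind)
  event <- as_tibble(event)
  if (nrow(event) != 1) abort("build_event_windows expects a single event")
  d <- event$start_day
  e <- event$end_day
  win <- switch(design_kind,
    point = tibble(window = c("pre", "post"),
                   start_day = c(d - 7L, d + 1L),
                   end_day = c(d - 1L, d + 7L)),
    diet = tibble(window = c("pre_month", paste0("month", 1:4)),
                  start_day = c(d - 28L, d, d + 28L, d + 56L, d + 84L),
                  end_day = c(d - 1L, d + 27L, d + 55L, d + 83L, d + 111L)),
    probiotic = tibble(window = c("before", "during", "after"),
                       start_day = c(d - 30L, d, e + 1L),
                       end_day = c(d - 1L, e, e + 30L)),
    cohort_vaccination = {
      w <- week_of_life(d)
      wks <- c(w - 1L, w, w + 1L)
      if (any(wks < 1)) abort("vaccination in week 1 has no prior week")
      tibble(window = c("week_before", "event_week", "week_after"),
             start_day = (wks - 1L) * 7L + 1L,
             end_day = wks * 7L)
    })
  win$start_day <- pmax(win$start_day, as.integer(clip_min_day))
  if (design_kind == "cohort_vaccination" && win$start_day[1] == 1L) {
    win$start_day[1] <- as.integer(clip_min_day)  # week 1 includes day 0
  }
  if (any(win$end_day < win$start_day)) {
    abort("event too close to the start of sampling: a window is empty by construction")
  }
  test_kind <- switch(design_kind,
                      point = "mann_whitney",
                      diet = "kruskal_wallis_dunn",
                      probiotic = "kruskal_wallis_dunn",
                      cohort_vaccination = "friedman_conover")
  structure(win,
            class = c("event_design", class(win)),
            test_kind = test_kind,
            pooling = if (test_kind == "friedman_conover")
              "average_per_subject_per_window" else "none",
            event = event)
}

# ---- rank tests -------------------------------------------------------------

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U via [stats::wilcox.test()]: exact by
#' enumeration when `n_x + n_y <= 12` and the data are tie-free, otherwise
#' the normal approximation with tie and continuity correction. When every
#' observation is identical the test is degenerate and `p = 1` is returned.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A tibble `(statistic, p_value, method)`; `statistic` is U for
#'   group `x`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(tibble(statistic = length(x) * length(y) / 2, p_value = 1,
                  method = "degenerate (complete ties)"))
  }
  use_exact <- (length(pooled) <= 12) && !any(duplicated(pooled))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (use_exact) "exact" else "normal approximation")
}

# enumerate all distinct ways to split n items into groups of given sizes;
# returns a list of integer label vectors (1-based group labels)
multiset_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  recurse <- function(avail, labels, g) {
    if (g > length(sizes)) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    if (g == length(sizes)) {
      labels[avail] <- g
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    picks <- utils::combn(avail, sizes[g], simplify = FALSE)
    for (p in picks) {
      lab <- labels
      lab[p] <- g
      recurse(setdiff(avail, p), lab, g + 1)
    }
  }
  recurse(seq_len(n), integer(n), 1)
  out
}

kw_statistic <- function(values, labels) {
  r <- rank(values)
  n <- length(values)
  groups <- split(r, labels)
  h <- 12 / (n * (n + 1)) * sum(vapply(groups, function(g) sum(g)^2 / length(g),
                                       numeric(1))) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(0)
  h / corr
}

#' Kruskal-Wallis test by ranks
#'
#' Tie-corrected H with p from the chi-square reference (k-1 df) via
#' [stats::kruskal.test()]. With `exact = TRUE` and total n <= 8 the p-value
#' is instead computed by complete enumeration of all group assignments.
#' All-identical observations give `H = 0, p = 1`.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @param exact Enumerate the permutation null exactly (total n <= 8 only).
#' @return A tibble `(statistic, df, p_value, method)`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("need >= 2 non-empty groups")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(seq_along(groups), lengths(groups))
  if (length(unique(values)) == 1) {
    return(tibble(statistic = 0, df = length(groups) - 1L, p_value = 1,
                  method = "degenerate (complete ties)"))
  }
  if (exact) {
    if (length(values) > 8) abort("exact enumeration supported only for total n <= 8")
    h_obs <- kw_statistic(values, labels)
    assigns <- multiset_assignments(lengths(groups))
    hs <- vapply(assigns, function(a) kw_statistic(values, a), numeric(1))
    return(tibble(statistic = h_obs, df = length(groups) - 1L,
                  p_value = mean(hs >= h_obs - 1e-12),
                  method = "exact enumeration"))
  }
  kt <- stats::kruskal.test(values, factor(labels))
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, method = "chi-square approximation")
}

#' Dunn's post hoc test
#'
#' All pairwise comparisons after a Kruskal-Wallis test, on the pooled
#' mid-ranks with the tie-corrected variance:
#' `z_ij = (meanrank_i - meanrank_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided normal
#' p per pair, Benjamini-Hochberg adjusted across the pairs.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return A tibble `(group1, group2, z, p_value, q_value)`.
#' @export
dunn_posthoc <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("need >= 2 non-empty groups")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(seq_along(groups), lengths(groups))
  n <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, labels, mean)
  sizes <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  var_base <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(groups), 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / sizes[i] + 1 / sizes[j]))
    z <- if (se == 0) 0 else (mean_rank[i] - mean_rank[j]) / se
    tibble(group1 = i, group2 = j, z = unname(z),
           p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- bind_rows(rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Friedman test for complete blocks
#'
#' Within-block mid-ranks; `Q = 12/(n k (k+1)) * sum R_j^2 - 3 n (k+1)`,
#' divided by the tie-correction factor
#' `1 - sum(t^3 - t) / (n k (k^2 - 1))`; p from chi-square with k-1 df.
#' Agrees with [stats::friedman.test()] on tie-free data.
#'
#' @param block_matrix Numeric matrix, subjects in rows, conditions in
#'   columns; every cell observed.
#' @return A tibble `(statistic, df, p_value)`.
#' @export
friedman_rank_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (anyNA(m)) abort("incomplete blocks: average or pool samples upstream")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("need >= 2 subjects and >= 2 conditions")
  r <- t(apply(m, 1, rank))
  rsum <- colSums(r)
  q0 <- 12 / (n * k * (k + 1)) * sum(rsum^2) - 3 * n * (k + 1)
  tie_sum <- sum(apply(m, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  corr <- 1 - tie_sum / (n * k * (k^2 - 1))
  stat <- if (corr <= 0) 0 else q0 / corr
  tibble(statistic = stat, df = k - 1L,
         p_value = if (corr <= 0) 1 else stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Conover's post hoc test after Friedman
#'
#' Pairwise comparisons of condition rank sums with the Conover
#' t-statistic on `(n-1)(k-1)` degrees of freedom, Benjamini-Hochberg
#' adjusted across pairs. A perfectly concordant block matrix has zero
#' residual variance; unequal rank sums then get p = 0 and equal ones
#' p = 1.
#'
#' @param block_matrix Numeric matrix, subjects in rows, conditions in
#'   columns.
#' @return A tibble `(group1, group2, statistic, p_value, q_value)`.
#' @export
conover_posthoc <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (anyNA(m)) abort("incomplete blocks: average or pool samples upstream")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("need >= 2 subjects and >= 2 conditions")
  r <- t(apply(m, 1, rank))
  rsum <- colSums(r)
  a1 <- sum(r^2)
  c1 <- n * k * (k + 1)^2 / 4
  tt <- if (a1 == c1) 0 else (k - 1) * sum((rsum - n * (k + 1) / 2)^2) / (a1 - c1)
  inner <- (2 * n * (a1 - c1)) / ((n - 1) * (k - 1)) * (1 - tt / (n * (k - 1)))
  se <- if (inner > 0) sqrt(inner) else 0
  df <- (n - 1) * (k - 1)
  pairs <- utils::combn(k, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    d <- rsum[i] - rsum[j]
    if (se == 0) {
      stat <- if (d == 0) 0 else Inf * sign(d)
      p <- if (d == 0) 1 else 0
    } else {
      stat <- d / se
      p <- 2 * stats::pt(-abs(stat), df)
    }
    tibble(group1 = i, group2 = j, statistic = unname(stat), p_value = p)
  })
  out <- bind_rows(rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m p_(j) / j)`, capped at
#' 1, mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# ---- window assembly and the per-feature battery ----------------------------

# Attach the design window (or NA) to each metadata row of one subject set.
assign_windows <- function(meta, design) {
  win <- as_tibble(design)[, c("window", "start_day", "end_day")]
  hit <- purrr::map_chr(meta$day_of_life, function(d) {
    k <- which(d >= win$start_day & d <= win$end_day)
    if (length(k) == 0) NA_character_ else win$window[k[1]]
  })
  meta |> mutate(window = factor(hit, levels = win$window))
}

#' Average CLR profiles per subject per window
#'
#' For every subject with at least one sample inside a window, the
#' arithmetic mean of that subject's CLR profiles across all its in-window
#' samples (averaging is linear, so profile rows still sum to zero).
#' Subjects lacking a required window are simply absent from that window's
#' rows; the test layer drops or errors on them as its design requires.
#'
#' @param clr Samples-by-features CLR tibble.
#' @param meta Metadata tibble.
#' @param design An `event_design` ([build_event_windows()]).
#' @return A tibble `(subject_id, window, n_samples, <features...>)`.
#' @export
average_profiles_per_window <- function(clr, meta, design) {
  feat <- setdiff(names(clr), "sample_id")
  joined <- clr |>
    inner_join(assign_windows(meta, design) |>
                 select("sample_id", "subject_id", "window"),
               by = "sample_id") |>
    filter(!is.na(.data$window))
  joined |>
    group_by(.data$subject_id, .data$window) |>
    summarise(n_samples = dplyr::n(),
              across(dplyr::all_of(feat), mean), .groups = "drop")
}

#' Run an event-window test battery over all features
#'
#' Applies the design's test to every feature's CLR values grouped by
#' window: Mann-Whitney U for two-window designs, Kruskal-Wallis (plus
#' Dunn post hoc) for three or more windows, or Friedman (plus Conover)
#' on per-subject window-averaged profiles for cohort designs. Raw
#' p-values are Benjamini-Hochberg adjusted across features and flagged
#' significant at `q <= fdr_threshold`.
#'
#' @param clr Samples-by-features CLR tibble.
#' @param meta Metadata tibble covering the CLR samples.
#' @param design An `event_design`.
#' @param fdr_threshold Significance gate on the q-value (default 0.1).
#' @param min_per_window Minimum samples (or subjects) required per window.
#' @return A tibble of class `event_test_tbl` with columns `(taxon,
#'   statistic, p_raw, q_bh, significant)`, list-columns `window_summary`
#'   (per-window n and median CLR) and `posthoc` (pairwise results where
#'   the design has one), and the design stored as attribute.
#' @export
run_event_tests <- function(clr, meta, design, fdr_threshold = 0.1,
                            min_per_window = 1L) {
  test_kind <- attr(design, "test_kind")
  event <- attr(design, "event")
  feat <- setdiff(names(clr), "sample_id")
  if (test_kind == "friedman_conover") {
    prof <- average_profiles_per_window(clr, meta, design)
    counts <- prof |> count(.data$subject_id)
    complete <- counts$subject_id[counts$n == nrow(design)]
    dropped <- setdiff(unique(prof$subject_id), complete)
    if (length(dropped) > 0) {
      inform(sprintf("dropping %d subject(s) without samples in every window: %s",
                     length(dropped), paste(dropped, collapse = ", ")))
    }
    prof <- prof |> filter(.data$subject_id %in% complete)
    if (length(complete) < 2) {
      abort("fewer than 2 subjects observed in every window")
    }
    wins <- levels(prof$window)
    rows <- purrr::map(feat, function(f) {
      block <- prof |>
        select("subject_id", "window", dplyr::all_of(f)) |>
        tidyr::pivot_wider(names_from = "window", values_from = dplyr::all_of(f))
      bm <- as.matrix(block[, wins])
      ft <- friedman_rank_test(bm)
      tibble(taxon = f, statistic = ft$statistic, p_raw = ft$p_value,
             window_summary = list(
               prof |> group_by(.data$window) |>
                 summarise(n = dplyr::n(),
                           median_clr = stats::median(.data[[f]]),
                           .groups = "drop")),
             posthoc = list(conover_posthoc(bm)))
    })
  } else {
    sub_meta <- meta
    if (!is.null(event) && "subject_id" %in% names(meta)) {
      sub_meta <- meta |> filter(.data$subject_id == event$subject_id)
    }
    grouped <- clr |>
      inner_join(assign_windows(sub_meta, design) |>
                   select("sample_id", "window"), by = "sample_id") |>
      filter(!is.na(.data$window))
    sizes <- table(grouped$window)
    short <- names(sizes)[sizes < min_per_window]
    if (length(short) > 0) {
      abort(sprintf("window(s) without enough samples: %s",
                    paste(short, collapse = ", ")))
    }
    rows <- purrr::map(feat, function(f) {
      vals <- split(grouped[[f]], grouped$window)
      summ <- tibble(window = names(vals),
                     n = lengths(vals),
                     median_clr = vapply(vals, stats::median, numeric(1)))
      if (test_kind == "mann_whitney") {
        mt <- mann_whitney_u(vals[[1]], vals[[2]])
        tibble(taxon = f, statistic = mt$statistic, p_raw = mt$p_value,
               window_summary = list(summ), posthoc = list(NULL))
      } else {
        kt <- kruskal_wallis(vals)
        tibble(taxon = f, statistic = kt$statistic, p_raw = kt$p_value,
               window_summary = list(summ),
               posthoc = list(dunn_posthoc(vals)))
      }
    })
  }
  out <- bind_rows(rows)
  out$q_bh <- bh_adjust(out$p_raw)
  out$significant <- out$q_bh <= fdr_threshold
  out <- out[, c("taxon", "statistic", "p_raw", "q_bh", "significant",
                 "window_summary", "posthoc")]
  structure(out, class = c("event_test_tbl", class(out)),
            design = design, fdr_threshold = fdr_threshold)
}

# ---- PERMANOVA --------------------------------------------------------------

permanova_f <- function(d2, labels, n) {
  ss_total <- sum(d2) / (2 * n)          # sum over ordered pairs = 2x upper
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  a <- length(unique(labels))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F from the partition of the squared-distance sums (the
#' Gower-centered formulation): `F = (SS_between/(a-1)) / (SS_within/(N-a))`.
#' The p-value comes from label permutations,
#' `p = (1 + #\{F_perm >= F_obs\}) / (n_permutations + 1)`, or from complete
#' enumeration of all distinct labelings when `method = "exact"` (then
#' `p = #\{F >= F_obs\} / n_labelings`, the observed labeling included).
#' Deterministic given `seed`.
#'
#' @param dist_matrix Symmetric distance matrix (e.g.
#'   [aitchison_distance_matrix()]).
#' @param grouping Group label per sample, >= 2 groups with >= 2 samples
#'   each.
#' @param n_permutations Number of sampled permutations (default 999).
#' @param seed Integer seed.
#' @param method `"sampled"` or `"exact"` enumeration.
#' @return An object of class `permanova_fit`; see [tidy.permanova_fit()].
#' @export
permanova <- function(dist_matrix, grouping, n_permutations = 999,
                      seed = 1L, method = c("sampled", "exact")) {
  method <- match.arg(method)
  d <- as.matrix(dist_matrix)
  n <- nrow(d)
  if (length(grouping) != n) abort("grouping length must match the distance matrix")
  labels <- as.character(grouping)
  sizes <- table(labels)
  if (length(sizes) < 2) abort("need >= 2 groups")
  if (any(sizes < 2)) abort("every group needs >= 2 samples")
  if (max(d) == 0) abort("constant (all-zero) distance matrix: F undefined")
  d2 <- d^2
  f_obs <- permanova_f(d2, labels, n)
  if (method == "exact") {
    assigns <- multiset_assignments(as.integer(sizes))
    # map group slot -> label name, order of sizes table
    fs <- vapply(assigns, function(a) permanova_f(d2, a, n), numeric(1))
    p <- mean(fs >= f_obs - 1e-12)
    n_used <- length(assigns)
  } else {
    hits <- with_seed(seed, {
      h <- 0L
      for (b in seq_len(n_permutations)) {
        if (permanova_f(d2, labels[sample.int(n)], n) >= f_obs - 1e-12) {
          h <- h + 1L
        }
      }
      h
    })
    p <- (1 + hits) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(list(statistic = f_obs, p_value = p, method = method,
                 n_permutations = n_used, n_samples = n,
                 n_groups = length(sizes), seed = seed),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%s, %d %s)\n",
              x$statistic, x$p_value, x$method, x$n_permutations,
              if (x$method == "exact") "labelings" else "permutations"))
  invisible(x)
}
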