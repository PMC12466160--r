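# Weekly detection status for all features of one subject's table:
# "detected" / "absent" / "unobserved" per (feature, week).
weekly_detection <- function(table, meta, weeks = 1:52) {
  m <- count_matrix(table)
  meta <- meta |> filter(.data$sample_id %in% colnames(m))
  status <- matrix("unobserved", nrow = nrow(m), ncol = length(weeks),
                   dimnames = list(rownames(m), paste0("week", weeks)))
  for (k in seq_along(weeks)) {
    sids <- meta$sample_id[meta$week_of_life == weeks[k]]
    if (length(sids) == 0) next
    pos <- rowSums(m[, sids, drop = FALSE] > 0) > 0
    status[, k] <- ifelse(pos, "detected", "absent")
  }
  status
}

#' Weekly detection trajectory of one feature
#'
#' Per week of life, whether the feature was detected (count > 0 in at
#' least one of that week's samples), absent (samples exist, all zero), or
#' unobserved (no sample that week). Derives the first detection week and
#' the longest run of consecutive *observed* undetected weeks after first
#' detection — unobserved weeks never extend a gap.
#'
#' @param table Wide count tibble (post feature filter; detection is
#'   count > 0, the per-sample read minimum is not re-applied).
#' @param meta Metadata tibble for the same subject.
#' @param feature Taxon label.
#' @param weeks Week grid (default 1:52).
#' @return A list with `feature`, `status` (character vector per week),
#'   `first_detection_week`, `longest_gap`, `post_gap_detected`,
#'   `n_weeks_detected`, `n_weeks_observed`.
#' @export
detection_trajectory <- function(table, meta, feature, weeks = 1:52) {
  if (!feature %in% table[[.taxon_col]]) {
    abort(sprintf("unknown feature: %s", feature))
  }
  status <- weekly_detection(table, meta, weeks)[feature, ]
  trajectory_stats(status, weeks, feature)
}

# Shared derivation from a per-week status vector.
trajectory_stats <- function(status, weeks = seq_along(status),
                             feature = NA_character_) {
  det <- status == "detected"
  obs <- status != "unobserved"
  first <- if (any(det)) weeks[which(det)[1]] else NA_integer_
  longest_gap <- 0L
  if (!is.na(first)) {
    runs <- rle(det[weeks > first & obs])
    gaps <- runs$lengths[!runs$values]
    if (length(gaps) > 0) longest_gap <- max(gaps)
  }
  list(feature = feature, status = status, weeks = weeks,
       first_detection_week = first,
       longest_gap = as.integer(longest_gap),
       longest_closed_gap = longest_closed_gap(det, obs, weeks, first),
       post_gap_detected = gap_then_redetect(det, obs, weeks, first),
       n_weeks_detected = sum(det),
       n_weeks_observed = sum(obs))
}

# longest run of observed-undetected weeks after first detection that is
# followed by a later detection (a "closed" gap)
longest_closed_gap <- function(det, obs, weeks, first) {
  if (is.na(first)) return(0L)
  idx <- which(weeks > first & obs)
  best <- 0L; run <- 0L
  for (k in idx) {
    if (det[k]) {
      best <- max(best, run)
      run <- 0L
    } else {
      run <- run + 1L
    }
  }
  as.integer(best)
}

gap_then_redetect <- function(det, obs, weeks, first) {
  longest_closed_gap(det, obs, weeks, first) > 0
}

#' Classify a colonizer archetype from its detection trajectory
#'
#' Rule-based formalization of the colonization patterns seen in dense
#' infant time series. In precedence order:
#' \describe{
#'   \item{re_appearing}{detected inside the early window, then an observed
#'     gap of at least `gap_min` weeks, then detected again — the transient
#'     early pulse that vanishes and re-emerges around dietary
#'     diversification.}
#'   \item{early_life}{detected inside the early window and in at least
#'     `persistence_min` of the observed weeks thereafter — established
#'     quickly and persistent throughout the year.}
#'   \item{later}{first detected at or after `later_min_week`.}
#'   \item{unclassified}{anything else (including never-detected).}
#' }
#' The re-appearing rule is checked first because a feature with a long
#' closed gap cannot be called "persistent throughout", even if its
#' post-re-emergence stretch pushes overall persistence past the bar; this
#' keeps the labels mutually exclusive.
#'
#' @param traj A trajectory from [detection_trajectory()].
#' @param early_window Weeks counting as "immediately after birth"
#'   (default 1:2).
#' @param persistence_min Minimum detected fraction of observed weeks after
#'   the early window for the early_life label (default 0.60).
#' @param gap_min Minimum closed gap (observed undetected weeks) for the
#'   re_appearing label (default 8).
#' @param later_min_week Earliest first-detection week for the later label
#'   (default 9).
#' @return A tibble `(feature, label, first_detection_week, longest_gap,
#'   persistence, reason)`.
#' @export
classify_colonizer <- function(traj, early_window = 1:2,
                               persistence_min = 0.60,
                               gap_min = 8L, later_min_week = 9L) {
  det <- traj$status == "detected"
  obs <- traj$status != "unobserved"
  weeks <- traj$weeks
  first <- traj$first_detection_week
  early_idx <- which(weeks %in% early_window)
  early_detected <- any(det[early_idx])
  after_idx <- which(weeks > max(early_window) & obs)
  persistence <- if (length(after_idx) > 0) mean(det[after_idx]) else NA_real_
  closed_gap <- longest_closed_gap(det, obs, weeks,
                                   if (is.na(first)) NA else first)
  label <- "unclassified"
  reason <- "no rule matched"
  if (is.na(first)) {
    reason <- "never detected"
  } else if (early_detected && closed_gap >= gap_min) {
    label <- "re_appearing"
    reason <- sprintf("early detection, closed gap of %d weeks, re-detected",
                      closed_gap)
  } else if (early_detected && !is.na(persistence) &&
             persistence >= persistence_min) {
    label <- "early_life"
    reason <- sprintf("early detection, persistent (%.0f%% of observed weeks)",
                      100 * persistence)
  } else if (first >= later_min_week) {
    label <- "later"
    reason <- sprintf("first detected week %d", first)
  }
  tibble(feature = traj$feature, label = label,
         first_detection_week = first, longest_gap = closed_gap,
         persistence = persistence, reason = reason)
}

#' Classify every feature of a subject's table
#'
#' @inheritParams detection_trajectory
#' @param ... Threshold arguments passed to [classify_colonizer()].
#' @return A tibble with one row per feature.
#' @export
classify_colonizers <- function(table, meta, weeks = 1:52, ...) {
  status <- weekly_detection(table, meta, weeks)
  purrr::map_dfr(rownames(status), function(f) {
    classify_colonizer(trajectory_stats(status[f, ], weeks, f), ...)
  })
}

#' Ward clustering of genus trajectories
#'
#' Agglomerative clustering of the features of one subject's CLR matrix
#' (features as points, samples in time order as coordinates) with Ward's
#' linkage (`ward.D2`) on Euclidean distances. The merge order and leaf
#' order are made reproducible by ordering features alphabetically before
#' clustering, which fixes `hclust`'s tie-breaking.
#'
#' @param clr Samples-by-features CLR tibble for one subject.
#' @return An object of class `hclust`; export with [cluster_newick()].
#' @export
cluster_genera <- function(clr) {
  m <- comp_matrix(clr)
  if (ncol(m) < 2) abort("need >= 2 features to cluster")
  traj <- t(m)                       # features x samples
  traj <- traj[order(rownames(traj)), , drop = FALSE]
  stats::hclust(stats::dist(traj, method = "euclidean"), method = "ward.D2")
}

#' Export a dendrogram as Newick
#'
#' @param hc An `hclust` object ([cluster_genera()]).
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
cluster_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Mother-infant genus overlap
#'
#' Which of the genera in an infant's first three stool samples also occur
#' in the maternal samples around delivery. Presence thresholds: a feature
#' is present in a maternal sample at count >= 3; it is present in the
#' infant's initial microbiome if it has count >= 3 in at least one of the
#' three samples, or count >= 1 consistently across all three.
#'
#' @param maternal_tables Named list of wide count tibbles, one per
#'   maternal matrix type (e.g. `list(stool = ..., oral = ..., vaginal =
#'   ...)`), each with >= 1 sample.
#' @param infant_first3 Wide count tibble holding exactly the infant's
#'   first three samples.
#' @return A list with `infant_features`, per-source feature sets
#'   (`maternal`), a tibble `summary` of set sizes (shared and unique per
#'   source, UpSet-style), and `shared_any`.
#' @export
maternal_overlap <- function(maternal_tables, infant_first3) {
  m_inf <- count_matrix(infant_first3)
  if (ncol(m_inf) != 3) {
    abort("the overlap rule is defined for exactly the first three infant samples")
  }
  if (length(maternal_tables) < 1) abort("need >= 1 maternal table")
  infant_set <- rownames(m_inf)[rowSums(m_inf >= 3) >= 1 | rowSums(m_inf >= 1) == 3]
  maternal_sets <- purrr::map(maternal_tables, function(tb) {
    mm <- count_matrix(tb)
    rownames(mm)[rowSums(mm >= 3) >= 1]
  })
  shared_any <- infant_set[infant_set %in% unique(unlist(maternal_sets))]
  summary <- purrr::imap_dfr(maternal_sets, function(set, src) {
    tibble(source = src,
           n_source = length(set),
           n_shared_with_infant = length(intersect(set, infant_set)),
           n_source_only = length(setdiff(set, infant_set)))
  }) |>
    bind_rows(tibble(source = "infant",
                     n_source = length(infant_set),
                     n_shared_with_infant = length(shared_any),
                     n_source_only = length(infant_set) - length(shared_any)))
  list(infant_features = infant_set,
       maternal = maternal_sets,
       shared_any = shared_any,
       summary = summary)
}
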