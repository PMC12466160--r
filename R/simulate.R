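#' Simulator configuration
#'
#' Defines the synthetic infant-gut regime the pipeline is exercised on: a
#' 55-genus table over the first year of life with four planted colonizer
#' archetypes, event-driven effects and Dirichlet-multinomial sequencing
#' noise.
#'
#' Sampling regimes: `"daily"` emulates a quasi-daily diary — every day
#' through `dense_until` (default day 126, the intensively sampled early
#' months) then days kept independently with probability `p_sample_late`
#' (default 0.52), yielding about 250 samples over the year plus the
#' day-0 meconium; `"weekly"` picks one random day per week and drops
#' whole weeks with probability `p_miss_week`; a custom integer day vector
#' is used verbatim.
#'
#' Archetypes (counts must sum to `n_features`):
#' \describe{
#'   \item{early_life}{sigmoid onset inside week 1, persistent all year;
#'     includes one dominant genus whose share declines in planted steps —
#'     the staircase that carries the rising-then-plateauing diversity
#'     regime (`dominant_steps`).}
#'   \item{re_appearing}{a faint pulse on days 1-14 near the detection
#'     limit, silence, then sigmoid re-onset after the solid-food event.}
#'   \item{later}{first onset at a per-feature day after solid food;
#'     `n_vaccination_onset` of them instead switch on at the vaccination
#'     day.}
#'   \item{transient_maternal}{a week-1 pulse only.}
#' }
#'
#' @param n_features Number of genera (default 55).
#' @param n_days Days in the study; samples live on days 0..`n_days - 1`
#'   (day 0 is the meconium).
#' @param sampling `"daily"`, `"weekly"`, or an integer vector of days.
#' @param archetypes Named integer vector with entries `early_life`,
#'   `re_appearing`, `later`, `transient_maternal`.
#' @param dense_until,p_sample_late,p_miss_week Sampling-regime knobs (see
#'   above).
#' @param depth_median,depth_sdlog Log-normal read depth (median 20000,
#'   sdlog 0.3).
#' @param concentration Dirichlet concentration scale; smaller values give
#'   stronger overdispersion (default 200).
#' @param noise_sd_early,noise_sd_late Day-to-day log-intensity noise sd at
#'   the start and end of the year (linearly interpolated); the decline
#'   emulates the settling of intra-week variability.
#' @param dominant_steps Tibble-like list `(day, level)` giving the
#'   dominant genus' intensity staircase; its change days are the planted
#'   diversity-regime breakpoints.
#' @param solid_food_day,probiotic_days,vaccination_day Event timing
#'   defaults: solid food at 5 months (day 133), probiotic exposure days
#'   12-60, first vaccination dose day 112 (week 16).
#' @param probiotic_effect,n_probiotic_targets Multiplicative probiotic
#'   effect (default 4-fold) on `n_probiotic_targets` genera (default 5)
#'   during the exposure, decaying exponentially (10-day scale) after.
#' @param n_vaccination_onset Later-colonizer genera whose onset is pinned
#'   to the vaccination day (default 2).
#' @param subject_sd Between-subject sd of per-feature log-intensity
#'   offsets used by [simulate_cohort()].
#' @param rng_seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_features = 55,
                       n_days = 365,
                       sampling = "daily",
                       archetypes = c(early_life = 20, re_appearing = 10,
                                      later = 18, transient_maternal = 7),
                       dense_until = 126,
                       p_sample_late = 0.52,
                       p_miss_week = 0.10,
                       depth_median = 20000,
                       depth_sdlog = 0.3,
                       concentration = 200,
                       noise_sd_early = 0.7,
                       noise_sd_late = 0.25,
                       dominant_steps = list(day = c(1, 14, 112, 133, 210),
                                             level = c(200, 80, 42, 20, 10)),
                       solid_food_day = 133,
                       probiotic_days = c(12, 60),
                       vaccination_day = 112,
                       probiotic_effect = 4,
                       n_probiotic_targets = 5,
                       n_vaccination_onset = 2,
                       subject_sd = 0.8,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  if (sum(archetypes) != n_features) {
    abort("archetype counts must sum to n_features")
  }
  need <- c("early_life", "re_appearing", "later", "transient_maternal")
  if (!all(need %in% names(archetypes))) {
    abort(sprintf("archetypes must name: %s", paste(need, collapse = ", ")))
  }
  if (any(c(solid_food_day, probiotic_days, vaccination_day) < 0) ||
      any(c(solid_food_day, probiotic_days, vaccination_day) >= n_days)) {
    abort("event days must fall inside [0, n_days)")
  }
  if (depth_median <= 0 || concentration <= 0 || noise_sd_early < 0 ||
      noise_sd_late < 0 || subject_sd < 0) {
    abort("scale parameters must be positive")
  }
  structure(cfg, class = "sim_config")
}

sigmoid <- function(d, center, scale) 1 / (1 + exp(-(d - center) / scale))

# Per-feature latent blueprint: baseline intensity, archetype profile
# parameters, event tags. Drawn once per subject (seeded by caller).
sim_blueprint <- function(config) {
  a <- config$archetypes
  labels <- rep(names(a), a)
  feat <- sprintf("genus_%02d", seq_len(config$n_features))
  base <- numeric(config$n_features)
  onset <- rep(NA_real_, config$n_features)
  pulse_level <- rep(0, config$n_features)
  el <- which(labels == "early_life")
  base[el] <- exp(stats::rnorm(length(el), log(2.2), 0.8))
  onset[el] <- stats::runif(length(el), 2, 6)
  dominant <- el[1]                      # the staircase genus
  ra <- which(labels == "re_appearing")
  base[ra] <- exp(stats::rnorm(length(ra), log(0.9), 0.5))
  onset[ra] <- config$solid_food_day + stats::runif(length(ra), 5, 50)
  pulse_level[ra] <- 0.05                # near the detection limit
  lt <- which(labels == "later")
  base[lt] <- exp(stats::rnorm(length(lt), log(0.22), 0.9))
  onset[lt] <- config$solid_food_day + stats::runif(length(lt), 0, 75)
  vac_onset <- integer(0)
  if (config$n_vaccination_onset > 0) {
    vac_onset <- lt[seq_len(min(config$n_vaccination_onset, length(lt)))]
    onset[vac_onset] <- config$vaccination_day
    base[vac_onset] <- pmax(base[vac_onset], 1.2)  # clearly detectable onset
  }
  tm <- which(labels == "transient_maternal")
  base[tm] <- exp(stats::rnorm(length(tm), log(1.2), 0.4))
  pro_targets <- el[-1][seq_len(min(config$n_probiotic_targets,
                                    length(el) - 1))]
  list(feature = feat, label = labels, base = base, onset = onset,
       pulse_level = pulse_level, dominant = dominant,
       vaccination_onset = vac_onset, probiotic_targets = pro_targets)
}

# deterministic archetype intensity profile for one feature over days 1..D
profile_matrix <- function(bp, config, days) {
  K <- config$n_features
  prof <- matrix(0, nrow = K, ncol = length(days))
  steps <- config$dominant_steps
  for (f in seq_len(K)) {
    lab <- bp$label[f]
    if (f == bp$dominant) {
      lev <- steps$level[findInterval(days, steps$day)]
      lev[days < steps$day[1]] <- steps$level[1]
      prof[f, ] <- lev / bp$base[f]      # base cancels: staircase is absolute
    } else if (lab == "early_life") {
      prof[f, ] <- sigmoid(days, bp$onset[f], 1.5)
    } else if (lab == "re_appearing") {
      prof[f, ] <- bp$pulse_level[f] / bp$base[f] * (days >= 1 & days <= 14) +
        sigmoid(days, bp$onset[f], 3)
    } else if (lab == "later") {
      if (f %in% bp$vaccination_onset) {
        # event-pinned onset: zero before the event day, full level from it
        prof[f, ] <- as.numeric(days >= bp$onset[f])
      } else {
        prof[f, ] <- sigmoid(days, bp$onset[f], 3) *
          (days >= bp$onset[f] - 6)         # hard zero before the approach
      }
    } else {                              # transient_maternal
      prof[f, ] <- as.numeric(days >= 0 & days <= 9)
    }
  }
  prof
}

# multiplicative event modifiers per feature per day
event_matrix <- function(bp, config, days) {
  K <- config$n_features
  mult <- matrix(1, nrow = K, ncol = length(days))
  p0 <- config$probiotic_days[1]
  p1 <- config$probiotic_days[2]
  eff <- config$probiotic_effect
  during <- days >= p0 & days <= p1
  after <- days > p1
  decay <- exp(-(days - p1) / 10)
  for (f in bp$probiotic_targets) {
    mult[f, during] <- eff
    mult[f, after] <- 1 + (eff - 1) * decay[after]
  }
  mult
}

sampled_days <- function(config) {
  last <- config$n_days - 1
  if (is.numeric(config$sampling)) {
    return(sort(unique(as.integer(config$sampling))))
  }
  if (config$sampling == "daily") {
    dense <- 1:min(config$dense_until, last)
    sparse <- if (config$dense_until < last) {
      cand <- (config$dense_until + 1):last
      cand[stats::runif(length(cand)) < config$p_sample_late]
    } else integer(0)
    c(dense, sparse)
  } else if (config$sampling == "weekly") {
    weeks <- seq_len(last %/% 7)
    keep <- weeks[stats::runif(length(weeks)) >= config$p_miss_week]
    vapply(keep, function(w) sample.int(7L, 1L) + (w - 1L) * 7L, integer(1))
  } else {
    abort("sampling must be 'daily', 'weekly' or an integer day vector")
  }
}

#' Simulate one infant's gut time series
#'
#' Generates a genus-level count table, sample metadata, an event diary
#' and the planted ground truth for one subject under a [sim_config()].
#' Per sampled day, latent intensities combine the archetype profile, the
#' event modifiers and log-normal day-to-day noise whose sd declines over
#' the year; proportions are the normalized intensities and counts are
#' drawn Dirichlet-multinomial at a log-normal depth. Day 0 is emitted as
#' an all-zero meconium sample. Fully deterministic given
#' `config$rng_seed`.
#'
#' @param config A [sim_config()].
#' @param subject_id Subject label (default `"infantA"`).
#' @param feature_offset Optional per-feature log-intensity offsets
#'   (used by [simulate_cohort()] for between-subject variability).
#' @return A list `(table, meta, events, truth)`: wide count tibble,
#'   metadata tibble, event tibble, and a `truth` list with per-feature
#'   archetype labels and onsets, event targets, the planted breakpoint
#'   days and the seed.
#' @export
simulate_infant <- function(config = sim_config(), subject_id = "infantA",
                            feature_offset = NULL) {
  with_seed(config$rng_seed, {
    bp <- sim_blueprint(config)
    days <- sampled_days(config)
    days <- days[days >= 1 & days <= config$n_days - 1]
    K <- config$n_features
    base <- bp$base
    if (!is.null(feature_offset)) base <- base * exp(feature_offset)
    prof <- profile_matrix(bp, config, days)
    emult <- event_matrix(bp, config, days)
    frac <- days / config$n_days
    noise_sd <- config$noise_sd_early +
      (config$noise_sd_late - config$noise_sd_early) * frac
    noise <- matrix(stats::rnorm(K * length(days)), nrow = K) *
      rep(noise_sd, each = K)
    lambda <- base * prof * emult * exp(noise)
    depths <- round(stats::rlnorm(length(days), log(config$depth_median),
                                  config$depth_sdlog))
    counts <- matrix(0L, nrow = K, ncol = length(days))
    for (j in seq_along(days)) {
      alpha <- config$concentration * lambda[, j] / sum(lambda[, j])
      w <- stats::rgamma(K, shape = alpha)
      if (sum(w) == 0) w[which.max(alpha)] <- 1
      counts[, j] <- as.integer(stats::rmultinom(1, depths[j], w / sum(w)))
    }
    ids <- sprintf("%s_d%03d", subject_id, c(0L, days))
    table <- matrix_to_count_tbl(
      cbind(matrix(0L, nrow = K, ncol = 1), counts) |>
        `dimnames<-`(list(bp$feature, ids)))
    meta <- tibble(
      sample_id = ids,
      subject_id = subject_id,
      day_of_life = as.integer(c(0L, days)),
      matrix_type = c("meconium", rep("stool", length(days)))
    ) |> validate_metadata()
    events <- tibble(
      subject_id = subject_id,
      event_type = c("probiotic", "vaccination", "solid_food"),
      start_day = as.integer(c(config$probiotic_days[1],
                               config$vaccination_day,
                               config$solid_food_day)),
      end_day = as.integer(c(config$probiotic_days[2],
                             config$vaccination_day,
                             config$solid_food_day)),
      label = c("probiotic exposure", "first vaccine dose",
                "solid food introduction"))
    truth <- list(
      features = tibble(
        feature = bp$feature,
        archetype = bp$label,
        expected_label = dplyr::recode(bp$label,
                                       transient_maternal = "unclassified"),
        base_intensity = base,
        onset_day = bp$onset),
      dominant_feature = bp$feature[bp$dominant],
      probiotic_targets = bp$feature[bp$probiotic_targets],
      probiotic_effect = config$probiotic_effect,
      vaccination_onset = bp$feature[bp$vaccination_onset],
      planted_breakpoints = config$dominant_steps$day[-1],
      seed = config$rng_seed)
    list(table = table, meta = meta, events = events, truth = truth)
  })
}

#' Simulate a weekly-sampled cohort
#'
#' Independent subjects sharing one archetype pool (feature identities and
#' labels) but with subject-specific onsets, noise and per-feature
#' log-intensity offsets (`subject_sd`), sampled weekly with missed weeks.
#'
#' @param n_subjects Number of subjects (default 11).
#' @param config Base [sim_config()]; sampling is forced to `"weekly"`.
#' @param seed Master seed; per-subject seeds are derived as
#'   `seed + 1000 * subject index`.
#' @return A list with `subjects` (named list of [simulate_infant()]
#'   results), a bound `meta` tibble, and `config`.
#' @export
simulate_cohort <- function(n_subjects = 11, config = sim_config(),
                            seed = 1L) {
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  config$sampling <- "weekly"
  subjects <- purrr::map(seq_len(n_subjects), function(s) {
    cfg <- config
    cfg$rng_seed <- as.integer(seed + 1000L * s)
    offset <- with_seed(cfg$rng_seed + 1L,
                        stats::rnorm(config$n_features, 0, config$subject_sd))
    simulate_infant(cfg, subject_id = sprintf("infant%02d", s),
                    feature_offset = offset)
  })
  names(subjects) <- vapply(subjects, function(x) x$meta$subject_id[1], "")
  list(subjects = subjects,
       meta = bind_rows(purrr::map(subjects, "meta")),
       config = config)
}

#' Score inference against the planted truth
#'
#' @param truth The `truth` element of [simulate_infant()].
#' @param labels Optional classifier output ([classify_colonizers()]):
#'   recovery rates are computed per archetype against the expected
#'   labels (`transient_maternal` is expected `unclassified`). Features
#'   absent from `labels` (e.g. filtered out) are ignored.
#' @param event_outcomes Optional `event_test_tbl` for the probiotic
#'   design: sensitivity = planted-and-significant / planted at the
#'   table's threshold, plus the false-positive rate among non-planted
#'   features.
#' @param breakpoint_days Optional detected breakpoint days ([cbs_segment()]
#'   segments' start days): distance from each planted breakpoint to the
#'   nearest detected one.
#' @return A list with `label_recovery` (tibble per archetype + overall),
#'   `event` (one-row tibble) and `breakpoints` (tibble), elements `NULL`
#'   where the input was not supplied.
#' @export
truth_report <- function(truth, labels = NULL, event_outcomes = NULL,
                         breakpoint_days = NULL) {
  out <- list(label_recovery = NULL, event = NULL, breakpoints = NULL)
  if (!is.null(labels)) {
    joined <- truth$features |>
      inner_join(labels |> select("feature", "label"), by = "feature")
    if (nrow(joined) == 0) abort("no features shared between truth and labels")
    per <- joined |>
      group_by(.data$archetype) |>
      summarise(n = dplyr::n(),
                recovered = sum(.data$label == .data$expected_label),
                rate = .data$recovered / .data$n, .groups = "drop")
    overall <- tibble(archetype = "overall", n = nrow(joined),
                      recovered = sum(joined$label == joined$expected_label),
                      rate = sum(joined$label == joined$expected_label) /
                        nrow(joined))
    out$label_recovery <- bind_rows(per, overall)
  }
  if (!is.null(event_outcomes)) {
    planted <- truth$probiotic_targets
    hit <- event_outcomes$taxon[event_outcomes$significant]
    out$event <- tibble(
      n_planted = length(planted),
      sensitivity = mean(planted %in% hit),
      false_positive_rate = {
        others <- setdiff(event_outcomes$taxon, planted)
        if (length(others) == 0) 0 else mean(others %in% hit)
      })
  }
  if (!is.null(breakpoint_days)) {
    out$breakpoints <- tibble(
      planted_day = truth$planted_breakpoints,
      nearest_detected = vapply(truth$planted_breakpoints, function(d) {
        if (length(breakpoint_days) == 0) NA_real_
        else breakpoint_days[which.min(abs(breakpoint_days - d))]
      }, numeric(1))
    ) |>
      mutate(distance = abs(.data$nearest_detected - .data$planted_day))
  }
  out
}
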