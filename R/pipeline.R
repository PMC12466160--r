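write_tsv_plain <- function(df, path, digits = 12) {
  out <- as.data.frame(df)
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  for (cn in names(out)[num]) out[[cn]] <- signif(out[[cn]], digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_paths <- function(outdir) {
  list(
    table = file.path(outdir, "counts.tsv"),
    meta = file.path(outdir, "metadata.csv"),
    events = file.path(outdir, "events.csv"),
    truth = file.path(outdir, "truth.json"),
    filtered = file.path(outdir, "counts_filtered.tsv"),
    clr = file.path(outdir, "clr.tsv"),
    diversity = file.path(outdir, "diversity_series.tsv"),
    weekly_cv = file.path(outdir, "weekly_cv.tsv"),
    segments = file.path(outdir, "hmd_segments.tsv"),
    breakpoints = file.path(outdir, "hmd_breakpoints.tsv"),
    events_dir = outdir,
    labels = file.path(outdir, "colonizer_labels.tsv"),
    dendrogram = file.path(outdir, "genus_dendrogram.nwk"),
    runs = file.path(outdir, "subsample_runs.tsv"),
    detection = file.path(outdir, "detection_frequency.tsv"),
    retention = file.path(outdir, "significance_retention.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
}

require_upstream <- function(paths, files, stage, prerequisite) {
  missing <- files[!file.exists(unlist(paths[files]))]
  if (length(missing) > 0) {
    abort(sprintf(
      "stage '%s' needs output(s) %s; run the '%s' stage first",
      stage, paste(missing, collapse = ", "), prerequisite))
  }
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates the stages over an output directory: `simulate` writes the
#' synthetic infant's count table, metadata, event diary and truth;
#' `preprocess` writes the filtered table and CLR matrix; `diversity` the
#' Shannon series and weekly CV profile; `segment` the homogeneous-
#' diversity periods; `events` the per-event test tables; `patterns` the
#' colonizer labels and genus dendrogram; `downsample` the weekly
#' subsample runs, detection frequencies and probiotic significance
#' retention. `all` runs everything in dependency order. Later stages read
#' the files earlier stages wrote, so partial reruns reuse upstream
#' outputs; a missing upstream file raises an error naming the
#' prerequisite stage. Every stage seed derives from `seed`, so a rerun
#' with identical inputs is byte-identical; the run is recorded in a JSON
#' manifest (config snapshot, per-stage seeds, output digests).
#'
#' @param outdir Output directory (created if needed).
#' @param command One of `"simulate"`, `"preprocess"`, `"diversity"`,
#'   `"segment"`, `"events"`, `"patterns"`, `"downsample"`, `"all"`.
#' @param config An [analysis_config()].
#' @param sim A [sim_config()] (its `rng_seed` is overridden by `seed`).
#' @param seed Master seed for every stage.
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(outdir,
                         command = c("all", "simulate", "preprocess",
                                     "diversity", "segment", "events",
                                     "patterns", "downsample"),
                         config = analysis_config(),
                         sim = sim_config(),
                         seed = 1L) {
  command <- match.arg(command)
  # force full validation of both configurations before any stage runs
  if (!inherits(config, "gut_config")) abort("config must be an analysis_config()")
  if (!inherits(sim, "sim_config")) abort("sim must be a sim_config()")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- stage_paths(outdir)
  seeds <- list(simulate = seed, segment = seed + 1L, downsample = seed + 2L)
  stages <- if (command == "all") {
    c("simulate", "preprocess", "diversity", "segment", "events",
      "patterns", "downsample")
  } else command

  if ("simulate" %in% stages) {
    sim$rng_seed <- as.integer(seeds$simulate)
    dat <- simulate_infant(sim)
    write_count_table(dat$table, paths$table)
    utils::write.csv(
      dat$meta |> select("sample_id", "subject_id", "day_of_life",
                         "matrix_type"),
      paths$meta, row.names = FALSE, quote = FALSE)
    utils::write.csv(dat$events, paths$events, row.names = FALSE, quote = TRUE)
    jsonlite::write_json(
      list(features = dat$truth$features,
           dominant_feature = dat$truth$dominant_feature,
           probiotic_targets = dat$truth$probiotic_targets,
           probiotic_effect = dat$truth$probiotic_effect,
           vaccination_onset = dat$truth$vaccination_onset,
           planted_breakpoints = dat$truth$planted_breakpoints,
           seed = dat$truth$seed),
      paths$truth, auto_unbox = TRUE, digits = NA)
  }

  if ("preprocess" %in% stages) {
    require_upstream(paths, c("table"), "preprocess", "simulate")
    table <- read_count_table(paths$table)
    filtered <- table |>
      drop_empty_samples() |>
      filter_features(config$filter_min_prevalence, config$filter_min_reads)
    write_count_table(filtered, paths$filtered)
    clr <- czm_replace(filtered, config$czm_fraction) |> clr_transform()
    write_tsv_plain(clr, paths$clr)
  }

  if ("diversity" %in% stages) {
    require_upstream(paths, c("table", "meta"), "diversity", "simulate")
    table <- read_count_table(paths$table)
    meta <- read_metadata(paths$meta)
    ser <- diversity_series(table, meta)
    write_tsv_plain(ser, paths$diversity)
    cv <- weekly_cv(ser, table, meta) |> select(-"feature_cv")
    write_tsv_plain(cv, paths$weekly_cv)
  }

  if ("segment" %in% stages) {
    require_upstream(paths, c("diversity", "meta"), "segment", "diversity")
    ser <- utils::read.delim(paths$diversity) |> as_tibble()
    meta <- read_metadata(paths$meta)
    fit <- cbs_segment(ser, alpha = config$cbs_alpha,
                       min_width = config$cbs_min_width,
                       n_permutations = config$cbs_n_permutations,
                       seed = seeds$segment) |>
      assign_periods(meta)
    write_tsv_plain(tidy(fit), paths$segments)
    write_tsv_plain(tibble(breakpoint_index = fit$breakpoints,
                           breakpoint_day = ser$day_of_life[fit$breakpoints]),
                    paths$breakpoints)
  }

  if ("events" %in% stages) {
    require_upstream(paths, c("clr", "meta", "events"), "events", "preprocess")
    clr <- utils::read.delim(paths$clr, check.names = FALSE) |> as_tibble()
    meta <- read_metadata(paths$meta)
    events <- read_events(paths$events)
    kinds <- c(probiotic = "probiotic", solid_food = "diet",
               vaccination = "point")
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (!ev$event_type %in% names(kinds)) next
      design <- build_event_windows(ev, kinds[[ev$event_type]])
      res <- run_event_tests(clr, meta, design,
                             fdr_threshold = config$fdr_threshold)
      write_tsv_plain(tidy(res),
                      file.path(outdir, sprintf("event_%s.tsv", ev$event_type)))
    }
  }

  if ("patterns" %in% stages) {
    require_upstream(paths, c("filtered", "clr", "meta"), "patterns",
                     "preprocess")
    filtered <- read_count_table(paths$filtered)
    meta <- read_metadata(paths$meta)
    labels <- classify_colonizers(filtered, meta)
    write_tsv_plain(labels, paths$labels)
    clr <- utils::read.delim(paths$clr, check.names = FALSE) |> as_tibble()
    cluster_newick(cluster_genera(clr), paths$dendrogram)
  }

  if ("downsample" %in% stages) {
    require_upstream(paths, c("filtered", "clr", "meta", "events"),
                     "downsample", "preprocess")
    filtered <- read_count_table(paths$filtered)
    meta <- read_metadata(paths$meta)
    events <- read_events(paths$events)
    clr <- utils::read.delim(paths$clr, check.names = FALSE) |> as_tibble()
    stool <- meta |> filter(.data$matrix_type == "stool")
    runs <- weekly_subsample(stool, n_runs = config$downsample_n_runs,
                             seed = seeds$downsample)
    write_tsv_plain(as_tibble(runs), paths$runs)
    freq <- detection_frequency(filtered, meta, runs)
    write_tsv_plain(freq, paths$detection)
    per_run <- downsampled_event_tests(clr, meta, runs, events,
                                       fdr_threshold = config$fdr_threshold)
    pro_ev <- events |> filter(.data$event_type == "probiotic")
    if (nrow(pro_ev) > 0) {
      ref <- run_event_tests(clr, meta,
                             build_event_windows(pro_ev[1, ], "probiotic"),
                             fdr_threshold = config$fdr_threshold)
      ret <- significance_retention(
        ref, per_run |> filter(.data$event_type == "probiotic"))
      write_tsv_plain(ret$retention, paths$retention)
    }
  }

  outputs <- list.files(outdir, pattern = "\\.(tsv|csv|json|nwk)$",
                        full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("gutcadence")),
    command = command,
    seed = seed,
    stage_seeds = seeds,
    config = unclass(config),
    sim_config = unclass(sim)[setdiff(names(unclass(sim)), "cfg")],
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Drop zero-total samples from a count table
#'
#' @param table A wide count tibble.
#' @return The table without zero-total sample columns.
#' @export
drop_empty_samples <- function(table) {
  m <- count_matrix(table)
  empty <- colnames(m)[colSums(m) == 0]
  table[, !(names(table) %in% empty), drop = FALSE]
}
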