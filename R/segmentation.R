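# Run code with a private RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Enumerate circular arcs (i, j] of a length-n series with both the arc and
# its complement holding >= min_width markers. Ordered lexicographically in
# (i, j) so which.max() realises the earliest-arc tie-break.
cbs_arcs <- function(n, min_width = 1) {
  pairs <- purrr::map(0:(n - 1), function(i) {
    j_lo <- i + min_width
    j_hi <- min(n, i + n - min_width)   # n_out = n - (j - i) >= min_width
    if (j_lo > j_hi) return(NULL)
    cbind(i = i, j = j_lo:j_hi)
  })
  pairs <- do.call(rbind, pairs)
  n_in <- pairs[, "j"] - pairs[, "i"]
  list(i = pairs[, "i"], j = pairs[, "j"], n_in = n_in, n_out = n - n_in)
}

# max |Z| over a precomputed arc set; sdev and total are permutation-invariant
cbs_scan <- function(x, arcs, sdev) {
  s0 <- c(0, cumsum(x))
  total <- s0[length(s0)]
  sum_in <- s0[arcs$j + 1] - s0[arcs$i + 1]
  z <- (sum_in / arcs$n_in - (total - sum_in) / arcs$n_out) /
    (sdev * sqrt(1 / arcs$n_in + 1 / arcs$n_out))
  az <- abs(z)
  k <- which.max(az)
  list(statistic = az[k], i = arcs$i[k], j = arcs$j[k])
}

#' Maximal circular mean-shift statistic
#'
#' Scans every circular arc (i, j] of an ordered series and returns the
#' maximum of the standardized mean-difference statistic
#' `Z_ij = (mean_in - mean_out) / (sd * sqrt(1/n_in + 1/n_out))`, where `sd`
#' is the overall sample standard deviation. Ties are broken by the
#' earliest (i, j) in lexicographic order; a constant series has statistic
#' 0. This is the test statistic of the circular-binary-segmentation split.
#'
#' @param series Ordered numeric series, length >= 2.
#' @param min_width Minimum markers required in the arc and its complement.
#' @return A list `(statistic, i, j)`; arc indices are `NA` for a constant
#'   series.
#' @export
cbs_max_statistic <- function(series, min_width = 1) {
  n <- length(series)
  if (n < 2 * min_width || n < 2) {
    abort("series must hold at least 2 * min_width points")
  }
  sdev <- stats::sd(series)
  if (sdev == 0) return(list(statistic = 0, i = NA_integer_, j = NA_integer_))
  cbs_scan(series, cbs_arcs(n, min_width), sdev)
}

# Permutation p-value for the max-|Z| statistic on one (sub)series.
cbs_perm_p <- function(x, arcs, n_permutations) {
  sdev <- stats::sd(x)
  if (sdev == 0) {
    return(list(p = 1, statistic = 0, i = NA_integer_, j = NA_integer_))
  }
  obs <- cbs_scan(x, arcs, sdev)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    xp <- x[sample.int(length(x))]
    if (cbs_scan(xp, arcs, sdev)$statistic >= obs$statistic - 1e-12) {
      hits <- hits + 1L
    }
  }
  c(obs, list(p = (1 + hits) / (n_permutations + 1)))
}

# Recursive splitter on x[lo..hi] (global indices); returns breakpoint
# positions b meaning "a new segment starts after global index b".
cbs_recurse <- function(x, lo, hi, alpha, min_width, n_permutations) {
  len <- hi - lo + 1
  if (len < 2 * min_width) return(integer())
  arcs <- cbs_arcs(len, min_width)
  res <- cbs_perm_p(x[lo:hi], arcs, n_permutations)
  if (is.na(res$i) || res$p > alpha) return(integer())
  i <- res$i; j <- res$j
  cand <- integer()
  if (i > 0) cand <- c(cand, i)
  if (j < len) cand <- c(cand, j)
  if (length(cand) == 0) return(integer())
  admissible <- function(bps) {
    sizes <- diff(c(0, sort(bps), len))
    all(sizes >= min_width)
  }
  keep <- if (admissible(cand)) {
    cand
  } else {
    # collapse the ternary split to a single admissible boundary; prefer the
    # one with the larger standalone binary-split statistic, earlier on ties
    ok <- cand[vapply(cand, function(b) admissible(b), logical(1))]
    if (length(ok) == 0) return(integer())
    if (length(ok) == 1) ok else {
      xs <- x[lo:hi]
      sdev <- stats::sd(xs)
      zb <- vapply(ok, function(b) {
        abs(mean(xs[1:b]) - mean(xs[(b + 1):len])) /
          (sdev * sqrt(1 / b + 1 / (len - b)))
      }, numeric(1))
      ok[which.max(zb)]
    }
  }
  keep <- sort(keep)
  bounds <- c(0, keep, len)
  out <- lo - 1 + keep
  for (s in seq_len(length(bounds) - 1)) {
    out <- c(out, cbs_recurse(x, lo + bounds[s], lo - 1 + bounds[s + 1],
                              alpha, min_width, n_permutations))
  }
  sort(out)
}

#' Circular binary segmentation of a diversity series
#'
#' Recursively splits a time-ordered series (typically the Shannon series)
#' into mean-homogeneous segments — the homogeneous microbial diversity
#' (HMD) periods. At each step the maximal circular arc statistic
#' ([cbs_max_statistic()]) is referred to a permutation null,
#' `p = (1 + #\{permuted max >= observed\}) / (n_permutations + 1)`; the
#' split is accepted when `p <= alpha` and recursion continues inside each
#' resulting segment. An interior arc yields two changepoints, an
#' edge-touching arc one; a candidate is kept only when every resulting
#' segment holds at least `min_width` markers. Deterministic given `seed`.
#'
#' @param series A diversity series tibble ([diversity_series()]) or a bare
#'   numeric vector in time order.
#' @param alpha Significance level for accepting a changepoint (default
#'   0.01).
#' @param min_width Minimum markers per changed segment (default 2).
#' @param n_permutations Permutations per split test (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param value Column holding the segmented values when `series` is a
#'   tibble.
#' @return An object of class `cbs_fit` with `breakpoints` (positions after
#'   which a new period starts), a `segments` tibble (period_id, start/end
#'   index and day, n_markers, mean level) and the inputs; see
#'   [tidy.cbs_fit()], [glance.cbs_fit()], [autoplot.cbs_fit()].
#' @export
cbs_segment <- function(series, alpha = 0.01, min_width = 2,
                        n_permutations = 1000, seed = 1L,
                        value = "shannon") {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie strictly in (0, 1)")
  if (min_width < 1) abort("min_width must be >= 1")
  info <- NULL
  if (is.data.frame(series)) {
    if (!value %in% names(series)) {
      abort(sprintf("column '%s' not found in series", value))
    }
    info <- series
    x <- series[[value]]
  } else {
    x <- as.numeric(series)
  }
  n <- length(x)
  if (n < 2 * min_width) abort("series shorter than 2 * min_width")
  bps <- with_seed(seed,
    cbs_recurse(x, 1L, n, alpha, min_width, as.integer(n_permutations)))
  bounds <- c(0L, bps, n)
  segments <- purrr::map_dfr(seq_len(length(bounds) - 1), function(s) {
    idx <- (bounds[s] + 1):bounds[s + 1]
    tibble(
      period_id = s,
      start_index = min(idx),
      end_index = max(idx),
      n_markers = length(idx),
      mean_level = mean(x[idx]),
      start_day = if (!is.null(info)) info$day_of_life[min(idx)] else NA_integer_,
      end_day = if (!is.null(info)) info$day_of_life[max(idx)] else NA_integer_
    )
  })
  structure(
    list(x = x, breakpoints = bps, segments = segments,
         sample_info = info, period0_sample = NULL,
         alpha = alpha, min_width = as.integer(min_width),
         n_permutations = as.integer(n_permutations), seed = seed),
    class = "cbs_fit")
}

#' Apply the meconium period-0 rule
#'
#' If the first sample of the segmented series is a meconium sample, it is
#' set apart as period 0 — emphasising its distinct stool type — and the
#' remaining periods are renumbered from 1. A meconium sample anywhere else
#' in the series leaves the result unchanged with a warning.
#'
#' @param fit A `cbs_fit` whose series carried sample metadata.
#' @param meta Optional metadata tibble; defaults to the sample info stored
#'   in the fit.
#' @return The updated `cbs_fit`, with `period0_sample` set when the rule
#'   fired.
#' @export
assign_periods <- function(fit, meta = NULL) {
  stopifnot(inherits(fit, "cbs_fit"))
  info <- fit$sample_info
  if (!is.null(meta) && !is.null(info)) {
    info <- info |>
      select(-dplyr::any_of("matrix_type")) |>
      left_join(meta |> select("sample_id", "matrix_type"), by = "sample_id")
  }
  if (is.null(info) || !"matrix_type" %in% names(info)) {
    abort("assign_periods needs sample metadata with matrix_type")
  }
  is_mec <- info$matrix_type == "meconium"
  if (!any(is_mec)) return(fit)
  if (!is_mec[1]) {
    warn("meconium sample is not the first sample; period-0 rule not applied")
    return(fit)
  }
  seg <- fit$segments
  first <- seg[1, ]
  if (first$n_markers == 1) {
    seg$period_id <- seq_len(nrow(seg)) - 1L
  } else {
    head0 <- first
    head0$end_index <- 1L
    head0$n_markers <- 1L
    head0$mean_level <- fit$x[1]
    head0$end_day <- if (!is.null(info)) info$day_of_life[1] else NA_integer_
    rest1 <- first
    rest1$start_index <- 2L
    rest1$n_markers <- first$n_markers - 1L
    rest1$mean_level <- mean(fit$x[2:first$end_index])
    rest1$start_day <- if (!is.null(info)) info$day_of_life[2] else NA_integer_
    seg <- bind_rows(head0, rest1, seg[-1, ])
    seg$period_id <- seq_len(nrow(seg)) - 1L
  }
  fit$segments <- seg
  fit$period0_sample <- info$sample_id[1]
  fit
}

#' Per-sample period labels from a segmentation
#'
#' @param fit A `cbs_fit`.
#' @return A tibble `(sample_id, day_of_life, value, period_id)` when the
#'   fit carries sample info, otherwise `(index, value, period_id)`.
#' @export
period_labels <- function(fit) {
  stopifnot(inherits(fit, "cbs_fit"))
  lab <- integer(length(fit$x))
  for (s in seq_len(nrow(fit$segments))) {
    seg <- fit$segments[s, ]
    lab[seg$start_index:seg$end_index] <- seg$period_id
  }
  if (!is.null(fit$sample_info)) {
    tibble(sample_id = fit$sample_info$sample_id,
           day_of_life = fit$sample_info$day_of_life,
           value = fit$x, period_id = lab)
  } else {
    tibble(index = seq_along(fit$x), value = fit$x, period_id = lab)
  }
}

#' @export
print.cbs_fit <- function(x, ...) {
  cat(sprintf(
    "Circular binary segmentation: %d points, %d breakpoint(s), %d period(s)\n",
    length(x$x), length(x$breakpoints), nrow(x$segments)))
  cat(sprintf("alpha = %g, min_width = %d, %d permutations, seed = %s\n",
              x$alpha, x$min_width, x$n_permutations, format(x$seed)))
  print(x$segments)
  invisible(x)
}
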