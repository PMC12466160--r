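suppressMessages({
  library(dplyr)
  library(tibble)
})

# small wide count table builder: counts is a features x samples matrix
make_counts <- function(counts, taxa = NULL, samples = NULL) {
  taxa <- taxa %||% sprintf("g%02d", seq_len(nrow(counts)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(counts)))
  dimnames(counts) <- list(taxa, samples)
  tibble(taxon = taxa) |>
    bind_cols(as_tibble(counts, .name_repair = "minimal"))
}

make_meta <- function(sample_ids, days, subject = "infantA",
                      matrix_type = NULL) {
  matrix_type <- matrix_type %||% rep("stool", length(sample_ids))
  validate_metadata(tibble(sample_id = sample_ids, subject_id = subject,
                           day_of_life = days, matrix_type = matrix_type))
}

`%||%` <- rlang::`%||%`

# -- independent oracles ------------------------------------------------------

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mwu <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# exhaustive-arc circular scan statistic (independent double loop)
oracle_cbs_max <- function(x, min_width = 1) {
  n <- length(x)
  sdev <- sd(x)
  if (sdev == 0) return(list(statistic = 0, i = NA, j = NA))
  best <- -Inf; bi <- NA; bj <- NA
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      n_in <- j - i; n_out <- n - n_in
      if (n_in < min_width || n_out < min_width) next
      m_in <- mean(x[(i + 1):j])
      m_out <- mean(x[setdiff(1:n, (i + 1):j)])
      z <- abs(m_in - m_out) / (sdev * sqrt(1 / n_in + 1 / n_out))
      if (z > best + 1e-12) {
        best <- z; bi <- i; bj <- j
      }
    }
  }
  list(statistic = best, i = bi, j = bj)
}

# PERMANOVA pseudo-F computed independently from group means in CLR space is
# not possible from a bare distance matrix; use the direct SS partition with
# an explicitly different accumulation (upper triangle loops).
oracle_permanova_f <- function(d, labels) {
  n <- nrow(d)
  ss_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ng <- length(idx)
    if (ng < 2) next
    acc <- 0
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) acc <- acc + d[idx[a], idx[b]]^2
    }
    ss_w <- ss_w + acc / ng
  }
  a <- length(unique(labels))
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

trajectory_stats_for_test <- function(status) {
  gutcadence:::trajectory_stats(status, seq_along(status), "f")
}

# a small simulated infant shared across tests (cheap-ish, built once)
default_infant <- local({
  dat <- NULL
  function() {
    if (is.null(dat)) dat <<- suppressMessages(simulate_infant(sim_config()))
    dat
  }
})
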