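# gutcadence

Analysis of dense longitudinal infant gut microbiome time series, built
around one question: **what does sampling cadence do to what you can see?**
A quasi-daily stool diary over the first year of life captures transient
colonizers and short-lived event responses that weekly sampling blurs or
erases. `gutcadence` implements the full downstream pipeline for genus-level
16S count tables — compositional preprocessing, diversity segmentation,
nonparametric event testing, colonizer-pattern classification — plus the
weekly-downsampling experiment that quantifies the information loss, and a
Dirichlet-multinomial simulator so everything runs without external data.

It is aimed at microbiome researchers analysing longitudinal count tables
(features × samples TSV, per-sample metadata CSV, an event diary CSV).

## What it computes

* **Compositional preprocessing.** Genera are filtered to those with
  ≥ 10 reads in ≥ 2 % of samples; zeros are replaced by the
  count-zero-multiplicative rule (each zero becomes δ = 0.65/n of the
  detection limit, non-zeros rescaled so ratios are preserved); the
  centered log-ratio transform maps each sample to
  clr_j = ln x_j − (1/K) Σ_k ln x_k, where Euclidean distance is the
  Aitchison distance.
* **Diversity over time.** Shannon index H = −Σ p_i ln p_i per sample,
  weekly coefficients of variation of H and of genus relative abundances.
* **Homogeneous microbial diversity (HMD) periods.** Circular binary
  segmentation of the time-ordered Shannon series: the maximal arc
  statistic Z_ij = (mean_in − mean_out)/(σ̂√(1/n_in + 1/n_out)) is referred
  to a permutation null (accept a changepoint at p ≤ 0.01, minimum
  segment width 2), recursively; a leading meconium sample is set apart as
  period 0.
* **Event-window tests on CLR values.** Mann–Whitney U for ±7-day point
  events; Kruskal–Wallis + Dunn for the five 28-day diet intervals and the
  30-day probiotic windows; Friedman + Conover on per-subject window
  averages for cohort designs; Benjamini–Hochberg across genera with
  significance at FDR ≤ 0.1; one-way PERMANOVA (999 permutations) on
  Aitchison distances.
* **Colonizer archetypes.** A rule-based classifier over weekly detection
  trajectories: *early-life* (detected in weeks 1–2, persistent),
  *re-appearing* (early pulse, ≥ 8-week observed gap, re-emergence),
  *later* (first detected at week ≥ 9), else unclassified. Ward clustering
  of genus trajectories and mother–infant overlap sets are included.
* **Downsampling experiment.** Five weekly subsamples (one random sample
  per week, distinct across runs where possible) are pushed through the
  same tests; per-genus weeks-detected and per-event significance
  retention are compared against the full-resolution reference.

## A worked example

```r
library(gutcadence)
library(dplyr)

dat  <- simulate_infant(sim_config(rng_seed = 1))   # ~250 quasi-daily samples
filt <- dat$table |> drop_empty_samples() |> filter_features()
clr  <- filt |> czm_replace() |> clr_transform()

ser <- diversity_series(dat$table, dat$meta)
fit <- cbs_segment(ser, alpha = 0.01, min_width = 2, seed = 12)
tidy(fit)
#> # A tibble: 5 × 7
#>   period_id start_index end_index n_markers mean_level start_day end_day
#>       <int>       <int>     <int>     <int>      <dbl>     <int>   <int>
#> 1         1           1        11        11       1.11         1      11
#> 2         2          12       131       120       1.96        12     134
#> 3         3         132       150        19       2.74       135     173
#> 4         4         151       164        14       3.07       174     197
#> 5         5         165       267       103       3.21       199     364
```

Five HMD periods: diversity rises from the neonatal period (mean Shannon
1.11) through the dietary-diversification phase and plateaus in a final
stable period of ~165 days at the year's highest diversity (3.21) — the
classic establishment trajectory.

```r
ev  <- dat$events |> filter(event_type == "probiotic")
res <- run_event_tests(clr, dat$meta, build_event_windows(ev, "probiotic"))
glance(res)
#> # A tibble: 1 × 4
#>   n_features n_significant fdr_threshold test_kind
#>        <int>         <int>         <dbl> <chr>
#> 1         55            20           0.1 kruskal_wallis_dunn
```

Twenty genera shift across the before/during/after probiotic windows at
FDR ≤ 0.1 — including all five genera the simulator actually perturbed
(4-fold). Re-running the same test on weekly subsamples
(`weekly_subsample()` + `downsampled_event_tests()`) loses most of these
calls, and `classify_colonizers()` on the subsampled table relabels about
two thirds of the planted re-appearing genera as "later" colonizers: the
sparse cadence misses their short early pulse entirely.

The whole chain, with files and a manifest:

```r
run_pipeline("out/", "all", seed = 1)
```

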