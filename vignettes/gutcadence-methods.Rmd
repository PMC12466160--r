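---
title: "Methods: compositional time-series analysis and sampling-cadence sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional time-series analysis and sampling-cadence sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gutcadence` analyses dense infant gut microbiome time series — genus-level
count tables with per-sample metadata and an event diary — and asks how
robust the findings are to sampling cadence. This vignette documents the
statistical model of each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design choices a maintainer should know
about.

## Data model and conventions

Counts are kept as exact integers until zero replacement; proportions are
always derived, never stored, because the zero-replacement rule must see
true zeros. Day of life counts birth as day 0 (a declared convention — the
data alone cannot distinguish it), and the week grid is birth-anchored:
`week = floor((day − 1)/7) + 1`, with day 0 in week 1, so the first year
spans exactly 52 weeks. Samples with zero total count are legal — meconium
frequently carries no amplifiable signal — and are excluded from every
composition-based step but kept in validation reports.

## Compositional preprocessing

Three steps, in a fixed order: **filter, replace zeros, transform**.

1. *Filter*: keep genera with ≥ `filter_min_reads` (10) reads in at least
   `ceiling(filter_min_prevalence × n_samples)` (2 %) samples. The
   condition is joint — a sample counts toward prevalence only when the
   read minimum is met in that sample — which is the strictest common
   reading, and ceiling (not rounding) is used so the threshold never
   drops to zero samples.
2. *Count-zero-multiplicative replacement*: in a sample with total `n` and
   `z` zeros, each zero becomes `δ = czm_fraction × (1/n)` and each
   non-zero proportion is rescaled by `(1 − zδ)`. The fraction defaults to
   0.65 of the detection limit, the long-standing default of the method's
   reference implementation; ratios between originally non-zero parts are
   preserved to machine precision (asserted at 1e-12 in tests).
3. *CLR*: `clr_j = ln x_j − mean_k ln x_k` with natural logarithms. Rows
   sum to zero within 1e-9; the transform is invariant to per-sample
   rescaling. Euclidean distance on CLR rows is the Aitchison distance,
   which is what PERMANOVA and the trajectory clustering consume.

## Diversity and weekly variability

Shannon's `H = −Σ p ln p` (natural log — the ecology default; base is a
convention the index itself does not fix) and richness are the two alpha
indices. Weekly variability uses the coefficient of variation
`100 × sd/mean` with the sample (n−1) standard deviation: within-week n is
small, so the unbiased estimator is the safer, and above all a *declared*,
choice. Weeks with fewer than two samples are flagged undefined rather
than dropped silently; per-genus CVs are computed on within-week relative
abundances and summarised across genera by median and quartiles.

## Segmentation into homogeneous diversity periods

The time-ordered Shannon series is segmented by circular binary
segmentation. For every circular arc (i, j] the standardized mean-shift
statistic

Z_ij = (mean_in − mean_out) / (σ̂ √(1/n_in + 1/n_out))

is computed with σ̂ the overall sample standard deviation of the segment
under test; the maximal |Z| is referred to a permutation null —
`p = (1 + #{permuted max ≥ observed}) / (n_permutations + 1)` — rather
than an asymptotic tail approximation. The permutation reference was
chosen because it is exact at the short series lengths that matter here
and is directly checkable against an exhaustive-arc enumeration oracle
(which the test suite does). A split is accepted at `p ≤ cbs_alpha`
(0.01) with at least `cbs_min_width` (2) markers per changed segment; an
interior arc yields two candidate changepoints, an edge-touching arc one,
and when the ternary split would violate the width constraint it collapses
to the single admissible boundary with the larger standalone binary-split
statistic (earlier boundary on ties). Recursion continues inside every
resulting segment; no undo/prune post-processing is applied. Missing days
are simply absent markers — the series is indexed by sample order, not
calendar day, so irregular sampling needs no imputation. Ties in the arc
scan are broken by the earliest (i, j) in lexicographic order, which means
a symmetric two-level series reports the *complement* arc of the late
segment — the same partition.

A leading meconium sample, when it carries counts and so enters the
series, is relabelled period 0 after segmentation to mark its distinct
stool type; a meconium sample anywhere else leaves the result unchanged
with a warning.

Calibration, verified in the test suite and recomputed by
`scripts/acceptance.R`: on 200 null series of length 100 the
false-breakpoint rate stays within the binomial envelope of α = 0.01; on
100 five-segment series with 3-sd shifts and 20-marker segments, all
planted breakpoints are recovered within ±2 positions in ≥ 95 % of runs.

## Event-window tests

All tests operate on CLR values, never raw counts. Window conventions:
±7-day windows around point events (Mann–Whitney U); five 28-day
intervals around solid-food introduction and before/during/after 30-day
probiotic windows (Kruskal–Wallis with Dunn's post hoc); and for cohort
designs, week-level windows with per-subject profile averaging followed by
Friedman with Conover's post hoc. Pre-event windows are clipped at birth.
Within a window set a sample belongs to at most one window.

Choices that the battery fixes explicitly: two-sided tests throughout;
mid-ranks and tie-corrected variances in every rank statistic; exact
Mann–Whitney p by enumeration when n ≤ 12 and tie-free, otherwise the
normal approximation with tie and continuity correction; Friedman's Q
carries the tie-correction factor `1 − Σ(t³−t)/(nk(k²−1))` (the base-R
implementation, which omits it, serves as the tie-free cross-check in the
tests). Benjamini–Hochberg adjustment is two-level: across genera within
one event test, and across pairwise comparisons within one genus for
Dunn/Conover. Significance is gated at q ≤ `fdr_threshold` (0.1); raw
p-values are always reported alongside, since display conventions
sometimes quote p ≤ 0.05.

When every subject ranks the conditions identically, Conover's residual
variance is zero; pairs with unequal rank sums then get p = 0 and equal
ones p = 1 — the degenerate but mathematically consistent limit.

PERMANOVA is one-way (factors are tested one at a time): the pseudo-F is
computed from the squared-distance partition
`F = (SS_between/(a−1)) / (SS_within/(N−a))` and referred to label
permutations (999 by default), or to complete enumeration of labelings on
small problems, where the p-value is the proportion of labelings (observed
included) reaching F — which makes the two-triplet toy problem come out at
exactly 2/20 = 0.1.

## Colonizer archetypes

The heatmap-level narrative of colonization — early-established persistent
genera, transiently present early genera that return with dietary
diversification, and genuinely late arrivals — is operationalized as an
explicit rule-based classifier over weekly detection trajectories, and its
outputs are flagged as such. Detection is count > 0 in any sample of the
week, applied after the global feature filter (presence, not abundance,
is what the detection-frequency analysis counts); weeks with no samples
are *unobserved* and never extend a gap. Thresholds, all config-exposed:
early window weeks 1–2 ("immediately after birth"), persistence ≥ 0.60 of
observed weeks after the early window, minimum observed gap of 8 weeks,
and first detection at week ≥ 9 for "later" (dietary diversification
around month 5 puts re-emergence well past week 9; a gap shorter than 8
weeks reads as dropout noise rather than true disappearance).

Rule precedence is a deliberate design decision: *re-appearing* is tested
before *early-life*. The two narrative definitions are not mutually
exclusive as stated — a genus with a long gap and a long re-emergence can
exceed the persistence bar — and a genus absent for 8+ observed weeks is
not "persistent throughout" under any reading, so the gap rule wins. This
keeps the four labels exhaustive and mutually exclusive (property-tested
over random trajectories).

## The weekly-downsampling experiment

One sample per populated week is selected uniformly; across the
`downsample_n_runs` (5) runs each week's samples are consumed without
replacement in a seeded random order until exhausted, then redrawn — the
operationalization of "different samples per iteration when possible",
which the source of the design left unspecified. Detection frequency per
genus (weeks detected) is compared per run against the full-resolution
reference, with 3- and 5-week reference thresholds flagged. Event tests
are re-run per subsample: the probiotic design unchanged; vaccination as a
rank-sum test of the three weekly samples nearest before versus after the
vaccination week (nearest in weeks, ties toward earlier), because ±7-day
windows cannot hold three weekly observations; runs with fewer than three
samples on a side are skipped with a notice. Downsampled colonizer
classification reuses the classifier with observed weeks = selected weeks.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
every property above is verified under. It emulates a quasi-daily diary of
one infant — 55 genera, days 0–364, day 0 an all-zero meconium — with
four planted archetypes (20 early-life, 10 re-appearing, 18 later, 7
transient-maternal), event effects, and Dirichlet-multinomial counts.

* **Latent intensities.** Each genus has a baseline intensity and a
  deterministic archetype profile: sigmoid onsets in week 1 for early-life
  genera; a faint day-1–14 pulse plus a post-solid-food sigmoid re-onset
  for re-appearing genera; per-genus onsets 0–75 days after solid food for
  later colonizers (two of which are instead switched on at the
  vaccination day); a week-1 pulse only for transient-maternal genera.
  Day-to-day log-normal noise declines linearly over the year (sd 0.7 →
  0.25), emulating the settling of intra-week variability.
* **The diversity regime** is carried by one dominant early genus (the
  *Bifidobacterium* role) whose intensity follows a declining staircase
  with steps at days 14, 112, 133 and 210 — the planted breakpoints. Step
  sizes were chosen once so that the staircase dominates the H noise
  (steps of ~0.3–0.6 Shannon units against within-phase sd ≤ 0.4); with
  smaller steps the planted regime would simply not be planted.
* **Events.** The probiotic (days 12–60) multiplies 5 target genera by 4,
  decaying exponentially (10-day scale) afterwards; effects are
  multiplicative on intensities so they are additive on the CLR scale and
  analytically checkable. Vaccination (day 112, week 16) switches on its
  designated genera; solid food (day 133, month 5) gates the later/
  re-appearing onsets.
* **Sampling.** The quasi-daily regime is daily through day 126 and then
  thins to 52 % of days, giving ≈ 250 samples — dense early months when
  diaries are most diligent, sparser later. This also means the ±7-day
  vaccination windows are fully sampled, as they must be for a 7-day
  design to be testable at all. Weekly cohorts draw one random day per
  week with 10 % of weeks missed, and per-subject log-normal feature
  offsets (sd 0.8) provide the between-subject separation that floors the
  cohort PERMANOVA p at 1/(permutations+1).
* **Counts.** Proportions are normalized intensities; counts are
  Dirichlet-multinomial with concentration 200 at a log-normal depth
  (median 20 000, sdlog 0.3). The Dirichlet concentration is what makes
  rare genera *intermittently* detectable: a genus at relative intensity
  ~2×10⁻⁴ is seen on only ~20 % of days regardless of depth. The
  re-appearing pulse level (0.05 intensity units) was placed in exactly
  this regime, because the phenomenon under study — a short early pulse
  that daily sampling catches and weekly sampling misses — lives at the
  detection limit by definition.

What the generator does **not** emulate: taxonomic correlation structure
(genera are conditionally independent given the Dirichlet draw), read-level
artifacts (chimeras, contamination), strain dynamics, autocorrelated
day-to-day noise, or any fit to real deposited data. Passing tests
therefore demonstrate that the pipeline's statistics behave as specified
under a realistic-order synthetic regime — calibrated nulls, recovered
planted effects — not that any biological claim about real infants is
reproduced.

## Numerical choices and degenerate inputs

Constant series have scan statistic 0 and are never split. Complete-tie
inputs return p = 1 (Mann–Whitney, Kruskal–Wallis, Friedman) instead of
NaN. Permutation counters use a 1e-12 slack when comparing statistics so
bit-level noise cannot flip a count. The CLR pipeline is fully
deterministic; every stochastic step (segmentation permutations,
subsampling, PERMANOVA, simulation) takes an explicit seed, stage seeds
derive from one master seed, and the pipeline writes a manifest (config
snapshot, seeds, output digests) sufficient to reproduce every file
byte-for-byte. TSV outputs round reals to 12 significant digits.

Problem sizes used by the verification runs — 200 null series and 100
recovery series for segmentation, 1000 features for the type-I
calibration, 50 subsampling seeds for the detection-loss contrast — were
chosen as the smallest sizes at which the binomial tolerances quoted above
are meaningful.

## Known limitations

* The classifier thresholds formalize a narrative; on real data they
  should be treated as tunable and reported alongside results.
* PERMANOVA is one-way; joint or sequential multi-factor designs are out
  of scope.
* Only Shannon and richness are implemented as alpha indices.
* The cohort pooling averages all in-window samples per subject; a
  minimum-time-interval sample preference (sometimes applied manually in
  practice) is deliberately not implemented, and this divergence is
  recorded here.
* Mixed-effects models for repeated measures are not provided; the rank
  tests treat windows as independent groups within a subject.
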