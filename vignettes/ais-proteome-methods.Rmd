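---
title: "Quantitative analysis of antibody-targeted proximity-labeling proteomes"
author: "proxirank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of antibody-targeted proximity-labeling proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxirank)
```

## The problem

Antibody-targeted proximity labeling biotinylates proteins in the immediate
neighbourhood of a bait epitope — here NFASC (neurofascin), which marks the
axon initial segment (AIS) of cultured neurons. Streptavidin capture followed
by quantitative mass spectrometry yields a protein-group table in which the
AIS signal is buried under three kinds of background: proteins adsorbed
non-specifically to the beads, endogenously biotinylated carboxylases (such
as PCCA) captured in every sample, and genuinely labeled proteins that are
abundant everywhere rather than AIS-enriched. proxirank implements the
ratiometric strategy that separates these layers:

* **negative controls** (omitting the primary antibody, `-1Ab`, or the
  biotin-phenol substrate, `-BP`) identify what is captured without targeted
  labeling;
* **spatial reference baits** (NeuN for the soma, MAP2 for somatodendrites,
  SMI312 for the axon) turn "biotinylated" into "biotinylated *and*
  AIS-enriched" by ranking each protein's bait-over-reference ratio.

The package operates downstream of the database search: its input is a
MaxQuant-style `proteinGroups` table (one row per protein group, with decoy
and contaminant flags, unique-peptide counts and per-channel reporter
intensities or heavy/light ratios).

## Identification filters

Every branch begins identically: contaminant and reverse-decoy rows are
removed and protein groups with fewer than two unique peptides are discarded.
Both filters are idempotent subsetting operations and commute with each
other. Protein identity across tables is the *leading accession* — the first
semicolon-separated token of the protein-group identifier — because group
memberships drift between searches while the leading accession is stable.
Reporter intensities of 0 are treated as missing (MaxQuant's convention for
an undetected reporter); H/L ratios are missing only when empty or `NaN`.

## Dimethyl H/L pair analysis

In the dimethyl experiments each comparison is a heavy/light pair (heavy =
anti-NFASC sample, light = control) measured in three independent
replicates. The branch applies, per pair:

1. **replicate coverage** — a protein must be quantified in at least two of
   three replicates (`replicate_coverage_filter()`);
2. **negative cutoff** — in the bait-versus-no-primary-antibody pair the H/L
   ratio must exceed 1.5 (strictly) in *every* replicate in which the
   protein is quantified (`negative_pair_cutoff()`). The cutoff is
   deliberately per-replicate: a protein missing in one replicate is not
   auto-excluded, because coverage is policed by the separate rule above;
3. **three-way intersection** of the surviving sets
   (`intersect_pairs()`), keyed on leading accessions.

Over the intersected set, log2(H/L) columns are centered on their median —
placing the unenriched bulk at zero — and averaged across replicates
(`average_normalized_ratios()`). Median centering is the default because the
centre of an H/L ratio distribution is dominated by unenriched proteins and
the median is robust to the enriched tail; mean centering is available via
`center = "mean"` for sensitivity analysis. Centering is computed after the
intersection so that the normalization population is the same set of
proteins that is reported.

## TMT multi-reference enrichment ranking

The 10-plex TMT design carries three NFASC bait channels, two negatives
(`-1Ab`, `-BP`), and five reference channels (NeuN, MAP2 ×2, SMI312 ×2) in
one run. The branch:

1. averages replicate channels per condition (`average_condition_channels()`)
   — **ratio of means**, not mean of ratios, which is the stabler choice with
   duplicate reference channels (a per-replicate-ratio mode would change
   only the noise properties, not the logic, and the condition means are the
   single place to swap it);
2. keeps proteins whose bait/negative mean-intensity ratio strictly exceeds
   2 against *both* negatives (`negative_control_filter()`); a protein
   detected in the bait but absent from a negative passes that negative's
   test (the ratio is effectively infinite);
3. computes per-reference normalized enrichment
   `log2(mean bait / mean reference)`, median-centered per column
   (`enrichment_ratios()`); a protein undetected in a reference receives a
   `+Inf` sentinel that sorts as maximally enriched, mirroring the
   developmental rule that bait-only detections are retained;
4. ranks each reference column in descending order (`rank_per_reference()`),
   averages the per-reference ranks into a rank score, and orders proteins
   by ascending score (`overall_rank()`);
5. intersects the per-reference top-200 lists into the high-confidence set
   (`top_n_overlap()`).

Tie handling is two-layered: tied enrichment values receive average
(fractional) ranks for the rank-score computation, while the reported
integer ranks (and the final overall rank) break residual ties by leading
accession, so output is deterministic and independent of input row order.
Because median centering subtracts a per-column constant, every rank — and
hence the high-confidence set — is invariant to global rescaling of the
intensities.

Replicate reproducibility (`replicate_correlation()`) is reported as the
squared Pearson correlation of log10 intensities over proteins quantified in
both members of a channel pair. MS intensities are log-normal over several
orders of magnitude; correlating raw intensities would let a handful of
abundant proteins dominate the statistic.

## Developmental dynamics across bridged experiments

Two parallel 10-plex experiments cover three stages of neuronal development
(DIV7, DIV14, DIV21), with DIV14 present in both as the bridge. Per stage,
the negative filter moves to the log2 scale: the mean over bait replicates
of `log2(bait) - log2(-1Ab)` must exceed 3.5 (DIV7, DIV21) or 1 (DIV14),
thresholds set by the stage-specific spread of the endogenously biotinylated
background; bait-only detections are retained. The surviving sets — plus an
independent prior DIV14 set when provided — are intersected across stages.

Cross-experiment comparability rests on a single anchor: every bait channel
is rescaled so that the endogenously biotinylated protein PCCA equals 1 in
that channel (`pcca_normalize()`). No additional batch factor is fitted —
the anchor is captured in every channel independent of targeted labeling,
and a channel-wise rescale is exactly the degree of freedom that differs
between runs. The operation is idempotent and commutes with per-channel
rescaling.

Downstream, proteins whose stage means change by more than 20% (max/min
pairwise ratio > 1.2, strict) in at least one stage pair are kept
(`change_filter()`); the alternative reading (relative change against the
earlier stage) differs only at the margin and is not the default. Profiles
are z-scored per protein with the population (divide-by-n) SD across the
three stages — three values per protein make the sample-SD correction both
noisy and irrelevant to the clustering geometry — and clustered by
agglomerative hierarchical clustering with Euclidean distance and complete
linkage, the defaults of the `cutree`-based heatmap tooling this mirrors,
cut into k = 6 clusters. Cluster ids are relabeled 1..k by descending size
so "cluster 1" is stable across runs. Trend labels derive from the cluster
mean z-profile: monotone `up`/`down`, `peaked`/`dipped` when DIV14 is the
extremum (a 3-point profile admits exactly these four shapes).

Volcano statistics between two stages use log2 fold changes of
anchor-normalized bait means and an unpaired two-tailed Student
(pooled-variance) t-test on the log2 values; DIV14 pools all four bait
channels across the two experiments, since two channels per experiment
cannot support a within-experiment test. Degenerate inputs are handled
explicitly: two zero-variance groups with equal means give p = 1; with
unequal means, p is set to the smallest representable positive value with a
warning. Calls use the conventional cutoffs |log2 FC| > 1 and p < 0.05.

## Imaging metrics

The validation-imaging math operates on already-extracted 1-D measurements:

* `corrected_mean_intensity()` — region mean minus same-image background
  (CMF); all downstream ratios are therefore invariant to a common additive
  offset.
* `specificity_ratio()` (AIS/soma CMF) and `polarity_index()`
  (AIS/dendrite CMF) — the denominator CMF must be positive.
* `periodicity()` — mean successive peak-to-peak spacing of a line profile
  in nm, the standard readout of the ~190 nm spectrin-based membrane
  periodic skeleton. Peaks are local maxima with topographic prominence of
  at least 20% of the profile's interquartile intensity range (making
  detection invariant to intensity scaling) and a minimum separation of
  100 nm, below any plausible spectrin period; both guards are configurable.
  Manual maximum-to-maximum measurement needs no such guards, an automated
  detector does. By default peak positions stay on the sampling grid; a
  3-point parabolic refinement (`refine = TRUE`) interpolates subpixel
  positions and is worthwhile when the period is not a multiple of the
  pixel size.

## The synthetic-data generator

`synthetic_spec()` + `generate_tmt_table()` / `generate_dimethyl_pairs()` /
`generate_stage_series()` emulate exactly the statistical structure the
pipeline assumes, with ground-truth labels attached so every recovery test
compares against the truth rather than hard-coded lists. The model:

* base abundance per protein is log-normal (log10 mean 6, SD 0.8), the
  dynamic range typical of a proteinGroups export;
* labeled channels multiply the base by condition effects: AIS proteins ×8
  in bait channels, compartment proteins ×4 in their own reference channel;
* negative-control channels capture non-specifically adsorbed proteins and
  endogenously biotinylated proteins at full strength but only a 5% leak of
  genuinely labeled signal — a realistic residual for omitting the primary
  antibody or the substrate;
* per-channel noise is log-normal with SD 0.25 on the log2 scale;
  channel values drop to missing at rate 0.02; decoy rows are flagged;
* the first endogenously biotinylated protein carries the PCCA accession
  (`P14882`) so the default anchor configuration works out of the box;
* every generator is a pure function of the spec including its seed.

The default composition (2000 background, 20 AIS at 8-fold, noise SD 0.25)
is the planted-signal condition exercised by the recovery tests. What the
generator does **not** emulate: correlated peptide-level missingness,
ratio compression from TMT co-isolation interference, abundance-dependent
noise, or realistic protein sequence content. Passing recovery tests
therefore demonstrate the pipeline's logic and its behaviour under
idealized noise — not performance on real co-isolation-compressed data.

One calibration subtlety: the volcano type-I rate is assessed on *raw*
generated tables. After anchor normalization every protein in a channel
shares the anchor's own measurement noise, which couples the nulls and
makes the empirical rate on any single seed swing far beyond binomial
error; calibrating the t-test requires independent nulls.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data:
the TMT fixture uses the full 2200-row planted table; the developmental
fixtures use 400–1000 background proteins with 60 trend-carrying proteins
(10 per template) at noise SD 0.05 for clustering recovery and 1000 null
proteins for calibration; periodicity uses 381-sample profiles (20 periods
at 10 nm sampling). These sizes give stable statistics while keeping a full
run in seconds. Medians use R's default linear interpolation for even
counts; all enrichment cutoffs are strict inequalities, so boundary-equal
values are excluded; all random draws flow from a single integer seed.

## Worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 1L)
gen <- generate_tmt_table(spec)
res <- tmt_rank_analysis(gen$table, div14_design())
res$counts
head(res$ranks[, c("protein_id", "avg_rank_score", "overall_rank")])
```

## Known limitations

* The exact reporter column choice of the original search exports
  ("Reporter intensity corrected" vs raw) is configurable but the corrected
  columns are the default; on real exports the choice shifts absolute
  ratios slightly.
* The bridged design is normalized by the anchor alone; systematic
  label-efficiency differences between experiments that also affect the
  anchor cannot be distinguished from biology.
* The clustering is parameterized (linkage, distance, k) rather than
  model-based; cluster counts other than 6 are worth inspecting on real
  data.
* Periodicity estimation assumes an approximately uniform sampling step and
  a single dominant period.
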