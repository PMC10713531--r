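# proxirank

Quantitative analysis of antibody-targeted proximity-labeling proteomics of
the axon initial segment (AIS), for proteomics analysts working with
MaxQuant-style `proteinGroups` exports.

In these experiments a peroxidase coupled to an anti-NFASC antibody
biotinylates proteins near the AIS of cultured neurons; streptavidin capture
and multiplexed mass spectrometry then quantify each protein across bait,
negative-control and spatial-reference samples. The analytical problem is to
separate AIS-enriched proteins from non-specific bead background,
endogenously biotinylated carboxylases, and abundant-everywhere proteins.
proxirank implements the full ratiometric workflow:

* **Dimethyl H/L pair analysis** — per-pair replicate-coverage filters, a
  strict H/L > 1.5 cutoff against the no-primary-antibody control, three-way
  intersection, and replicate-averaged median-centered
  log<sub>2</sub>(H/L) enrichment:
  `norm log2(H/L) = log2(H/L) − median log2(H/L)` per replicate column.
* **10-plex TMT multi-reference ranking** — condition means over replicate
  channels, a bait/negative ratio cutoff (> 2 against both −BP and −1Ab),
  median-centered `log2(NFASC/reference)` per reference (NeuN = soma,
  MAP2 = somatodendrites, SMI312 = axon), descending per-reference ranks,
  an overall rank by average rank score, and the high-confidence set as the
  overlap of the per-reference top-200 lists.
* **Developmental dynamics** — two bridged 10-plex experiments across
  DIV7/14/21 with stage-specific log2 cutoffs (3.5 / 1), cross-stage
  intersection, PCCA-anchored normalization of bait channels, a >20% change
  filter, z-scored profile clustering (Euclidean, complete linkage, k = 6)
  with fraction/trend summaries, and volcano statistics (pooled-variance
  t-test, |log2 FC| > 1, p < 0.05).
* **Imaging metrics** — corrected mean fluorescence (region − background),
  AIS/soma specificity and AIS/dendrite polarity ratios, and line-profile
  periodicity (mean peak-to-peak spacing, prominence-guarded peak
  detection) for the ~190 nm membrane periodic skeleton.
* **Synthetic data** — generators for TMT tables, dimethyl pairs and
  bridged stage series with planted ground truth, so the entire pipeline is
  testable without any external download.

## Worked example

```r
library(proxirank)

spec <- synthetic_spec(seed = 1L)            # 2000 background + 20 AIS proteins at 8x
gen  <- generate_tmt_table(spec)             # 10-plex TMT table + truth labels
res  <- tmt_rank_analysis(gen$table, div14_design())

res$counts
#>        detected    biotinylated high_confidence
#>            2063             171             171

head(res$ranks[, c("protein_id", "rank_NeuN", "rank_MAP2", "rank_SMI312",
                   "avg_rank_score", "overall_rank")], 5)
#>   protein_id rank_NeuN rank_MAP2 rank_SMI312 avg_rank_score overall_rank
#> 1   SYN02002         7         4           3       4.666667            1
#> 2   SYN02017        12         1           1       4.666667            2
#> 3   SYN02013        11         2           4       5.666667            3
#> 4   SYN02016         6         3          13       7.333333            4
#> 5   SYN02012         8        10           5       7.666667            5

res$correlations
#>   channel_a channel_b n_common r_squared
#> 1   NFASC_1   NFASC_2     1971 0.9838109
#> 2   NFASC_1   NFASC_3     1975 0.9832620
#> 3   NFASC_2   NFASC_3     1971 0.9845043
```

Of 2200 generated protein groups, 2063 survive the decoy and unique-peptide
filters, 171 pass the negative-control ratio cutoff (the genuinely labeled
fraction), and the bait replicates correlate at r² ≈ 0.98 on the log scale.
All 20 planted AIS proteins land in the overall top 30:

```r
ais <- gen$truth$protein_id[gen$truth$category == "ais"]
sum(ais %in% res$ranks$protein_id[res$ranks$overall_rank <= 30])
#> [1] 20
```

Real exports are read with `read_protein_groups()` /` read_hl_table()`
against a `channel_design()` (or a YAML design file, see
`read_channel_design()`); `run_analysis()` drives any branch from a single
config file, and `inst/scripts/proxirank` wraps it for the shell.

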