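dev_table <- function(vals, design, ...) {
  colnames(vals) <- design$channels$channel_id
  toy_table(vals, ...)
}

test_that("stage negative filter applies the per-stage log2 cutoff on bait replicates", {
  designs <- stage_design()
  d1 <- designs$TMT1  # DIV7 + DIV14
  v <- matrix(NA_real_, 3L, 10L)
  colnames(v) <- d1$channels$channel_id
  # DIV7: bait reps (1600, 1600), negative 100 -> mean log2 diff 4 > 3.5: kept
  v[1L, c("NFASC_DIV7_1", "NFASC_DIV7_2")] <- 1600
  v[1L, "no_primary_antibody_DIV7_1"] <- 100
  # DIV7: bait reps (800, 800) -> diff 3 <= 3.5: dropped
  v[2L, c("NFASC_DIV7_1", "NFASC_DIV7_2")] <- 800
  v[2L, "no_primary_antibody_DIV7_1"] <- 100
  # bait-only detection is retained
  v[3L, "NFASC_DIV7_1"] <- 50
  qt <- toy_table(v)
  expect_setequal(stage_negative_filter(qt, d1, "DIV7"), c("P001", "P003"))
  # DIV14: bait reps (300, 100), negative 100 -> mean diff ~0.79 < 1: dropped
  v14 <- matrix(NA_real_, 1L, 10L)
  colnames(v14) <- d1$channels$channel_id
  v14[1L, c("NFASC_DIV14_1", "NFASC_DIV14_2")] <- c(300, 100)
  v14[1L, "no_primary_antibody_DIV14_1"] <- 100
  expect_length(stage_negative_filter(toy_table(v14), d1, "DIV14"), 0L)
  # but the same protein passes at a lower explicit threshold
  expect_equal(stage_negative_filter(toy_table(v14), d1, "DIV14", threshold = 0.5),
               "P001")
})

test_that("cross-stage intersection reduces to the smallest nested set and handles empties", {
  expect_setequal(cross_stage_intersection(c("A", "B", "C"), c("A", "B"), "A"), "A")
  expect_length(cross_stage_intersection(c("A", "B"), character(0L), c("A")), 0L)
  expect_setequal(cross_stage_intersection(list(c("A", "B"), c("B", "A"))), c("A", "B"))
})

test_that("anchor normalization rescales bait channels so the anchor equals 1", {
  designs <- stage_design()
  d1 <- designs$TMT1
  v <- matrix(1000, 2L, 10L)
  colnames(v) <- d1$channels$channel_id
  v[1L, "NFASC_DIV7_1"] <- 500   # anchor
  v[2L, "NFASC_DIV7_1"] <- 1000  # protein X: becomes 2.0
  qt <- toy_table(v, ids = c("P14882", "P002"))
  norm <- pcca_normalize(qt, d1)
  m <- channel_values(norm)
  expect_equal(m["P14882", "NFASC_DIV7_1"], 1)
  expect_equal(m["P002", "NFASC_DIV7_1"], 2)
  # non-bait channels untouched
  expect_equal(m["P002", "no_primary_antibody_DIV7_1"], 1000)
  # idempotence
  expect_equal(channel_values(pcca_normalize(norm, d1)), m)
  # scale invariance: 10x one bait channel changes nothing after normalization
  v2 <- v
  v2[, "NFASC_DIV14_1"] <- v2[, "NFASC_DIV14_1"] * 10
  expect_equal(channel_values(pcca_normalize(toy_table(v2, ids = c("P14882", "P002")), d1)), m)
  # anchor missing in a bait channel is an error naming the channel
  v3 <- v
  d2 <- designs$TMT2
  colnames(v3) <- d2$channels$channel_id
  v3[1L, "NFASC_DIV21_1"] <- NA
  expect_error(pcca_normalize(toy_table(v3, ids = c("P14882", "P002")), d2),
               "NFASC_DIV21_1")
})

test_that("change filter keeps proteins with >20% relative change in some stage pair", {
  prof <- rbind(P1 = c(100, 110, 119),  # max ratio 1.19: dropped
                P2 = c(100, 125, 110),  # ratio 1.25: kept
                P3 = c(50, 50, 50))     # constant: dropped
  colnames(prof) <- c("DIV7", "DIV14", "DIV21")
  expect_equal(change_filter(prof), "P2")
  # symmetric in stage order and scale invariant
  expect_equal(change_filter(prof[, c(3, 1, 2)]), "P2")
  expect_equal(change_filter(prof * 1e3), "P2")
  # non-positive means are excluded with a warning
  prof2 <- rbind(prof, P4 = c(0, 10, 10))
  expect_warning(kept <- change_filter(prof2), "non-positive")
  expect_equal(kept, "P2")
})

test_that("z-scored profiles have mean 0 and population SD 1, with constant profiles at zero", {
  prof <- rbind(A = c(1, 2, 3), B = c(5, 5, 5))
  z <- zscore_profiles(prof)
  expect_equal(unname(z["A", ]), c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(unname(z["A", ]), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(unname(z["B", ]), c(0, 0, 0))
  # permuting stages permutes z identically
  expect_equal(unname(zscore_profiles(prof[, c(2, 3, 1)])["A", ]),
               unname(z["A", c(2, 3, 1)]))
  # property: random profiles standardize exactly
  set.seed(5)
  r <- matrix(rnorm(60), 20L)
  zr <- zscore_profiles(r)
  expect_equal(rowMeans(zr), rep(0, 20L), tolerance = 1e-12)
  expect_equal(apply(zr, 1L, function(v) sqrt(mean(v^2))), rep(1, 20L),
               tolerance = 1e-12)
})

test_that("clustering recovers well-separated planted templates and relabels by size", {
  set.seed(2)
  tpl <- trend_templates()
  raw <- t(sapply(rep(seq_along(tpl), times = c(15, 12, 10, 9, 8, 6)),
                  function(i) tpl[[i]]))
  planted <- rep(seq_along(tpl), times = c(15, 12, 10, 9, 8, 6))
  z <- zscore_profiles(raw + matrix(rnorm(length(raw), 0, 0.05), nrow(raw)))
  rownames(z) <- sprintf("P%03d", seq_len(nrow(z)))
  cl <- cluster_profiles(z, k = 6L)
  expect_true(partitions_identical(cl, planted))
  # labels are 1..k by descending size
  expect_equal(as.integer(table(cl)), sort(as.integer(table(cl)), decreasing = TRUE))
  expect_equal(sum(table(cl)), nrow(z))
  # k = 1 puts everything together; duplicates always co-cluster
  expect_true(all(cluster_profiles(z, k = 1L) == 1L))
  zdup <- rbind(z, P999 = z[1L, ])
  cldup <- cluster_profiles(zdup, k = 6L)
  expect_equal(unname(cldup["P999"]), unname(cldup[rownames(z)[1L]]))
  expect_error(cluster_profiles(z[1:3, ], k = 6L), "exceeds")
})

test_that("cluster fractions sum to 100% and trend labels follow the mean profile", {
  z <- rbind(matrix(rep(c(-1, 0, 1), 5L), 5L, byrow = TRUE),
             matrix(rep(c(1, 0, -1), 3L), 3L, byrow = TRUE),
             matrix(rep(c(-1, 1.5, -0.5), 2L), 2L, byrow = TRUE))
  colnames(z) <- c("DIV7", "DIV14", "DIV21")
  rownames(z) <- sprintf("P%02d", 1:10)
  cl <- c(rep(1L, 5L), rep(2L, 3L), rep(3L, 2L))
  s <- cluster_fraction_summary(cl, z)
  expect_equal(s$fraction_pct, c(50, 30, 20))
  expect_equal(sum(s$fraction_pct), 100)
  expect_equal(s$trend, c("up", "down", "peaked"))
})

test_that("volcano statistics compute pooled-variance t-tests with fold-change calls", {
  designs <- stage_design()
  # protein with a clean 4x DIV7 -> DIV21 increase and one flat protein;
  # per-channel jitter makes variances non-zero
  mk <- function(design, div_vals) {
    ch <- design$channels
    v <- matrix(NA_real_, 3L, 10L)
    colnames(v) <- ch$channel_id
    for (j in seq_len(nrow(ch))) {
      jitter <- c(1, 1.05)[ch$replicate_index[j]]
      v[, j] <- div_vals[[ch$stage[j]]] * jitter
    }
    toy_table(v, ids = c("P14882", "UP1", "FLAT"))
  }
  t1 <- mk(designs$TMT1, list(DIV7 = c(100, 50, 80), DIV14 = c(100, 100, 80)))
  t2 <- mk(designs$TMT2, list(DIV21 = c(100, 200, 80), DIV14 = c(100, 100, 80)))
  v <- volcano_stats(list(t1, t2), designs, c("UP1", "FLAT"), "DIV7", "DIV21")
  up <- v[v$protein_id == "UP1", ]
  expect_equal(up$log2_fc, 2, tolerance = 1e-6)
  expect_equal(up$call, "up")
  flat <- v[v$protein_id == "FLAT", ]
  expect_equal(flat$log2_fc, 0, tolerance = 1e-6)
  expect_equal(flat$call, "ns")
  # swapping stages negates fold changes and preserves p-values
  v_swap <- volcano_stats(list(t1, t2), designs, c("UP1", "FLAT"), "DIV21", "DIV7")
  expect_equal(v_swap$log2_fc, -v$log2_fc)
  expect_equal(v_swap$p_value, v$p_value, tolerance = 1e-12)
})

test_that("volcano degenerate groups: equal constant groups give p = 1, unequal give tiny p", {
  designs <- stage_design()
  mk <- function(design, div7, div21 = div7) {
    ch <- design$channels
    v <- matrix(NA_real_, 2L, 10L)
    colnames(v) <- ch$channel_id
    for (j in seq_len(nrow(ch))) {
      v[, j] <- if (ch$stage[j] == "DIV7") div7 else div21
    }
    toy_table(v, ids = c("A", "B"))
  }
  t1 <- mk(designs$TMT1, c(100, 100))
  t2 <- mk(designs$TMT2, c(100, 100))
  v <- volcano_stats(list(t1, t2), designs, c("A", "B"), "DIV7", "DIV21")
  expect_equal(v$p_value, c(1, 1))
  expect_equal(v$call, c("ns", "ns"))
  t2b <- mk(designs$TMT2, c(400, 100))
  expect_warning(
    v2 <- volcano_stats(list(t1, t2b), designs, c("A", "B"), "DIV7", "DIV21"),
    "zero variance")
  expect_equal(v2$p_value[v2$protein_id == "A"], .Machine$double.xmin)
  expect_equal(v2$call[v2$protein_id == "A"], "up")
})

test_that("the full developmental branch recovers planted trends end to end", {
  spec <- synthetic_spec(n_background = 200L, n_ais = 30L,
                         n_reference_enriched = c(NeuN = 5L, MAP2 = 5L, SMI312 = 0L),
                         n_endogenous_biotin = 3L, log2_noise_sd = 0.05,
                         missing_rate = 0, n_contaminant_decoys = 6L, seed = 33L)
  gen <- generate_stage_series(spec)
  res <- development_analysis(gen$tables[[1L]], gen$tables[[2L]], gen$designs)
  # planted AIS proteins carry trends and pass stage filters and the change filter
  ais <- gen$truth$protein_id[gen$truth$category == "ais"]
  expect_true(all(ais %in% res$ids$common))
  expect_true(all(ais %in% res$ids$changing))
  # filter chain is monotone
  expect_lte(res$counts[["changing"]], res$counts[["common"]])
  # clustered trends agree with the planted templates
  truth_trend <- gen$truth$trend[match(names(res$assignments), gen$truth$protein_id)]
  expect_true(partitions_identical(res$assignments, truth_trend))
  # a planted 4-fold DIV7 -> DIV21 increase is called "up"
  up_ids <- gen$truth$protein_id[gen$truth$trend == "up"]
  v <- res$volcano$DIV7_vs_DIV21
  expect_true(all(v$call[v$protein_id %in% up_ids] == "up"))
})
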