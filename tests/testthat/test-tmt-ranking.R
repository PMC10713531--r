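make_ratio_matrix <- function(values, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(values)))
  rownames(values) <- ids
  values
}

test_that("condition averaging takes the mean of non-missing replicate channels", {
  design <- div14_design()
  vals <- matrix(NA_real_, 3L, 10L,
                 dimnames = list(NULL, design$channels$channel_id))
  vals[1L, c("NFASC_1", "NFASC_2", "NFASC_3")] <- c(100, 200, 300)
  vals[2L, c("MAP2_1", "MAP2_2")] <- c(80, NA)
  vals[3L, ] <- NA
  qt <- toy_table(vals)
  means <- average_condition_channels(qt, design)
  expect_equal(means["P001", "NFASC"], 200)
  expect_equal(means["P002", "MAP2"], 80)
  expect_true(all(is.na(means["P003", ])))
})

test_that("negative-control filter requires strict ratio > 2 against both negatives", {
  design <- div14_design()
  mk <- function(nfasc, no_bp, no_1ab) {
    v <- matrix(NA_real_, 1L, 10L,
                dimnames = list(NULL, design$channels$channel_id))
    v[1L, c("NFASC_1", "NFASC_2", "NFASC_3")] <- nfasc
    v[1L, "no_BP_1"] <- no_bp
    v[1L, "no_primary_antibody_1"] <- no_1ab
    v
  }
  # ratios 2.5 and 2.22: kept
  qt <- toy_table(mk(100, 40, 45))
  expect_equal(negative_control_filter(qt, design), "P001")
  # ratio 100/60 = 1.67: dropped
  expect_length(negative_control_filter(toy_table(mk(100, 60, 45)), design), 0L)
  # boundary ratio exactly 2 fails the strict inequality
  expect_length(negative_control_filter(toy_table(mk(100, 50, 45)), design), 0L)
  # missing negative counts as an infinite ratio and passes
  expect_equal(negative_control_filter(toy_table(mk(100, NA, 45)), design), "P001")
  # missing bait fails
  expect_length(negative_control_filter(toy_table(mk(NA, 40, 45)), design), 0L)
})

test_that("enrichment ratios are median-centered per reference with +Inf for missing references", {
  design <- div14_design()
  v <- matrix(NA_real_, 3L, 10L,
              dimnames = list(NULL, design$channels$channel_id))
  v[, c("NFASC_1", "NFASC_2", "NFASC_3")] <- c(400, 800, 400)
  v[, "NeuN_1"] <- c(100, 100, NA)
  v[, c("MAP2_1", "MAP2_2")] <- c(400, 100, 400)
  v[, c("SMI312_1", "SMI312_2")] <- c(400, 200, 100)
  qt <- toy_table(v)
  r <- enrichment_ratios(qt, design, sprintf("P%03d", 1:3))
  # raw NeuN log2 FCs are (2, 3, Inf); finite median 2.5 -> centered (-0.5, 0.5, Inf)
  expect_equal(unname(r[, "NeuN"]), c(-0.5, 0.5, Inf))
  # each column has median 0 over its finite entries
  for (ref in colnames(r)) {
    expect_equal(median(r[is.finite(r[, ref]), ref]), 0)
  }
})

test_that("per-reference ranks match an independent sort oracle on random matrices", {
  set.seed(7)
  for (i in 1:3) {
    n <- 100L
    m <- make_ratio_matrix(cbind(NeuN = rnorm(n), MAP2 = rnorm(n), SMI312 = rnorm(n)))
    m[sample(n, 3L), "NeuN"] <- Inf  # missing-reference sentinels sort first
    rk <- rank_per_reference(m)
    for (ref in colnames(m)) {
      expect_equal(rk[[paste0("rank_", ref)]],
                   oracle_rank_desc(m[, ref], rownames(m)))
      expect_setequal(rk[[paste0("rank_", ref)]], seq_len(n))
    }
  }
})

test_that("ties get fractional ranks for scores and deterministic id-order integer ranks", {
  m <- make_ratio_matrix(cbind(NeuN = c(2.0, -0.5, 1.0, 1.0)),
                         ids = c("B", "D", "C", "A"))
  rk <- rank_per_reference(m)
  expect_equal(rk$rank_NeuN, c(1L, 4L, 3L, 2L))  # tie A before C by id
  expect_equal(rk$frank_NeuN, c(1, 4, 2.5, 2.5))
})

test_that("overall rank averages fractional ranks and re-sorts with id tiebreak", {
  set.seed(12)
  n <- 50L
  m <- make_ratio_matrix(cbind(NeuN = rnorm(n), MAP2 = rnorm(n), SMI312 = rnorm(n)))
  out <- overall_rank(rank_per_reference(m))
  # oracle: recompute the score sort directly
  score <- rowMeans(cbind(rank(-m[, "NeuN"], ties.method = "average"),
                          rank(-m[, "MAP2"], ties.method = "average"),
                          rank(-m[, "SMI312"], ties.method = "average")))
  oracle <- rownames(m)[order(score, rownames(m))]
  expect_equal(out$protein_id, oracle)
  expect_setequal(out$overall_rank, seq_len(n))
  expect_equal(out$avg_rank_score, unname(score[match(out$protein_id, rownames(m))]))
  # simple tie case: equal scores broken lexicographically
  m2 <- make_ratio_matrix(cbind(NeuN = c(1, 2), MAP2 = c(2, 1)), ids = c("B", "A"))
  out2 <- overall_rank(rank_per_reference(m2))
  expect_equal(out2$protein_id, c("A", "B"))
  expect_equal(out2$avg_rank_score, c(1.5, 1.5))
})

test_that("top-n overlap intersects per-reference top lists and warns when n exceeds the table", {
  m <- make_ratio_matrix(cbind(NeuN = c(3, 2, 1, 0), MAP2 = c(3, 0, 2, 1),
                               SMI312 = c(3, 1, 0, 2)),
                         ids = c("A", "B", "C", "D"))
  rk <- rank_per_reference(m)
  expect_setequal(top_n_overlap(rk, 2L), "A")
  expect_setequal(top_n_overlap(rk, 4L), c("A", "B", "C", "D"))
  expect_warning(res <- top_n_overlap(rk, 10L), "exceeds")
  expect_setequal(res, c("A", "B", "C", "D"))
  # monotone non-decreasing in n
  sizes <- vapply(1:4, function(n) length(top_n_overlap(rk, n)), integer(1L))
  expect_true(all(diff(sizes) >= 0))
})

test_that("identical per-reference rankings give |overlap| = n", {
  m <- make_ratio_matrix(cbind(NeuN = 10:1, MAP2 = 10:1, SMI312 = 10:1))
  rk <- rank_per_reference(m)
  for (n in c(1L, 5L, 10L)) expect_length(top_n_overlap(rk, n), n)
})

test_that("replicate correlation is 1 for identical and proportional channels, near 0 for independent ones", {
  design <- div14_design()
  set.seed(4)
  n <- 1000L
  base <- 10^rnorm(n, 6, 0.8)
  v <- matrix(NA_real_, n, 10L, dimnames = list(NULL, design$channels$channel_id))
  v[, "NFASC_1"] <- base
  v[, "NFASC_2"] <- base          # identical
  v[, "NFASC_3"] <- 2 * base      # proportional: affine on the log scale
  qt <- toy_table(v)
  corr <- replicate_correlation(qt, design, "NFASC")
  expect_equal(corr$r_squared, rep(1, 3L), tolerance = 1e-12)
  expect_equal(corr$n_common, rep(n, 3L))
  # independent log-normal draws decorrelate
  v[, "NFASC_2"] <- 10^rnorm(n, 6, 0.8)
  corr2 <- replicate_correlation(toy_table(v), design, "NFASC")
  expect_lt(corr2$r_squared[corr2$channel_a == "NFASC_1" &
                            corr2$channel_b == "NFASC_2"], 0.05)
  # too few common elements is an error
  v[1:(n - 2L), "NFASC_2"] <- NA
  expect_error(replicate_correlation(toy_table(v), design, "NFASC"), "common elements")
})

test_that("ranks are invariant to input row order and to global intensity rescaling", {
  spec <- synthetic_spec(n_background = 150L, n_ais = 10L,
                         n_reference_enriched = c(NeuN = 5L, MAP2 = 5L, SMI312 = 5L),
                         seed = 19L)
  gen <- generate_tmt_table(spec)
  design <- div14_design()
  res <- suppressWarnings(tmt_rank_analysis(gen$table, design))
  # shuffle rows
  set.seed(2)
  shuffled <- gen$table[sample(nrow(gen$table)), ]
  shuffled <- quant_table(shuffled[, 1:5], as.matrix(shuffled[, -(1:5)]),
                          value_kind = "reporter_intensity")
  res_sh <- suppressWarnings(tmt_rank_analysis(shuffled, design))
  ord <- order(res$ranks$protein_id)
  ord_sh <- order(res_sh$ranks$protein_id)
  expect_equal(res$ranks$overall_rank[ord], res_sh$ranks$overall_rank[ord_sh])
  # scale every channel of every protein by a constant
  scaled <- quant_table(as.data.frame(gen$table)[, 1:5],
                        channel_values(gen$table) * 7.3,
                        value_kind = "reporter_intensity")
  res_sc <- suppressWarnings(tmt_rank_analysis(scaled, design))
  ord_sc <- order(res_sc$ranks$protein_id)
  expect_equal(res$ranks$overall_rank[ord], res_sc$ranks$overall_rank[ord_sc])
  expect_setequal(res_sc$high_confidence, res$high_confidence)
})
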