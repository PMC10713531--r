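#' Per-condition mean intensities across replicate channels
#'
#' Summarizes replicate channels of each condition (optionally within a
#' stage) by the arithmetic mean of the non-missing channels; a condition
#' is missing only when all of its channels are missing.
#'
#' @param table a [quant_table()].
#' @param design a [channel_design()].
#' @param stage optional stage restricting which channels are used.
#' @return Numeric matrix, rows = proteins (rownames = leading accession),
#'   columns = conditions.
#' @export
average_condition_channels <- function(table, design, stage = NULL) {
  ch <- design_channels(design, stage = stage)
  if (nrow(ch) == 0L) stop("no channels in design", if (!is.null(stage)) paste0(" for stage ", stage))
  values <- channel_values(table)
  conds <- unique(ch$condition)
  out <- vapply(conds, function(cond) {
    cols <- ch$channel_id[ch$condition == cond]
    rowMeans(values[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(values),
                                       dimnames = list(rownames(values), conds))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- rownames(values)
  out
}

#' Negative-control enrichment filter for a TMT experiment
#'
#' A protein is biotinylated (rather than background) if its mean bait
#' (NFASC) intensity exceeds `cutoff` times its mean intensity in each
#' negative control (no biotin-phenol and no primary antibody). A protein
#' detected in the bait but missing in a negative passes that negative's
#' test (infinite ratio); a protein missing in the bait fails. Both
#' inequalities are strict.
#'
#' @param table a [quant_table()].
#' @param design a [channel_design()].
#' @param cutoff ratio cutoff (default 2).
#' @param stage optional stage restriction.
#' @return Character vector of leading accessions passing both negatives.
#' @export
negative_control_filter <- function(table, design, cutoff = 2, stage = NULL) {
  means <- average_condition_channels(table, design, stage)
  neg_conds <- unique(design_channels(design, stage = stage, role = "negative")$condition)
  pos <- means[, "NFASC"]
  pass <- !is.na(pos)
  for (neg in neg_conds) {
    ratio <- ifelse(is.na(means[, neg]), Inf, pos / means[, neg])
    pass <- pass & !is.na(pos) & ratio > cutoff
  }
  rownames(means)[pass]
}

#' Normalized log2 enrichment ratios against each spatial reference
#'
#' For every reference condition in the design, computes
#' log2(mean bait / mean reference) per protein, then centers each
#' reference column on its median so unenriched proteins sit at zero.
#' A protein detected in the bait but missing in a reference receives a
#' `+Inf` sentinel that sorts as maximally enriched.
#'
#' @param table a [quant_table()].
#' @param design a [channel_design()].
#' @param ids proteins to include (normally the output of
#'   [negative_control_filter()]).
#' @param stage optional stage restriction.
#' @param center centering statistic, see [median_center_log_ratios()].
#' @return Numeric matrix of normalized log2 fold changes, rows = `ids`,
#'   columns = reference conditions.
#' @export
enrichment_ratios <- function(table, design, ids, stage = NULL, center = "median") {
  means <- average_condition_channels(table, design, stage)
  ids <- intersect(ids, rownames(means))
  means <- means[ids, , drop = FALSE]
  refs <- unique(design_channels(design, stage = stage, role = "reference")$condition)
  if (length(refs) == 0L) stop("design declares no reference conditions")
  raw <- vapply(refs, function(r) {
    ifelse(is.na(means[, r]), Inf, log2(means[, "NFASC"] / means[, r]))
  }, numeric(length(ids)))
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = length(ids),
                                       dimnames = list(ids, refs))
  out <- apply(raw, 2L, median_center_log_ratios, center = center)
  if (is.null(dim(out))) out <- matrix(out, nrow = length(ids))
  dimnames(out) <- list(ids, refs)
  out
}

# descending integer rank with deterministic id tiebreak: rank 1 = largest
rank_descending <- function(x, ids) {
  ord <- order(-x, ids)
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

#' Per-reference ranks of normalized enrichment
#'
#' Ranks proteins within each reference column in descending order of
#' normalized log2 fold change (rank 1 = most enriched). Integer ranks are
#' a permutation of 1..n with ties broken by leading accession; fractional
#' (average-tie) ranks are kept alongside for rank-score averaging.
#'
#' @param ratios matrix from [enrichment_ratios()].
#' @return A `rank_table`: data frame with `protein_id`, one `rank_<ref>`
#'   integer column per reference, and matching `frank_<ref>` fractional
#'   columns.
#' @export
rank_per_reference <- function(ratios) {
  ids <- rownames(ratios)
  out <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (ref in colnames(ratios)) {
    x <- ratios[, ref]
    out[[paste0("rank_", ref)]] <- rank_descending(x, ids)
    out[[paste0("frank_", ref)]] <- rank(-x, ties.method = "average")
  }
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Overall rank from average per-reference rank scores
#'
#' The average rank score is the mean of a protein's fractional ranks
#' across the references; the overall rank orders proteins by ascending
#' score (ties broken by leading accession), so the most consistently
#' bait-enriched proteins rank first.
#'
#' @param ranks a `rank_table` from [rank_per_reference()].
#' @return The same table with `avg_rank_score` and `overall_rank` added,
#'   sorted by `overall_rank`.
#' @export
overall_rank <- function(ranks) {
  fcols <- grep("^frank_", names(ranks), value = TRUE)
  if (length(fcols) == 0L) stop("no per-reference rank columns present")
  score <- rowMeans(as.matrix(ranks[fcols]))
  ranks$avg_rank_score <- score
  ranks$overall_rank <- rank_descending(-score, ranks$protein_id)
  ranks <- ranks[order(ranks$overall_rank), , drop = FALSE]
  rownames(ranks) <- NULL
  ranks
}

#' High-confidence set: overlap of the per-reference top-n lists
#'
#' @param ranks a `rank_table` with per-reference integer ranks.
#' @param n list depth (default 200). If `n` exceeds the table size the
#'   full table is used with a warning.
#' @return Character vector of proteins in the top `n` of every reference.
#' @export
top_n_overlap <- function(ranks, n = 200L) {
  rcols <- grep("^rank_", names(ranks), value = TRUE)
  if (n > nrow(ranks)) {
    warning("n = ", n, " exceeds table size ", nrow(ranks), "; using the full table")
    n <- nrow(ranks)
  }
  sets <- lapply(rcols, function(cl) ranks$protein_id[ranks[[cl]] <= n])
  Reduce(intersect, sets)
}

#' Reproducibility of replicate channels
#'
#' Squared Pearson correlation of log10 intensities between every pair of
#' replicate channels of a condition, over the proteins quantified in both
#' members of the pair.
#'
#' @param table a [quant_table()].
#' @param design a [channel_design()].
#' @param condition condition whose replicates are compared.
#' @param stage optional stage restriction.
#' @return Data frame with `channel_a`, `channel_b`, `n_common`,
#'   `r_squared`.
#' @export
replicate_correlation <- function(table, design, condition, stage = NULL) {
  ch <- design_channels(design, stage = stage, condition = condition)
  if (nrow(ch) < 2L) stop("condition ", condition, " has fewer than 2 replicate channels")
  values <- channel_values(table)
  pairs <- utils::combn(ch$channel_id, 2L)
  out <- apply(pairs, 2L, function(p) {
    x <- values[, p[1L]]
    y <- values[, p[2L]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) stop("fewer than 3 common elements between ", p[1L], " and ", p[2L])
    c(n_common = sum(ok), r_squared = stats::cor(log10(x[ok]), log10(y[ok]))^2)
  })
  data.frame(channel_a = pairs[1L, ], channel_b = pairs[2L, ],
             n_common = as.integer(out["n_common", ]),
             r_squared = unname(out["r_squared", ]),
             stringsAsFactors = FALSE)
}

#' Full TMT enrichment-ranking analysis
#'
#' The complete bait-enrichment branch for one 10-plex TMT experiment:
#' decoy/contaminant removal, the unique-peptide filter, the
#' negative-control ratio cutoff, normalized enrichment against each
#' spatial reference, per-reference and overall ranks, and the top-n
#' overlap defining the high-confidence set.
#'
#' @param table a raw [quant_table()].
#' @param design a [channel_design()].
#' @param min_unique unique-peptide threshold (default 2).
#' @param cutoff negative-control ratio cutoff (default 2).
#' @param top_n depth of the per-reference lists (default 200).
#' @param stage optional stage restriction.
#' @param center centering statistic for ratio normalization.
#' @return List with `counts` (detected, biotinylated, high_confidence),
#'   `ranks` (the full rank table with normalized fold changes merged in),
#'   `high_confidence` (character vector), and `correlations` for the
#'   bait replicates.
#' @export
tmt_rank_analysis <- function(table, design, min_unique = 2L, cutoff = 2,
                              top_n = 200L, stage = NULL, center = "median") {
  detected <- filter_unique_peptides(filter_decoys_contaminants(table), min_unique)
  biotinylated <- negative_control_filter(detected, design, cutoff, stage)
  ratios <- enrichment_ratios(detected, design, biotinylated, stage, center)
  ranks <- overall_rank(rank_per_reference(ratios))
  hc <- top_n_overlap(ranks, top_n)
  fc <- as.data.frame(ratios)
  names(fc) <- paste0("norm_log2_fc_", names(fc))
  fc$protein_id <- rownames(ratios)
  ranks <- merge(ranks, fc, by = "protein_id", sort = FALSE)
  ranks <- ranks[order(ranks$overall_rank), , drop = FALSE]
  rownames(ranks) <- NULL
  corr <- replicate_correlation(detected, design, "NFASC", stage)
  list(
    counts = c(detected = nrow(detected),
               biotinylated = length(biotinylated),
               high_confidence = length(hc)),
    ranks = ranks,
    high_confidence = hc,
    correlations = corr
  )
}
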