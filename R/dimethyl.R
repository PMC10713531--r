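#' A dimethyl labeling experiment pair
#'
#' One heavy/light comparison (heavy = the NFASC bait sample, light = a
#' control or reference sample) measured in independent replicates. Each
#' replicate is a [quant_table()] of kind `hl_ratio` with a single channel
#' holding the per-protein H/L ratio.
#'
#' @param label one of `"NFASC_vs_no1Ab"`, `"NFASC_vs_NeuN"`,
#'   `"NFASC_vs_MAP2"`.
#' @param replicates list of `hl_ratio` [quant_table()]s (normally 3).
#' @return An object of class `dimethyl_pair`.
#' @export
dimethyl_pair <- function(label = c("NFASC_vs_no1Ab", "NFASC_vs_NeuN", "NFASC_vs_MAP2"),
                          replicates) {
  label <- match.arg(label)
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  for (r in replicates) {
    if (!inherits(r, "quant_table")) stop("each replicate must be a quant_table")
    if (value_kind(r) != "hl_ratio") stop("replicates must have value_kind 'hl_ratio'")
    if (length(channel_names(r)) != 1L) {
      stop("each hl_ratio replicate must carry exactly one value column")
    }
  }
  structure(list(label = label, replicates = replicates), class = "dimethyl_pair")
}

# per-replicate H/L ratios after decoy and unique-peptide prefilters,
# assembled into an id x replicate matrix keyed by leading accession
pair_ratio_matrix <- function(pair, min_unique = 2L) {
  cleaned <- lapply(pair$replicates, function(r) {
    r <- filter_unique_peptides(filter_decoys_contaminants(r), min_unique)
    cv <- channel_values(r)
    v <- stats::setNames(cv[, 1L], rownames(cv))
    v[!duplicated(names(v))]
  })
  ids <- sort(unique(unlist(lapply(cleaned, names))))
  m <- vapply(cleaned, function(v) unname(v[ids]), numeric(length(ids)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(ids))
  rownames(m) <- ids
  m
}

#' Replicate-coverage filter for a dimethyl pair
#'
#' Keeps proteins whose H/L ratio is quantified (non-missing) in at least
#' `min_quantified` replicates, after removing decoys/contaminants and
#' protein groups with fewer than `min_unique` unique peptides.
#'
#' @param pair a [dimethyl_pair()].
#' @param min_quantified minimum number of replicates with a quantified
#'   ratio (default 2 of 3).
#' @param min_unique unique-peptide threshold applied first (default 2).
#' @return Character vector of leading accessions passing the filter.
#' @export
replicate_coverage_filter <- function(pair, min_quantified = 2L, min_unique = 2L) {
  m <- pair_ratio_matrix(pair, min_unique)
  rownames(m)[rowSums(!is.na(m)) >= min_quantified]
}

#' Negative-control cutoff for the no-primary-antibody dimethyl pair
#'
#' In the bait-versus-no-primary-antibody comparison, true biotinylated
#' proteins must show H/L strictly above `threshold` in every replicate in
#' which they are quantified, and be quantified in at least
#' `min_quantified` replicates.
#'
#' @param pair a [dimethyl_pair()] with label `"NFASC_vs_no1Ab"`.
#' @param threshold H/L cutoff (default 1.5).
#' @param min_quantified,min_unique as in [replicate_coverage_filter()].
#' @return Character vector of leading accessions passing the cutoff.
#' @export
negative_pair_cutoff <- function(pair, threshold = 1.5, min_quantified = 2L,
                                 min_unique = 2L) {
  if (pair$label != "NFASC_vs_no1Ab") {
    stop("negative_pair_cutoff applies to the NFASC_vs_no1Ab pair")
  }
  m <- pair_ratio_matrix(pair, min_unique)
  covered <- rowSums(!is.na(m)) >= min_quantified
  all_pass <- apply(m, 1L, function(v) all(v[!is.na(v)] > threshold))
  rownames(m)[covered & all_pass]
}

#' Three-way intersection of per-pair protein sets
#'
#' @param ids_no1Ab,ids_neun,ids_map2 character vectors of leading
#'   accessions from the three pair filters.
#' @return Character vector: proteins present in all three sets.
#' @export
intersect_pairs <- function(ids_no1Ab, ids_neun, ids_map2) {
  Reduce(intersect, list(ids_no1Ab, ids_neun, ids_map2))
}

#' Center a column of log2 ratios on its median (or mean)
#'
#' Ratio normalization: subtracting the column's median log-ratio places
#' the bulk of unenriched proteins at zero. Missing values are preserved;
#' the transformation is a constant shift, so relative differences are
#' unchanged. Infinite sentinels (proteins undetected in the denominator)
#' are ignored when locating the center and pass through unchanged.
#'
#' @param x numeric vector of log2 ratios (may contain `NA` and `Inf`).
#' @param center `"median"` (default; linear interpolation for even
#'   counts) or `"mean"`.
#' @return The centered vector.
#' @export
median_center_log_ratios <- function(x, center = c("median", "mean")) {
  center <- match.arg(center)
  finite <- x[is.finite(x)]
  if (length(finite) == 0L) stop("cannot center a column with no finite values")
  shift <- if (center == "median") stats::median(finite) else mean(finite)
  ifelse(is.finite(x), x - shift, x)
}

#' Replicate-averaged normalized log2 H/L ratios for a dimethyl pair
#'
#' For each replicate, log2-transforms the H/L ratios (restricted to `ids`
#' when given), centers the column on its median, and averages the
#' centered values across replicates, ignoring missing replicates.
#' Proteins with no quantified replicate are excluded from the result.
#'
#' @param pair a [dimethyl_pair()].
#' @param ids optional character vector restricting (and ordering) the
#'   proteins; centering is computed over this set.
#' @param min_unique unique-peptide prefilter threshold.
#' @param center passed to [median_center_log_ratios()].
#' @return Data frame with columns `protein_id` and `avg_norm_log2`.
#' @export
average_normalized_ratios <- function(pair, ids = NULL, min_unique = 2L,
                                      center = "median") {
  m <- pair_ratio_matrix(pair, min_unique)
  if (!is.null(ids)) {
    m <- m[intersect(ids, rownames(m)), , drop = FALSE]
  }
  lm2 <- log2(m)
  centered <- apply(lm2, 2L, median_center_log_ratios, center = center)
  if (is.null(dim(centered))) centered <- matrix(centered, nrow = nrow(m),
                                                 dimnames = dimnames(m))
  avg <- rowMeans(centered, na.rm = TRUE)
  keep <- rowSums(!is.na(centered)) > 0L
  data.frame(protein_id = rownames(m)[keep], avg_norm_log2 = unname(avg[keep]),
             stringsAsFactors = FALSE)
}

#' Full dimethyl pair analysis
#'
#' Runs the complete ratiometric branch: per-pair replicate-coverage
#' filters on the two reference pairs, the H/L cutoff on the
#' no-primary-antibody pair, the three-way intersection, and — over the
#' intersected set — median-centered, replicate-averaged log2 H/L against
#' each reference.
#'
#' @param pair_no1Ab,pair_neun,pair_map2 the three [dimethyl_pair()]s.
#' @param threshold H/L cutoff for the negative pair (default 1.5).
#' @param min_quantified,min_unique filter parameters.
#' @param center centering statistic, see [median_center_log_ratios()].
#' @return List with `ids` (per-pair and intersected sets), `counts`, and
#'   `result`: a data frame `protein_id`, `avg_norm_log2_neun`,
#'   `avg_norm_log2_map2`.
#' @export
dimethyl_analysis <- function(pair_no1Ab, pair_neun, pair_map2,
                              threshold = 1.5, min_quantified = 2L,
                              min_unique = 2L, center = "median") {
  ids_no1Ab <- negative_pair_cutoff(pair_no1Ab, threshold, min_quantified, min_unique)
  ids_neun <- replicate_coverage_filter(pair_neun, min_quantified, min_unique)
  ids_map2 <- replicate_coverage_filter(pair_map2, min_quantified, min_unique)
  common <- intersect_pairs(ids_no1Ab, ids_neun, ids_map2)
  neun <- average_normalized_ratios(pair_neun, common, min_unique, center)
  map2 <- average_normalized_ratios(pair_map2, common, min_unique, center)
  result <- merge(neun, map2, by = "protein_id", suffixes = c("_neun", "_map2"))
  names(result) <- c("protein_id", "avg_norm_log2_neun", "avg_norm_log2_map2")
  result <- result[order(result$protein_id), , drop = FALSE]
  rownames(result) <- NULL
  list(
    ids = list(no1Ab = ids_no1Ab, NeuN = ids_neun, MAP2 = ids_map2,
               common = common),
    counts = c(no1Ab = length(ids_no1Ab), NeuN = length(ids_neun),
               MAP2 = length(ids_map2), common = length(common)),
    result = result
  )
}
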