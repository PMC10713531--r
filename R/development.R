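#' Stage-specific negative-control filter on the log2 scale
#'
#' For one developmental stage, a protein passes if the mean over the bait
#' (NFASC) replicate channels of log2(bait) - log2(no-primary-antibody)
#' strictly exceeds the stage threshold. The defaults reflect the
#' endogenous-biotin background distribution at each stage: 3.5 for DIV7
#' and DIV21, 1 for DIV14. Proteins detected in the bait but missing in
#' the negative are retained; proteins with no bait signal are dropped.
#'
#' @param table a [quant_table()] (already decoy/peptide filtered).
#' @param design a [channel_design()] covering the stage.
#' @param stage stage name (`"DIV7"`, `"DIV14"`, `"DIV21"`).
#' @param threshold log2-difference cutoff; default chosen by stage.
#' @return Character vector of leading accessions passing the filter.
#' @export
stage_negative_filter <- function(table, design, stage,
                                  threshold = if (stage == "DIV14") 1 else 3.5) {
  pos_ch <- design_channels(design, stage = stage, condition = "NFASC")$channel_id
  neg_ch <- design_channels(design, stage = stage,
                            condition = c("no_primary_antibody", "no_BP"))$channel_id
  if (length(pos_ch) == 0L || length(neg_ch) == 0L) {
    stop("design lacks bait or negative channels for stage ", stage)
  }
  values <- channel_values(table)
  pos <- log2(values[, pos_ch, drop = FALSE])
  neg <- rowMeans(log2(values[, neg_ch, drop = FALSE]), na.rm = TRUE)
  detected <- rowSums(!is.na(pos)) > 0L
  # bait-only detections are retained regardless of the threshold
  neg_missing <- is.nan(neg) | is.na(neg)
  diff_mean <- rowMeans(pos - neg, na.rm = TRUE)
  pass <- detected & (neg_missing | (!is.nan(diff_mean) & diff_mean > threshold))
  rownames(values)[pass]
}

#' Intersection of biotinylated-protein sets across stages and experiments
#'
#' @param ... character vectors of leading accessions (one per stage or
#'   experiment, including any prior independent dataset).
#' @return Character vector: proteins present in every input set.
#' @export
cross_stage_intersection <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]])) sets <- sets[[1L]]
  Reduce(intersect, sets)
}

#' Anchor-protein (PCCA) normalization of bait channels
#'
#' Endogenously biotinylated carboxylases such as PCCA are captured in
#' every channel independent of targeted labeling, making them internal
#' anchors for cross-channel and cross-experiment comparability. Every
#' bait (NFASC) channel is rescaled so the anchor's value equals 1 in that
#' channel; within-channel relative ratios are unchanged and the operation
#' is idempotent.
#'
#' @param table a [quant_table()].
#' @param design a [channel_design()].
#' @param anchor_id leading accession of the anchor protein (default
#'   `"P14882"`, rat PCCA).
#' @return The normalized [quant_table()] (only bait channels rescaled).
#' @export
pcca_normalize <- function(table, design, anchor_id = "P14882") {
  values <- channel_values(table)
  idx <- match(anchor_id, rownames(values))
  if (is.na(idx)) stop("anchor protein ", anchor_id, " not found in table")
  pos_ch <- design_channels(design, condition = "NFASC")$channel_id
  anchor <- values[idx, pos_ch]
  if (anyNA(anchor)) {
    stop("anchor protein ", anchor_id, " is not quantified in channel(s): ",
         paste(pos_ch[is.na(anchor)], collapse = ", "))
  }
  values[, pos_ch] <- sweep(values[, pos_ch, drop = FALSE], 2L, anchor, "/")
  qt_set_values(table, values)
}

#' Per-stage mean normalized bait abundance
#'
#' Averages the (anchor-normalized) bait channels of each stage, pooling
#' channels across bridged experiments when a stage appears in both.
#'
#' @param tables list of [quant_table()]s (one per TMT experiment),
#'   already anchor-normalized.
#' @param designs list of matching [channel_design()]s.
#' @param ids proteins to profile (leading accessions).
#' @return Numeric matrix, rows = `ids`, columns = stages in
#'   chronological order.
#' @export
stage_profiles <- function(tables, designs, ids) {
  stopifnot(length(tables) == length(designs))
  stages <- unique(unlist(lapply(designs, function(d) {
    design_channels(d, condition = "NFASC")$stage
  })))
  stages <- stages[order(as.numeric(sub("DIV", "", stages)))]
  out <- matrix(NA_real_, length(ids), length(stages),
                dimnames = list(ids, stages))
  for (stage in stages) {
    cols <- list()
    for (i in seq_along(tables)) {
      ch <- design_channels(designs[[i]], stage = stage, condition = "NFASC")$channel_id
      if (length(ch) == 0L) next
      v <- channel_values(tables[[i]])
      v <- v[intersect(ids, rownames(v)), ch, drop = FALSE]
      m <- matrix(NA_real_, length(ids), ncol(v), dimnames = list(ids, NULL))
      m[rownames(v), ] <- v
      cols <- c(cols, list(m))
    }
    pooled <- do.call(cbind, cols)
    out[, stage] <- rowMeans(pooled, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Filter for proteins changing across development
#'
#' Keeps proteins whose stage means change by more than `min_change`
#' (relative) between at least one pair of stages, i.e. whose max/min
#' pairwise ratio strictly exceeds `1 + min_change`. Proteins with a
#' missing or non-positive stage mean are excluded with a warning.
#'
#' @param profiles matrix from [stage_profiles()].
#' @param min_change minimum relative change (default 0.20).
#' @return Character vector of changing proteins.
#' @export
change_filter <- function(profiles, min_change = 0.20) {
  bad <- apply(profiles, 1L, function(v) any(is.na(v) | v <= 0))
  if (any(bad)) {
    warning(sum(bad), " protein(s) with missing or non-positive stage means excluded")
  }
  ok <- profiles[!bad, , drop = FALSE]
  ratio <- apply(ok, 1L, function(v) max(v) / min(v))
  rownames(ok)[ratio > 1 + min_change]
}

#' Z-scored developmental profiles
#'
#' Standardizes each protein's stage means to mean 0 and population
#' (divide-by-n) standard deviation 1 across the stages, so profiles are
#' compared by shape rather than absolute abundance. Constant profiles
#' map to all-zero z-scores.
#'
#' @param profiles matrix from [stage_profiles()].
#' @return Matrix of the same shape holding z-scores.
#' @export
zscore_profiles <- function(profiles) {
  t(apply(profiles, 1L, function(v) {
    mu <- mean(v)
    sd_pop <- sqrt(mean((v - mu)^2))
    if (sd_pop == 0) rep(0, length(v)) else (v - mu) / sd_pop
  }))
}

#' Cluster developmental profiles
#'
#' Agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage by default — the defaults of the heatmap tooling this mirrors)
#' of z-scored profiles, with the tree cut into exactly `k` clusters.
#' Cluster ids are relabeled 1..k by descending cluster size (ties by
#' original dendrogram label) so cluster 1 is always the largest.
#'
#' @param zscores matrix from [zscore_profiles()].
#' @param k number of clusters (default 6).
#' @param method linkage method passed to [stats::hclust()].
#' @param dist_method distance passed to [stats::dist()].
#' @return Named integer vector of cluster ids (names = protein ids).
#' @export
cluster_profiles <- function(zscores, k = 6L, method = "complete",
                             dist_method = "euclidean") {
  if (k > nrow(zscores)) {
    stop("k = ", k, " exceeds the number of profiles (", nrow(zscores), ")")
  }
  hc <- stats::hclust(stats::dist(zscores, method = dist_method), method = method)
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  relabel <- order(-as.integer(sizes), as.integer(names(sizes)))
  map <- integer(k)
  map[as.integer(names(sizes))[relabel]] <- seq_len(k)
  out <- map[raw]
  names(out) <- rownames(zscores)
  out
}

#' Cluster sizes, fractions and trend labels
#'
#' Summarizes each cluster by its share of the clustered proteins and a
#' trend label derived from the cluster's mean z-profile: `up` / `down`
#' for monotone profiles, `peaked` / `dipped` when the middle stage is the
#' extremum.
#'
#' @param assignments integer vector from [cluster_profiles()].
#' @param zscores the matching z-score matrix.
#' @return Data frame with `cluster`, `n`, `fraction_pct`, `trend`, and
#'   one `mean_z_<stage>` column per stage.
#' @export
cluster_fraction_summary <- function(assignments, zscores) {
  stopifnot(length(assignments) == nrow(zscores))
  ks <- sort(unique(assignments))
  rows <- lapply(ks, function(kk) {
    sub <- zscores[assignments == kk, , drop = FALSE]
    m <- colMeans(sub)
    trend <- if (all(diff(m) >= 0)) "up"
      else if (all(diff(m) <= 0)) "down"
      else if (which.max(m) == 2L) "peaked"
      else "dipped"
    out <- data.frame(cluster = kk, n = nrow(sub),
                      fraction_pct = 100 * nrow(sub) / length(assignments),
                      trend = trend, stringsAsFactors = FALSE)
    for (j in seq_along(m)) out[[paste0("mean_z_", colnames(zscores)[j])]] <- m[j]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential abundance between two stages (volcano statistics)
#'
#' For each protein, the log2 fold change of mean anchor-normalized bait
#' intensity between two stages and an unpaired two-tailed Student
#' (pooled-variance) t-test on the log2 values. Replicates are pooled
#' across bridged experiments for stages present in both. Calls follow
#' the conventional volcano cutoffs: `up` if log2 FC > `fc_cutoff` and
#' p < `alpha`, `down` if log2 FC < -`fc_cutoff` and p < `alpha`,
#' otherwise `ns`.
#'
#' @param tables,designs anchor-normalized experiments as in
#'   [stage_profiles()].
#' @param ids proteins to test.
#' @param stage_a,stage_b the two stages; fold change is stage_b over
#'   stage_a.
#' @param fc_cutoff log2 fold-change cutoff (default 1).
#' @param alpha p-value cutoff (default 0.05).
#' @return Data frame with `protein_id`, `log2_fc`, `p_value`, `call`.
#' @export
volcano_stats <- function(tables, designs, ids, stage_a, stage_b,
                          fc_cutoff = 1, alpha = 0.05) {
  gather <- function(stage) {
    cols <- list()
    for (i in seq_along(tables)) {
      ch <- design_channels(designs[[i]], stage = stage, condition = "NFASC")$channel_id
      if (length(ch) == 0L) next
      v <- channel_values(tables[[i]])
      m <- matrix(NA_real_, length(ids), length(ch), dimnames = list(ids, NULL))
      keep <- intersect(ids, rownames(v))
      m[keep, ] <- v[keep, ch, drop = FALSE]
      cols <- c(cols, list(m))
    }
    do.call(cbind, cols)
  }
  a <- gather(stage_a)
  b <- gather(stage_b)
  res <- lapply(ids, function(id) {
    xa <- log2(a[id, ][!is.na(a[id, ])])
    xb <- log2(b[id, ][!is.na(b[id, ])])
    if (length(xa) < 2L || length(xb) < 2L) {
      return(data.frame(protein_id = id, log2_fc = NA_real_, p_value = NA_real_,
                        call = "ns", stringsAsFactors = FALSE))
    }
    fc <- mean(xb) - mean(xa)
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      if (fc == 0) {
        p <- 1
      } else {
        warning("zero variance with unequal means for ", id,
                "; p set to the smallest positive value")
        p <- .Machine$double.xmin
      }
    } else {
      p <- stats::t.test(xb, xa, var.equal = TRUE)$p.value
    }
    data.frame(protein_id = id, log2_fc = fc, p_value = p, call = "ns",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$call[!is.na(out$p_value) & out$p_value < alpha & out$log2_fc > fc_cutoff] <- "up"
  out$call[!is.na(out$p_value) & out$p_value < alpha & out$log2_fc < -fc_cutoff] <- "down"
  rownames(out) <- NULL
  out
}

#' Full developmental-dynamics analysis over two bridged TMT experiments
#'
#' Runs the complete developmental branch: per-stage negative filters,
#' the cross-stage intersection (optionally including an independent prior
#' DIV14 set), anchor normalization, the relative-change filter, z-scored
#' profile clustering with fraction/trend summaries, and volcano
#' statistics for every stage pair.
#'
#' @param tmt1,tmt2 raw [quant_table()]s for the two experiments.
#' @param designs list of two [channel_design()]s (see [stage_design()]).
#' @param prior_div14 optional character vector: biotinylated proteins
#'   from an independent DIV14 experiment to include in the intersection.
#' @param anchor_id anchor accession for [pcca_normalize()].
#' @param min_unique,min_change,k,fc_cutoff,alpha tuning parameters with
#'   the pipeline defaults.
#' @return List with `counts`, `ids`, `profiles`, `zscores`,
#'   `assignments`, `cluster_summary`, and `volcano` (one data frame per
#'   stage pair).
#' @export
development_analysis <- function(tmt1, tmt2, designs = stage_design(),
                                 prior_div14 = NULL, anchor_id = "P14882",
                                 min_unique = 2L, min_change = 0.20, k = 6L,
                                 fc_cutoff = 1, alpha = 0.05) {
  clean <- function(x) filter_unique_peptides(filter_decoys_contaminants(x), min_unique)
  t1 <- clean(tmt1)
  t2 <- clean(tmt2)
  ids_div7 <- stage_negative_filter(t1, designs[[1L]], "DIV7")
  ids_div14_1 <- stage_negative_filter(t1, designs[[1L]], "DIV14")
  ids_div21 <- stage_negative_filter(t2, designs[[2L]], "DIV21")
  ids_div14_2 <- stage_negative_filter(t2, designs[[2L]], "DIV14")
  sets <- list(ids_div7, ids_div14_1, ids_div14_2, ids_div21)
  if (!is.null(prior_div14)) sets <- c(sets, list(prior_div14))
  common <- cross_stage_intersection(sets)
  n1 <- pcca_normalize(t1, designs[[1L]], anchor_id)
  n2 <- pcca_normalize(t2, designs[[2L]], anchor_id)
  profiles <- stage_profiles(list(n1, n2), designs, common)
  changing <- suppressWarnings(change_filter(profiles, min_change))
  z <- zscore_profiles(profiles[changing, , drop = FALSE])
  assignments <- cluster_profiles(z, k = k)
  summary <- cluster_fraction_summary(assignments, z)
  stages <- colnames(profiles)
  pairs <- utils::combn(stages, 2L)
  volcano <- lapply(seq_len(ncol(pairs)), function(j) {
    volcano_stats(list(n1, n2), designs, changing, pairs[1L, j], pairs[2L, j],
                  fc_cutoff, alpha)
  })
  names(volcano) <- apply(pairs, 2L, paste, collapse = "_vs_")
  list(
    counts = c(DIV7 = length(ids_div7), DIV14_tmt1 = length(ids_div14_1),
               DIV14_tmt2 = length(ids_div14_2), DIV21 = length(ids_div21),
               common = length(common), changing = length(changing)),
    ids = list(DIV7 = ids_div7, DIV14_tmt1 = ids_div14_1,
               DIV14_tmt2 = ids_div14_2, DIV21 = ids_div21, common = common,
               changing = changing),
    profiles = profiles, zscores = z, assignments = assignments,
    cluster_summary = summary, volcano = volcano
  )
}
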