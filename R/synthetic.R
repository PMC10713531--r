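#' Specification of a synthetic proximity-labeling proteome
#'
#' Describes the planted composition of a synthetic proteinGroups-style
#' table: log-normal background proteins, AIS proteins enriched in the
#' bait channels, compartment-reference-enriched proteins, endogenously
#' biotinylated proteins present in every channel (the first of which is
#' the PCCA anchor), and decoy/contaminant rows. Defaults match the
#' planted-signal conditions used throughout the test suite: 2000
#' background proteins, 20 AIS proteins at 8-fold bait enrichment,
#' log2-scale channel noise SD 0.25.
#'
#' @param n_background number of unenriched background proteins.
#' @param n_ais number of planted AIS proteins.
#' @param n_reference_enriched named integer vector: planted
#'   compartment-enriched proteins per reference condition.
#' @param n_endogenous_biotin endogenously biotinylated proteins (>= 1;
#'   includes the PCCA anchor).
#' @param ais_enrichment_fold bait-channel enrichment of AIS proteins
#'   over references (> 1).
#' @param reference_enrichment_fold enrichment of compartment proteins in
#'   their own reference channels.
#' @param negative_background_fraction fraction of a protein's labeled
#'   signal leaking into the negative-control channels.
#' @param log2_noise_sd per-channel multiplicative noise SD on the log2
#'   scale.
#' @param missing_rate probability that a channel value drops to missing.
#' @param n_contaminant_decoys flagged contaminant/reverse rows appended.
#' @param seed integer seed making every generator a pure function of the
#'   spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_background = 2000L, n_ais = 20L,
                           n_reference_enriched = c(NeuN = 50L, MAP2 = 50L, SMI312 = 50L),
                           n_endogenous_biotin = 10L,
                           ais_enrichment_fold = 8,
                           reference_enrichment_fold = 4,
                           negative_background_fraction = 0.05,
                           log2_noise_sd = 0.25,
                           missing_rate = 0.02,
                           n_contaminant_decoys = 20L,
                           seed = 1L) {
  counts <- c(n_background, n_ais, n_reference_enriched, n_endogenous_biotin,
              n_contaminant_decoys)
  if (any(counts < 0)) stop("all category counts must be non-negative")
  if (n_endogenous_biotin < 1L) stop("n_endogenous_biotin must be >= 1 (the anchor)")
  if (ais_enrichment_fold <= 1) stop("ais_enrichment_fold must exceed 1")
  if (negative_background_fraction <= 0 || negative_background_fraction >= 1) {
    stop("negative_background_fraction must lie in (0, 1)")
  }
  if (log2_noise_sd < 0) stop("log2_noise_sd must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  structure(list(n_background = as.integer(n_background),
                 n_ais = as.integer(n_ais),
                 n_reference_enriched = n_reference_enriched,
                 n_endogenous_biotin = as.integer(n_endogenous_biotin),
                 ais_enrichment_fold = ais_enrichment_fold,
                 reference_enrichment_fold = reference_enrichment_fold,
                 negative_background_fraction = negative_background_fraction,
                 log2_noise_sd = log2_noise_sd,
                 missing_rate = missing_rate,
                 n_contaminant_decoys = as.integer(n_contaminant_decoys),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# planted protein roster: accession, gene, category (and owning reference)
synthetic_roster <- function(spec) {
  cat <- c(rep("background", spec$n_background),
           rep("ais", spec$n_ais),
           rep(paste0("reference_", names(spec$n_reference_enriched)),
               spec$n_reference_enriched),
           rep("endogenous_biotin", spec$n_endogenous_biotin),
           rep("decoy", spec$n_contaminant_decoys))
  n <- length(cat)
  id <- sprintf("SYN%05d", seq_len(n))
  # the anchor carries the canonical PCCA accession so default configs work
  anchor <- which(cat == "endogenous_biotin")[1L]
  if (!is.na(anchor)) id[anchor] <- "P14882"
  data.frame(protein_group_id = id,
             gene_name = ifelse(id == "P14882", "Pcca",
                                paste0("Gene", seq_len(n))),
             category = cat, stringsAsFactors = FALSE)
}

# per-protein relative signal in a channel of the given condition.
# Labeled channels see compartment-dependent enrichment. Negative-control
# channels capture non-specifically adsorbed proteins (background, decoys)
# and endogenously biotinylated proteins at full strength, but only a leak
# fraction of genuinely labeled (AIS / compartment-enriched) signal.
channel_effect <- function(category, condition, spec) {
  leak <- spec$negative_background_fraction
  vapply(category, function(cat) {
    if (cat %in% c("endogenous_biotin", "background", "decoy")) return(1)
    if (condition %in% c("no_primary_antibody", "no_BP")) {
      # leak from the protein's bait-channel signal level
      leak * (if (cat == "ais") spec$ais_enrichment_fold else 1)
    } else if (cat == "ais") {
      if (condition == "NFASC") spec$ais_enrichment_fold else 1
    } else {
      # reference_<cond> proteins are boosted in their own compartment
      if (condition == sub("^reference_", "", cat)) spec$reference_enrichment_fold else 1
    }
  }, numeric(1L), USE.NAMES = FALSE)
}

# base abundance draw: log-normal, log10 mean 6 sd 0.8
draw_base <- function(n) 10^stats::rnorm(n, mean = 6, sd = 0.8)

apply_noise_missing <- function(values, spec) {
  noise <- matrix(2^stats::rnorm(length(values), 0, spec$log2_noise_sd),
                  nrow = nrow(values))
  values <- values * noise
  if (spec$missing_rate > 0) {
    drop <- matrix(stats::runif(length(values)) < spec$missing_rate,
                   nrow = nrow(values))
    values[drop] <- NA_real_
  }
  values
}

#' Generate a synthetic 10-plex TMT proteinGroups table with ground truth
#'
#' Draws a log-normal base abundance per protein, applies per-channel
#' multiplicative condition effects (bait enrichment for AIS proteins,
#' compartment enrichment for reference proteins, leak-only signal in the
#' negative controls, flat signal for endogenously biotinylated proteins),
#' log-normal channel noise and random missingness, and flags decoy rows.
#' Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param design a [channel_design()] (default [div14_design()]).
#' @return List with `table` (a [quant_table()]) and `truth` (data frame
#'   with `protein_id`, `category`).
#' @export
generate_tmt_table <- function(spec, design = div14_design()) {
  set.seed(spec$seed)
  roster <- synthetic_roster(spec)
  n <- nrow(roster)
  base <- draw_base(n)
  ch <- design$channels
  values <- vapply(seq_len(nrow(ch)), function(j) {
    base * channel_effect(roster$category, ch$condition[j], spec)
  }, numeric(n))
  values <- apply_noise_missing(values, spec)
  colnames(values) <- ch$channel_id
  decoy <- roster$category == "decoy"
  # half the decoy rows are contaminants, half reverse hits
  is_contaminant <- decoy & (seq_len(n) %% 2L == 0L)
  meta <- data.frame(
    protein_group_id = roster$protein_group_id,
    gene_name = roster$gene_name,
    # a sprinkling of one-peptide identifications exercises the peptide filter
    unique_peptides = ifelse(roster$category == "background" & seq_len(n) %% 17L == 0L,
                             1L, 2L + seq_len(n) %% 5L),
    is_contaminant = is_contaminant,
    is_reverse = decoy & !is_contaminant,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(protein_id = leading_accession(roster$protein_group_id),
                      category = roster$category, stringsAsFactors = FALSE)
  list(table = quant_table(meta, values), truth = truth)
}

#' Generate synthetic dimethyl H/L pairs with ground truth
#'
#' Builds the three heavy/light comparisons (bait vs no-primary-antibody,
#' vs NeuN, vs MAP2) from the same planted structure as
#' [generate_tmt_table()]: each replicate's H/L ratio is the ratio of the
#' bait-channel to the control-channel signal under independent log-normal
#' noise, with missingness applied per replicate.
#'
#' @param spec a [synthetic_spec()].
#' @param n_replicates replicates per pair (default 3).
#' @return List with `pairs` (named list of [dimethyl_pair()]s) and
#'   `truth`.
#' @export
generate_dimethyl_pairs <- function(spec, n_replicates = 3L) {
  set.seed(spec$seed)
  roster <- synthetic_roster(spec)
  n <- nrow(roster)
  decoy <- roster$category == "decoy"
  is_contaminant <- decoy & (seq_len(n) %% 2L == 0L)
  meta <- data.frame(
    protein_group_id = roster$protein_group_id,
    gene_name = roster$gene_name,
    unique_peptides = ifelse(roster$category == "background" & seq_len(n) %% 17L == 0L,
                             1L, 2L + seq_len(n) %% 5L),
    is_contaminant = is_contaminant,
    is_reverse = decoy & !is_contaminant,
    stringsAsFactors = FALSE
  )
  controls <- c(NFASC_vs_no1Ab = "no_primary_antibody",
                NFASC_vs_NeuN = "NeuN", NFASC_vs_MAP2 = "MAP2")
  heavy <- channel_effect(roster$category, "NFASC", spec)
  pairs <- lapply(names(controls), function(label) {
    light <- channel_effect(roster$category, controls[[label]], spec)
    reps <- lapply(seq_len(n_replicates), function(i) {
      ratio <- (heavy / light) *
        2^stats::rnorm(n, 0, spec$log2_noise_sd * sqrt(2))
      if (spec$missing_rate > 0) {
        ratio[stats::runif(n) < spec$missing_rate] <- NA_real_
      }
      quant_table(meta, matrix(ratio, ncol = 1L,
                               dimnames = list(NULL, "Ratio H/L")),
                  value_kind = "hl_ratio")
    })
    dimethyl_pair(label, reps)
  })
  names(pairs) <- names(controls)
  truth <- data.frame(protein_id = leading_accession(roster$protein_group_id),
                      category = roster$category, stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth)
}

#' Planted developmental trend templates
#'
#' Six stage-multiplier templates (DIV7, DIV14, DIV21) with distinct
#' shapes: gradual up, gradual down, DIV14 peak, DIV14 dip, late onset,
#' early onset.
#'
#' @return Named list of length-3 numeric multiplier vectors.
#' @export
trend_templates <- function() {
  list(up = c(1, 2, 4), down = c(4, 2, 1), peak14 = c(1, 4, 1),
       dip14 = c(4, 1, 4), late = c(1, 1, 4), early = c(4, 4, 1))
}

#' Generate two bridged developmental TMT experiments with ground truth
#'
#' Emulates the bridged design: experiment 1 carries DIV7 + DIV14,
#' experiment 2 carries DIV21 + DIV14 (the bridge stage). Background and
#' AIS proteins are assigned stage-multiplier trends (round-robin over
#' `trends` for AIS proteins, flat for others unless overridden); the
#' endogenously biotinylated anchor stays constant across stages up to
#' noise.
#'
#' @param spec a [synthetic_spec()].
#' @param trends named list of stage multipliers (default
#'   [trend_templates()]) cycled over the planted AIS proteins.
#' @param designs list of two [channel_design()]s (default
#'   [stage_design()]).
#' @return List with `tables` (two [quant_table()]s), `designs`, and
#'   `truth` (with the assigned trend per protein).
#' @export
generate_stage_series <- function(spec, trends = trend_templates(),
                                  designs = stage_design()) {
  set.seed(spec$seed)
  roster <- synthetic_roster(spec)
  n <- nrow(roster)
  base <- draw_base(n)
  stages <- c("DIV7", "DIV14", "DIV21")
  trend_name <- rep("flat", n)
  ais_idx <- which(roster$category == "ais")
  trend_name[ais_idx] <- names(trends)[(seq_along(ais_idx) - 1L) %% length(trends) + 1L]
  mult <- matrix(1, n, 3L, dimnames = list(NULL, stages))
  for (tn in names(trends)) {
    hit <- trend_name == tn
    if (any(hit)) mult[hit, ] <- matrix(trends[[tn]], sum(hit), 3L, byrow = TRUE)
  }
  decoy <- roster$category == "decoy"
  is_contaminant <- decoy & (seq_len(n) %% 2L == 0L)
  meta <- data.frame(
    protein_group_id = roster$protein_group_id,
    gene_name = roster$gene_name,
    unique_peptides = 2L + seq_len(n) %% 5L,
    is_contaminant = is_contaminant,
    is_reverse = decoy & !is_contaminant,
    stringsAsFactors = FALSE
  )
  build <- function(design) {
    ch <- design$channels
    values <- vapply(seq_len(nrow(ch)), function(j) {
      stage_mult <- mult[, ch$stage[j]]
      # the anchor (and all endogenous-biotin rows) ignores stage trends
      stage_mult[roster$category == "endogenous_biotin"] <- 1
      base * stage_mult * channel_effect(roster$category, ch$condition[j], spec)
    }, numeric(n))
    values <- apply_noise_missing(values, spec)
    # the anchor must be quantified everywhere to serve as the anchor
    a <- which(roster$protein_group_id == "P14882")
    values[a, is.na(values[a, ])] <- base[a]
    colnames(values) <- ch$channel_id
    quant_table(meta, values)
  }
  tables <- lapply(designs, build)
  truth <- data.frame(protein_id = leading_accession(roster$protein_group_id),
                      category = roster$category, trend = trend_name,
                      stringsAsFactors = FALSE)
  list(tables = tables, designs = designs, truth = truth)
}
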