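# shared fixture builders: all fixtures are constructed in code

# minimal quant_table with explicit channel values
toy_table <- function(values, ids = NULL, peptides = NULL,
                      contaminant = FALSE, reverse = FALSE,
                      genes = NULL, value_kind = "reporter_intensity") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  if (is.null(peptides)) peptides <- rep(3L, n)
  if (is.null(genes)) genes <- paste0("gene", seq_len(n))
  meta <- data.frame(protein_group_id = ids, gene_name = genes,
                     unique_peptides = peptides,
                     is_contaminant = rep_len(contaminant, n),
                     is_reverse = rep_len(reverse, n),
                     stringsAsFactors = FALSE)
  quant_table(meta, values, value_kind = value_kind)
}

# single-channel H/L table for a dimethyl replicate
toy_hl <- function(ratios, ids = NULL, peptides = NULL,
                   contaminant = FALSE, reverse = FALSE) {
  toy_table(matrix(ratios, ncol = 1L, dimnames = list(NULL, "HL")),
            ids = ids, peptides = peptides, contaminant = contaminant,
            reverse = reverse, value_kind = "hl_ratio")
}

toy_dimethyl_pair <- function(label, ratio_matrix, ids = NULL, ...) {
  ratio_matrix <- as.matrix(ratio_matrix)
  dimethyl_pair(label, lapply(seq_len(ncol(ratio_matrix)), function(j) {
    toy_hl(ratio_matrix[, j], ids = ids, ...)
  }))
}

# brute-force descending rank oracle: position in an explicit sort
oracle_rank_desc <- function(x, ids) {
  ord <- order(-x, ids)
  r <- integer(length(x))
  for (pos in seq_along(ord)) r[ord[pos]] <- pos
  r
}

# two partitions agree perfectly iff their contingency table is a
# permutation matrix (one non-empty cell per row and column)
partitions_identical <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# write a 10-channel proteinGroups-style TSV for the DIV14 design
write_toy_protein_groups <- function(path, n = 3L, design = div14_design(),
                                     zero_cell = NULL) {
  set.seed(99)
  vals <- matrix(round(runif(n * 10L, 100, 1000)), n, 10L)
  if (!is.null(zero_cell)) vals[zero_cell[1L], zero_cell[2L]] <- 0
  df <- data.frame(check.names = FALSE,
                   `Protein IDs` = sprintf("Q%05d;Q%05d-2", seq_len(n), seq_len(n)),
                   `Gene names` = paste0("G", seq_len(n)),
                   `Unique peptides` = rep(3L, n),
                   `Potential contaminant` = "",
                   `Reverse` = "")
  vals_df <- as.data.frame(vals)
  names(vals_df) <- design$channels$column
  utils::write.table(cbind(df, vals_df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  vals
}
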