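#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated proteinGroups export into a [quant_table()],
#' pulling one value column per channel declared in the design. Reporter
#' intensities of 0 (MaxQuant's convention for an undetected reporter) and
#' empty cells become `NA`. Metadata column names follow the design's
#' `columns` mapping, so non-default export dialects are supported.
#'
#' @param path path to the tab-separated file.
#' @param design a [channel_design()]; its `column` field names the value
#'   column for each channel.
#' @param value_kind `"reporter_intensity"` (zeros are missing) or
#'   `"hl_ratio"` (only empty/NaN is missing).
#' @return A [quant_table()] with rows in file order.
#' @export
read_protein_groups <- function(path, design,
                                value_kind = c("reporter_intensity", "hl_ratio")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "NaN", ""))
  cols <- design$columns
  required <- unlist(cols[c("id", "unique_peptides")], use.names = FALSE)
  value_cols <- design$channels$column
  missing_cols <- setdiff(c(required, value_cols), names(raw))
  if (length(missing_cols) > 0L) {
    stop("required column(s) absent from ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))
  }
  flag <- function(colname) {
    if (!colname %in% names(raw)) return(rep(FALSE, nrow(raw)))
    v <- raw[[colname]]
    !is.na(v) & v %in% c("+", "TRUE", "True", "true", "1", "yes")
  }
  meta <- data.frame(
    protein_group_id = as.character(raw[[cols$id]]),
    gene_name = if (cols$gene %in% names(raw)) {
      ifelse(is.na(raw[[cols$gene]]), "", as.character(raw[[cols$gene]]))
    } else "",
    unique_peptides = as.integer(raw[[cols$unique_peptides]]),
    is_contaminant = flag(cols$contaminant),
    is_reverse = flag(cols$reverse),
    stringsAsFactors = FALSE
  )
  values <- as.matrix(raw[, value_cols, drop = FALSE])
  storage.mode(values) <- "double"
  if (value_kind == "reporter_intensity") {
    values[!is.na(values) & values == 0] <- NA_real_
  }
  values[is.nan(values)] <- NA_real_
  colnames(values) <- design$channels$channel_id
  quant_table(meta, values, value_kind = value_kind)
}

#' Read a proteinGroups table carrying a single H/L ratio column
#'
#' Convenience reader for dimethyl-labeling exports: like
#' [read_protein_groups()] but pulling one heavy/light ratio column.
#' `NaN` and empty cells (a protein not quantified in that replicate)
#' become `NA`.
#'
#' @param path path to the tab-separated file.
#' @param ratio_column name of the H/L ratio column (default
#'   `"Ratio H/L"`).
#' @param columns metadata column-name overrides as in [channel_design()].
#' @return A [quant_table()] of kind `hl_ratio` with one channel.
#' @export
read_hl_table <- function(path, ratio_column = "Ratio H/L", columns = list()) {
  ch <- data.frame(channel_id = "HL", condition = "NFASC", role = "positive",
                   stage = NA_character_, replicate_index = 1L,
                   column = ratio_column, stringsAsFactors = FALSE)
  # a one-channel design cannot satisfy the full design invariants, so the
  # reader assembles the table directly
  design <- structure(list(
    channels = ch,
    columns = utils::modifyList(
      list(id = "Protein IDs", gene = "Gene names",
           unique_peptides = "Unique peptides",
           contaminant = "Potential contaminant", reverse = "Reverse"),
      as.list(columns))
  ), class = "channel_design")
  read_protein_groups(path, design, value_kind = "hl_ratio")
}

#' Remove contaminant and reverse-decoy protein groups
#'
#' Drops rows flagged as potential contaminants or as reverse (decoy) hits.
#' Row order is preserved; the filter is idempotent.
#'
#' @param table a [quant_table()].
#' @return The filtered [quant_table()].
#' @export
filter_decoys_contaminants <- function(table) {
  qt_subset(table, !table$is_contaminant & !table$is_reverse)
}

#' Keep protein groups with enough unique peptides
#'
#' @param table a [quant_table()].
#' @param min_unique minimum number of unique peptides (default 2, the
#'   standard identification-confidence threshold).
#' @return The filtered [quant_table()].
#' @export
filter_unique_peptides <- function(table, min_unique = 2L) {
  if (min_unique < 0) stop("min_unique must be non-negative")
  qt_subset(table, table$unique_peptides >= min_unique)
}

#' Write a result table as tab-separated text
#'
#' Values round-trip bit-exactly for text-representable fields:
#' numerics are written with full precision (17 significant digits).
#'
#' @param table a data frame (or `quant_table`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8"),
    error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e))
  )
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path input path.
#' @return A data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), fileEncoding = "UTF-8")
}

#' Write a quant_table in the proteinGroups dialect
#'
#' Inverse of [read_protein_groups()]: metadata columns take the design's
#' column names, channel columns the design's `column` names, missing
#' reporter intensities are written as 0 and missing H/L ratios as `NaN`,
#' matching the MaxQuant conventions.
#'
#' @param table a [quant_table()].
#' @param design the matching [channel_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, design, path) {
  cols <- design$columns
  values <- channel_values(table)
  fill <- if (value_kind(table) == "reporter_intensity") 0 else NaN
  values[is.na(values)] <- fill
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    table$protein_group_id, table$gene_name,
                    table$unique_peptides,
                    ifelse(table$is_contaminant, "+", ""),
                    ifelse(table$is_reverse, "+", ""))
  names(out) <- unlist(cols[c("id", "gene", "unique_peptides",
                              "contaminant", "reverse")], use.names = FALSE)
  out <- cbind(out, as.data.frame(values, optional = TRUE))
  names(out)[-(1:5)] <- design$channels$column
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
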