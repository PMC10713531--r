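#' Protein-group quantification table
#'
#' A `quant_table` is a data frame with one row per protein group, carrying
#' the metadata columns `protein_group_id`, `gene_name`, `unique_peptides`,
#' `is_contaminant`, `is_reverse`, followed by one numeric column per
#' quantification channel. Undetected values are `NA` (MaxQuant emits 0 for
#' undetected reporter channels; those are converted to `NA` on read).
#'
#' @param meta data frame with the five metadata columns described above.
#' @param values numeric matrix (rows = proteins, columns = channels) or a
#'   data frame of channel columns.
#' @param channel_names character vector of channel identifiers; defaults to
#'   the column names of `values`.
#' @param value_kind `"reporter_intensity"` or `"hl_ratio"`.
#'
#' @return An object of class `quant_table` (a data frame).
#' @export
quant_table <- function(meta, values, channel_names = colnames(values),
                        value_kind = c("reporter_intensity", "hl_ratio")) {
  value_kind <- match.arg(value_kind)
  meta_cols <- c("protein_group_id", "gene_name", "unique_peptides",
                 "is_contaminant", "is_reverse")
  missing_cols <- setdiff(meta_cols, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  values <- as.matrix(values)
  if (is.null(channel_names)) {
    stop("channel_names must be supplied when `values` has no column names")
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (ncol(values) != length(channel_names)) {
    stop("`values` has ", ncol(values), " columns but ",
         length(channel_names), " channel names were given")
  }
  if (nrow(meta) != nrow(values)) stop("meta and values disagree on row count")
  if (any(!is.na(values) & values < 0)) stop("channel values must be non-negative")
  if (any(!nzchar(meta$protein_group_id))) stop("protein_group_id must be non-empty")
  storage.mode(values) <- "double"
  colnames(values) <- channel_names
  out <- cbind(meta[meta_cols], as.data.frame(values, optional = TRUE))
  rownames(out) <- NULL
  structure(out,
            channel_names = channel_names,
            value_kind = value_kind,
            class = c("quant_table", "data.frame"))
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d protein groups x %d channels (%s)\n",
              nrow(x), length(channel_names(x)), value_kind(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Channel identifiers of a quant_table
#' @param x a `quant_table`.
#' @return Character vector of channel names.
#' @export
channel_names <- function(x) attr(x, "channel_names")

#' Value kind of a quant_table
#' @param x a `quant_table`.
#' @return `"reporter_intensity"` or `"hl_ratio"`.
#' @export
value_kind <- function(x) attr(x, "value_kind")

#' Channel value matrix of a quant_table
#' @param x a `quant_table`.
#' @return Numeric matrix, rows = protein groups, columns = channels,
#'   rownames = leading accessions.
#' @export
channel_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[, channel_names(x), drop = FALSE])
  rownames(m) <- leading_accession(x$protein_group_id)
  m
}

# subset rows of a quant_table, preserving class and attributes
qt_subset <- function(x, keep) {
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            channel_names = channel_names(x),
            value_kind = value_kind(x),
            class = c("quant_table", "data.frame"))
}

# replace the channel value matrix, preserving everything else
qt_set_values <- function(x, values) {
  stopifnot(nrow(values) == nrow(x))
  out <- as.data.frame(x)
  out[, channel_names(x)] <- values
  structure(out,
            channel_names = channel_names(x),
            value_kind = value_kind(x),
            class = c("quant_table", "data.frame"))
}

#' Leading accession of semicolon-joined protein group identifiers
#'
#' Protein-group memberships drift between database searches; the first
#' (leading) accession is the stable key used for all set operations across
#' tables.
#'
#' @param ids character vector of protein group identifiers.
#' @return Character vector of leading accessions.
#' @export
leading_accession <- function(ids) {
  sub(";.*$", "", as.character(ids))
}

#' Channel design: mapping of channels to conditions, roles and stages
#'
#' Declares, for each quantification channel, the biological condition
#' (`NFASC` bait, `no_primary_antibody` / `no_BP` negatives, `NeuN` /
#' `MAP2` / `SMI312` spatial references), its role, the developmental stage
#' and the replicate index. One condition must be the positive bait
#' (`NFASC`); at least one negative control is required; reference
#' conditions are drawn from NeuN (soma), MAP2 (somatodendrites) and
#' SMI312 (axon).
#'
#' @param channels data frame with columns `channel_id`, `condition`,
#'   `role`, `stage`, `replicate_index`, and optionally `column` (the name
#'   of the value column in the proteinGroups file; defaults to
#'   `"Reporter intensity corrected <i>"` in channel order).
#' @param columns named list overriding metadata column names in the
#'   proteinGroups dialect; recognized names: `id`, `gene`,
#'   `unique_peptides`, `contaminant`, `reverse`.
#'
#' @return An object of class `channel_design`.
#' @export
channel_design <- function(channels, columns = list()) {
  channels <- as.data.frame(channels)
  required <- c("channel_id", "condition", "role", "stage", "replicate_index")
  missing_cols <- setdiff(required, names(channels))
  if (length(missing_cols) > 0L) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  conditions <- c("NFASC", "no_primary_antibody", "no_BP", "NeuN", "MAP2", "SMI312")
  roles <- c("positive", "negative", "reference")
  bad <- setdiff(unique(channels$condition), conditions)
  if (length(bad) > 0L) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(channels$role), roles)
  if (length(bad) > 0L) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(channels$channel_id)) {
    stop("duplicate channel mapping: ",
         paste(unique(channels$channel_id[duplicated(channels$channel_id)]),
               collapse = ", "))
  }
  pos <- unique(channels$condition[channels$role == "positive"])
  if (!identical(pos, "NFASC")) {
    stop("exactly one positive condition (NFASC) is required")
  }
  if (!any(channels$role == "negative")) stop("at least one negative condition is required")
  refs <- unique(channels$condition[channels$role == "reference"])
  bad <- setdiff(refs, c("NeuN", "MAP2", "SMI312"))
  if (length(bad) > 0L) stop("invalid reference condition(s): ", paste(bad, collapse = ", "))
  channels$stage[is.na(channels$stage)] <- NA_character_
  if (is.null(channels$column)) {
    channels$column <- paste("Reporter intensity corrected", seq_len(nrow(channels)))
  }
  defaults <- list(id = "Protein IDs", gene = "Gene names",
                   unique_peptides = "Unique peptides",
                   contaminant = "Potential contaminant", reverse = "Reverse")
  columns <- utils::modifyList(defaults, as.list(columns))
  rownames(channels) <- NULL
  structure(list(channels = channels, columns = columns),
            class = "channel_design")
}

#' @export
print.channel_design <- function(x, ...) {
  cat("channel_design with", nrow(x$channels), "channels\n")
  print(x$channels)
  invisible(x)
}

#' Read a channel design from a YAML or JSON config file
#'
#' @param path file path; format is chosen by extension (`.yaml`/`.yml`
#'   parsed with yaml, `.json` with jsonlite).
#' @return A [channel_design()].
#' @export
read_channel_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ch <- cfg$channels
  if (is.null(ch)) stop("design file has no `channels` entry")
  if (!is.data.frame(ch)) {
    ch <- do.call(rbind, lapply(ch, function(row) {
      as.data.frame(row[c("channel_id", "condition", "role", "stage",
                          "replicate_index", "column")[
        c("channel_id", "condition", "role", "stage",
          "replicate_index", "column") %in% names(row)]])
    }))
  }
  channel_design(ch, columns = if (is.null(cfg$columns)) list() else cfg$columns)
}

#' Write a channel design to a YAML config file
#' @param design a [channel_design()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_channel_design <- function(design, path) {
  ch <- design$channels
  yaml::write_yaml(list(
    columns = design$columns,
    channels = lapply(seq_len(nrow(ch)), function(i) as.list(ch[i, ]))
  ), path)
  invisible(path)
}

#' Standard 10-plex TMT design for the DIV14 AIS experiment
#'
#' Three NFASC (bait) channels, one no-primary-antibody and one
#' no-biotin-phenol negative, one NeuN (soma), two MAP2 (somatodendrite)
#' and two SMI312 (axon) reference channels, all at DIV14.
#'
#' @param channel_ids optional character vector of 10 channel identifiers.
#' @return A [channel_design()].
#' @export
div14_design <- function(channel_ids = NULL) {
  ch <- data.frame(
    condition = c("NFASC", "NFASC", "NFASC", "no_primary_antibody", "no_BP",
                  "NeuN", "MAP2", "MAP2", "SMI312", "SMI312"),
    role = c("positive", "positive", "positive", "negative", "negative",
             "reference", "reference", "reference", "reference", "reference"),
    stage = "DIV14",
    replicate_index = c(1L, 2L, 3L, 1L, 1L, 1L, 1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  ch$channel_id <- if (is.null(channel_ids)) {
    paste0(ch$condition, "_", ch$replicate_index)
  } else channel_ids
  channel_design(ch)
}

#' Bridged two-experiment design for the developmental TMT series
#'
#' Two parallel 10-plex experiments share DIV14 as the bridge: TMT1 carries
#' DIV7 + DIV14, TMT2 carries DIV21 + DIV14. Each stage contributes two
#' NFASC channels, a no-primary-antibody negative, and NeuN and MAP2
#' references.
#'
#' @return List of two [channel_design()] objects named `TMT1` and `TMT2`.
#' @export
stage_design <- function() {
  one_stage <- function(stage) {
    data.frame(
      condition = c("NFASC", "NFASC", "no_primary_antibody", "NeuN", "MAP2"),
      role = c("positive", "positive", "negative", "reference", "reference"),
      stage = stage,
      replicate_index = c(1L, 2L, 1L, 1L, 1L),
      stringsAsFactors = FALSE
    )
  }
  mk <- function(stages) {
    ch <- rbind(one_stage(stages[1]), one_stage(stages[2]))
    ch$channel_id <- paste0(ch$condition, "_", ch$stage, "_", ch$replicate_index)
    channel_design(ch)
  }
  list(TMT1 = mk(c("DIV7", "DIV14")), TMT2 = mk(c("DIV21", "DIV14")))
}

# design channels restricted to a stage (NA stage matches everything)
design_channels <- function(design, stage = NULL, condition = NULL, role = NULL) {
  ch <- design$channels
  if (!is.null(stage)) ch <- ch[!is.na(ch$stage) & ch$stage == stage, , drop = FALSE]
  if (!is.null(condition)) ch <- ch[ch$condition %in% condition, , drop = FALSE]
  if (!is.null(role)) ch <- ch[ch$role %in% role, , drop = FALSE]
  ch
}
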