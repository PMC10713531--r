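#' Run a declared analysis from a config file
#'
#' Single entry point wiring the modules into the pipeline's analyses.
#' The config (YAML or a list) declares the analysis, its inputs and any
#' parameter overrides; all thresholds default to the pipeline values
#' (H/L cutoff 1.5, negative ratio cutoff 2, stage log2 cutoffs 3.5/1,
#' top-200 overlap, 20% change, k = 6 clusters, volcano cutoffs at
#' log2 FC +-1 and p 0.05). Result tables are written under
#' `output_dir` and a machine-readable run summary is returned (and
#' written as JSON).
#'
#' Config fields by analysis:
#' \describe{
#'   \item{`simulate`}{`spec` (overrides for [synthetic_spec()]); writes a
#'     proteinGroups-dialect TSV, the matching design YAML and a
#'     truth-labels TSV.}
#'   \item{`tmt_rank`}{`input` (proteinGroups TSV), `design` (YAML);
#'     params `min_unique`, `cutoff`, `top_n`, `center`.}
#'   \item{`dimethyl`}{`pairs`: named lists `no1Ab`, `NeuN`, `MAP2` of
#'     replicate TSV paths; params `threshold`, `min_quantified`,
#'     `min_unique`, `ratio_column`.}
#'   \item{`development`}{`input_tmt1`, `input_tmt2`, optional
#'     `design_tmt1`/`design_tmt2`, optional `prior_div14` (text file of
#'     accessions); params `anchor_id`, `min_change`, `k`, `fc_cutoff`,
#'     `alpha`.}
#'   \item{`imaging`}{`regions` (CSV with columns `metric`
#'     in `specificity`/`polarity`, `ais_mean`, `ais_bg`, `other_mean`,
#'     `other_bg`) and/or `profiles` (CSV with `profile_id`, `position`,
#'     `intensity`, `pixel_size_nm`).}
#' }
#'
#' @param config path to a YAML config or an equivalent named list.
#' @param seed integer seed applied before any randomized step; defaults
#'   to the config's `seed` (or 1).
#' @param verbose if `TRUE`, log progress to stderr.
#' @return A `run_summary` list: `analysis`, `parameters`, `counts`,
#'   `inputs` (MD5 digests), `outputs`, `seed`.
#' @export
run_analysis <- function(config, seed = NULL, verbose = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  analysis <- config$analysis
  if (is.null(analysis) ||
      !analysis %in% c("simulate", "tmt_rank", "dimethyl", "development", "imaging")) {
    stop("config must declare `analysis` as one of simulate, tmt_rank, ",
         "dimethyl, development, imaging")
  }
  seed <- as.integer(if (!is.null(seed)) seed else if (!is.null(config$seed)) config$seed else 1L)
  out_dir <- if (is.null(config$output_dir)) "." else config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (verbose) message("[proxirank] ", ...)
  # fail on missing inputs before any computation
  declared_inputs <- as.character(unlist(
    config[intersect(c("input", "design", "input_tmt1", "input_tmt2",
                       "design_tmt1", "design_tmt2", "prior_div14",
                       "regions", "profiles", "pairs"), names(config))],
    use.names = FALSE))
  absent <- declared_inputs[!file.exists(declared_inputs)]
  if (length(absent) > 0L) stop("input file(s) not found: ", paste(absent, collapse = ", "))
  set.seed(seed)
  params <- if (is.null(config$params)) list() else config$params
  log_msg("running analysis: ", analysis)
  runner <- switch(analysis,
                   simulate = run_simulate, tmt_rank = run_tmt_rank,
                   dimethyl = run_dimethyl, development = run_development,
                   imaging = run_imaging)
  res <- runner(config, params, out_dir, seed)
  summary <- structure(list(analysis = analysis,
                            parameters = res$parameters,
                            counts = res$counts,
                            inputs = input_digests(declared_inputs),
                            outputs = res$outputs,
                            seed = seed),
                       class = "run_summary")
  validate_count_chain(summary)
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(unclass(summary), summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_msg("wrote ", summary_path)
  summary
}

input_digests <- function(paths) {
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

# filter chains must only shrink; a violation means a wiring bug
validate_count_chain <- function(summary) {
  chains <- list(c("detected", "biotinylated", "high_confidence"),
                 c("common", "changing"))
  for (chain in chains) {
    present <- chain[chain %in% names(summary$counts)]
    if (length(present) >= 2L) {
      v <- unlist(summary$counts[present])
      if (any(diff(v) > 0)) {
        stop("filter counts are not non-increasing: ",
             paste(present, v, sep = "=", collapse = ", "))
      }
    }
  }
  invisible(summary)
}

merge_params <- function(defaults, params) {
  utils::modifyList(defaults, params[names(params) %in% names(defaults)])
}

run_simulate <- function(config, params, out_dir, seed) {
  spec_args <- if (is.null(config$spec)) list() else config$spec
  spec_args$seed <- seed
  spec <- do.call(synthetic_spec, spec_args)
  design <- div14_design()
  gen <- generate_tmt_table(spec, design)
  paths <- file.path(out_dir, c("proteinGroups.txt", "design.yaml", "truth.tsv"))
  write_protein_groups(gen$table, design, paths[1L])
  write_channel_design(design, paths[2L])
  write_table(gen$truth, paths[3L])
  list(parameters = unclass(spec),
       counts = list(n_proteins = nrow(gen$table)),
       outputs = as.list(paths))
}

run_tmt_rank <- function(config, params, out_dir, seed) {
  p <- merge_params(list(min_unique = 2L, cutoff = 2, top_n = 200L,
                         center = "median"), params)
  design <- read_channel_design(config$design)
  table <- read_protein_groups(config$input, design)
  res <- tmt_rank_analysis(table, design, min_unique = p$min_unique,
                           cutoff = p$cutoff, top_n = p$top_n,
                           center = p$center)
  paths <- c(ranks = file.path(out_dir, "rank_table.tsv"),
             hc = file.path(out_dir, "high_confidence.txt"),
             corr = file.path(out_dir, "replicate_correlation.json"))
  write_table(res$ranks, paths["ranks"])
  writeLines(res$high_confidence, paths["hc"])
  jsonlite::write_json(res$correlations, paths["corr"], digits = NA)
  list(parameters = p, counts = as.list(res$counts), outputs = as.list(paths))
}

run_dimethyl <- function(config, params, out_dir, seed) {
  p <- merge_params(list(threshold = 1.5, min_quantified = 2L, min_unique = 2L,
                         center = "median", ratio_column = "Ratio H/L"), params)
  read_pair <- function(label, paths) {
    dimethyl_pair(label, lapply(paths, read_hl_table, ratio_column = p$ratio_column))
  }
  res <- dimethyl_analysis(
    read_pair("NFASC_vs_no1Ab", config$pairs$no1Ab),
    read_pair("NFASC_vs_NeuN", config$pairs$NeuN),
    read_pair("NFASC_vs_MAP2", config$pairs$MAP2),
    threshold = p$threshold, min_quantified = p$min_quantified,
    min_unique = p$min_unique, center = p$center)
  paths <- c(scatter = file.path(out_dir, "dimethyl_enrichment.tsv"),
             ids = file.path(out_dir, "dimethyl_ids.txt"),
             venn = file.path(out_dir, "venn_counts.json"))
  write_table(res$result, paths["scatter"])
  writeLines(res$ids$common, paths["ids"])
  venn <- list(no1Ab = length(res$ids$no1Ab), NeuN = length(res$ids$NeuN),
               MAP2 = length(res$ids$MAP2),
               no1Ab_NeuN = length(intersect(res$ids$no1Ab, res$ids$NeuN)),
               no1Ab_MAP2 = length(intersect(res$ids$no1Ab, res$ids$MAP2)),
               NeuN_MAP2 = length(intersect(res$ids$NeuN, res$ids$MAP2)),
               triple = length(res$ids$common))
  jsonlite::write_json(venn, paths["venn"], auto_unbox = TRUE)
  list(parameters = p, counts = as.list(res$counts), outputs = as.list(paths))
}

run_development <- function(config, params, out_dir, seed) {
  p <- merge_params(list(anchor_id = "P14882", min_unique = 2L,
                         min_change = 0.20, k = 6L, fc_cutoff = 1,
                         alpha = 0.05), params)
  designs <- if (!is.null(config$design_tmt1)) {
    list(read_channel_design(config$design_tmt1),
         read_channel_design(config$design_tmt2))
  } else {
    stage_design()
  }
  tmt1 <- read_protein_groups(config$input_tmt1, designs[[1L]])
  tmt2 <- read_protein_groups(config$input_tmt2, designs[[2L]])
  prior <- if (!is.null(config$prior_div14)) readLines(config$prior_div14) else NULL
  res <- development_analysis(tmt1, tmt2, designs, prior_div14 = prior,
                              anchor_id = p$anchor_id, min_unique = p$min_unique,
                              min_change = p$min_change, k = p$k,
                              fc_cutoff = p$fc_cutoff, alpha = p$alpha)
  clusters <- data.frame(protein_id = names(res$assignments),
                         cluster = unname(res$assignments),
                         stringsAsFactors = FALSE)
  paths <- c(clusters = file.path(out_dir, "cluster_assignments.tsv"),
             fractions = file.path(out_dir, "cluster_fractions.json"),
             common = file.path(out_dir, "common_proteins.txt"))
  write_table(cbind(clusters, as.data.frame(res$zscores[clusters$protein_id, ])),
              paths["clusters"])
  jsonlite::write_json(res$cluster_summary, paths["fractions"], digits = NA)
  writeLines(res$ids$common, paths["common"])
  volcano_paths <- vapply(names(res$volcano), function(nm) {
    path <- file.path(out_dir, paste0("volcano_", nm, ".tsv"))
    write_table(res$volcano[[nm]], path)
    path
  }, character(1L))
  list(parameters = p, counts = as.list(res$counts),
       outputs = c(as.list(paths), as.list(volcano_paths)))
}

run_imaging <- function(config, params, out_dir, seed) {
  outputs <- list()
  counts <- list()
  if (!is.null(config$regions)) {
    reg <- utils::read.csv(config$regions, stringsAsFactors = FALSE)
    reg$value <- vapply(seq_len(nrow(reg)), function(i) {
      fn <- switch(reg$metric[i], specificity = specificity_ratio,
                   polarity = polarity_index,
                   stop("unknown imaging metric: ", reg$metric[i]))
      fn(reg$ais_mean[i], reg$ais_bg[i], reg$other_mean[i], reg$other_bg[i])
    }, numeric(1L))
    groups <- split(reg$value, reg$metric)
    summary <- do.call(rbind, lapply(names(groups), function(g) {
      s <- group_mean_sem(groups[[g]])
      data.frame(metric = g, n = s["n"], mean = s["mean"], sem = s["sem"])
    }))
    path <- file.path(out_dir, "region_metrics.tsv")
    write_table(reg, path)
    spath <- file.path(out_dir, "region_summary.tsv")
    write_table(summary, spath)
    outputs <- c(outputs, list(regions = path, region_summary = spath))
    counts$n_regions <- nrow(reg)
  }
  if (!is.null(config$profiles)) {
    prof <- utils::read.csv(config$profiles, stringsAsFactors = FALSE)
    per <- lapply(split(prof, prof$profile_id), function(d) {
      d <- d[order(d$position), ]
      res <- periodicity(d$intensity, d$pixel_size_nm[1L])
      data.frame(profile_id = d$profile_id[1L],
                 mean_spacing_nm = res$mean_spacing_nm,
                 n_peaks = res$n_peaks)
    })
    per <- do.call(rbind, per)
    s <- group_mean_sem(per$mean_spacing_nm)
    path <- file.path(out_dir, "periodicity.tsv")
    write_table(per, path)
    outputs <- c(outputs, list(periodicity = path))
    counts$n_profiles <- nrow(per)
    counts$mean_periodicity_nm <- unname(s["mean"])
  }
  list(parameters = params, counts = counts, outputs = outputs)
}

#' Recompute the published filter-chain counts from deposited tables
#'
#' Runs the three analysis branches with their default thresholds against
#' locally deposited MaxQuant exports and returns every filter-chain
#' count. The deposited files are not shipped with the package; place
#' them under `dir` with these names (all tab-separated proteinGroups
#' dialect):
#' \itemize{
#'   \item `div14_proteinGroups.txt` + `div14_design.yaml`
#'   \item `dimethyl_<pair>_rep<i>.txt` for pair in `no1Ab`, `NeuN`,
#'     `MAP2` and i in 1..3 (each with a `Ratio H/L` column)
#'   \item `dev_tmt1_proteinGroups.txt`, `dev_tmt2_proteinGroups.txt`
#'     (+ optional `dev_tmt1_design.yaml`, `dev_tmt2_design.yaml`)
#' }
#'
#' @param dir directory holding the deposited tables.
#' @return Named list of counts (`detected`, `biotinylated`,
#'   `high_confidence`, `dimethyl_no1Ab`, `dimethyl_common`, `DIV7`,
#'   `DIV21`, `common`, `changing`, cluster fractions).
#' @export
reproduce_published_counts <- function(dir) {
  need <- file.path(dir, c("div14_proteinGroups.txt", "div14_design.yaml",
                           "dev_tmt1_proteinGroups.txt", "dev_tmt2_proteinGroups.txt",
                           t(outer(c("no1Ab", "NeuN", "MAP2"), 1:3,
                                   function(p, i) sprintf("dimethyl_%s_rep%d.txt", p, i)))))
  absent <- need[!file.exists(need)]
  if (length(absent) > 0L) {
    stop("deposited table(s) not found under ", dir, ": ",
         paste(basename(absent), collapse = ", "))
  }
  design <- read_channel_design(file.path(dir, "div14_design.yaml"))
  tmt <- tmt_rank_analysis(read_protein_groups(file.path(dir, "div14_proteinGroups.txt"),
                                               design), design)
  pair <- function(p) {
    dimethyl_pair(paste0("NFASC_vs_", p),
                  lapply(sprintf(file.path(dir, "dimethyl_%s_rep%d.txt"), p, 1:3),
                         read_hl_table))
  }
  dm <- dimethyl_analysis(pair("no1Ab"), pair("NeuN"), pair("MAP2"))
  designs <- if (file.exists(file.path(dir, "dev_tmt1_design.yaml"))) {
    list(read_channel_design(file.path(dir, "dev_tmt1_design.yaml")),
         read_channel_design(file.path(dir, "dev_tmt2_design.yaml")))
  } else stage_design()
  dev <- development_analysis(
    read_protein_groups(file.path(dir, "dev_tmt1_proteinGroups.txt"), designs[[1L]]),
    read_protein_groups(file.path(dir, "dev_tmt2_proteinGroups.txt"), designs[[2L]]),
    designs, prior_div14 = tmt$ranks$protein_id)
  c(as.list(tmt$counts),
    list(dimethyl_no1Ab = unname(dm$counts["no1Ab"]),
         dimethyl_common = unname(dm$counts["common"])),
    as.list(dev$counts),
    list(cluster_fractions_pct = dev$cluster_summary$fraction_pct))
}
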