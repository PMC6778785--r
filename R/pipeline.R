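#' Load the packaged 96-strain marker table
#'
#' Returns the published per-strain summary table for the 96-strain pooled
#' experiment: strain name, number of strain-unique SNVs, average total
#' read coverage per unique SNV, the standard error of that coverage
#' (across all unique SNVs and all replicates), and the sequencing-derived
#' starvation-resistance trait value. The file ships with the package as a
#' versioned TSV and is integrity-checked on load.
#'
#' @return data frame with 96 rows and columns `strain, n_unique_snvs,
#'   avg_coverage, se_coverage, trait_value`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_strains.tsv", package = "poolselect",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (sum != "e4ccba2293d2dc1e39bc948a3a50d6df")
    stop("packaged strain table is corrupted (md5 mismatch: ", sum, ")")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 96L)
  df
}

#' Run the pooled-selection pipeline end to end
#'
#' Orchestrates the stages in dependency order -- simulate a pooled
#' experiment, identify strain-unique SNVs, infer per-library strain
#' frequencies, convert them to trait values, and optionally run the naive
#' marker scan -- writing each stage's TSV output plus a YAML run manifest
#' (seeds, input checksums and row counts per output) to `outdir`. Outputs
#' are a pure function of (inputs, config, seeds): re-running with the same
#' configuration reproduces byte-identical files.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognised fields: `outdir` (required), `stages` (subset of
#'   `c("simulate", "summarize", "frequencies", "traits", "scan")`, default
#'   all), `seed`, `sim` (list of [sim_config()] overrides), `count_table`
#'   (path to an existing count TSV, used instead of simulating),
#'   `min_total_reads`, `exclusions` (strains dropped from the exported
#'   trait file), `maf_min`, `replicate_day_map`.
#' @return (invisibly) the manifest, a named list also written to
#'   `manifest.yaml`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outdir))
  stages <- config$stages %||%
    c("simulate", "summarize", "frequencies", "traits", "scan")
  bad <- setdiff(stages, c("simulate", "summarize", "frequencies",
                           "traits", "scan"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "poolselect",
                   version = as.character(utils::packageVersion("poolselect")),
                   seed = config$seed %||% 1L,
                   stages = stages, outputs = list())
  emit <- function(name, df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs[[name]] <<- list(path = path, rows = nrow(df),
                                      md5 = unname(tools::md5sum(path)))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  panel <- NULL
  counts <- NULL
  map <- NULL
  if ("simulate" %in% stages) run_stage("simulate", {
    sc <- do.call(sim_config, utils::modifyList(
      list(seed = manifest$seed), config$sim %||% list()))
    truth <- simulate_frequency_trajectories(sc)
    counts <- simulate_count_table(truth, sc)
    panel <- sim_strain_panel(sc)
    emit("count_table", as.data.frame(counts),
         file.path(config$outdir, "counts.tsv"))
    truth_df <- data.frame(strain = sc$strains,
                           initial_frequency = sc$initial_frequencies,
                           mortality_rate = sc$mortality_rates,
                           recovery_weight = sc$recovery_weights,
                           true_trait_value = truth$true_trait_values,
                           stringsAsFactors = FALSE)
    emit("strain_truth", truth_df, file.path(config$outdir, "truth.tsv"))
  })
  if (!is.null(config$count_table)) run_stage("load-counts", {
    if (!file.exists(config$count_table))
      stop("count table not found: ", config$count_table)
    counts <- read_count_table(config$count_table)
    manifest$inputs$count_table <-
      list(path = config$count_table,
           md5 = unname(tools::md5sum(config$count_table)))
  })
  if (any(c("summarize", "frequencies", "traits", "scan") %in% stages)) {
    if (is.null(panel) && !is.null(config$vcf))
      panel <- run_stage("read-vcf", read_strain_panel_vcf(config$vcf))
    if (is.null(counts)) stop("no count table: enable 'simulate' or set count_table")
    map <- if (!is.null(panel))
      identify_unique_snvs(panel, config$missing_policy %||% "strict")
    else strain_column_map(counts)
  }
  if ("summarize" %in% stages) run_stage("summarize", {
    emit("marker_summary", strain_marker_summary(map, counts),
         file.path(config$outdir, "marker_summary.tsv"))
  })
  freqs <- NULL
  if (any(c("frequencies", "traits") %in% stages)) run_stage("frequencies", {
    freqs <- infer_frequencies(map, counts,
                               min_total_reads = config$min_total_reads %||% 1)
    emit("frequencies", freqs, file.path(config$outdir, "frequencies.tsv"))
  })
  traits <- NULL
  if ("traits" %in% stages) run_stage("traits", {
    traits <- compute_trait_values(freqs, config$replicate_day_map)
    emit("traits", traits, file.path(config$outdir, "traits.tsv"))
    exported <- export_gwas_traits(traits,
                                   exclusions = config$exclusions %||% character())
    emit("gwas_traits", exported[order(exported$strain), ],
         file.path(config$outdir, "gwas_traits.tsv"))
  })
  if ("scan" %in% stages) run_stage("scan", {
    if (is.null(panel)) stop("the scan stage needs a genotype panel")
    if (is.null(traits)) stop("the scan stage needs the traits stage")
    scan <- marker_scan(panel, traits,
                        maf_min = config$maf_min %||% 0.05)
    res <- scan$results
    res$note <- scan$note
    emit("scan", res, file.path(config$outdir, "scan.tsv"))
    manifest$scan <- list(n_markers_tested = scan$n_markers_tested,
                          bonferroni_line = scan$bonferroni_line)
  })
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  invisible(manifest)
}

#' Unique-SNV map from a pre-filtered count table
#'
#' A count table already restricted to strain-unique SNVs carries the
#' owning strain in its `strain` column; this rebuilds the variant-to-strain
#' map from that column so frequency inference can run without the
#' genotype panel the filtering came from.
#'
#' @param counts a `pooled_count_table` with a `strain` column.
#' @return a `unique_snv_map`.
#' @export
strain_column_map <- function(counts) {
  if (is.null(counts$strain))
    stop("count table has no 'strain' column and no panel was supplied")
  assignments <- data.frame(chrom = counts$chrom, pos = counts$pos,
                            ref = counts$ref, alt = counts$alt,
                            key = variant_key(counts$chrom, counts$pos,
                                              counts$ref, counts$alt),
                            strain = counts$strain, stringsAsFactors = FALSE)
  strains <- sort(unique(assignments$strain))
  per <- table(factor(assignments$strain, levels = strains))
  structure(list(assignments = assignments,
                 per_strain_count = stats::setNames(as.integer(per), strains)),
            class = "unique_snv_map")
}
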