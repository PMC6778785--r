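#' Construct a pooled count table
#'
#' A pooled count table stores, for each variant, reference- and
#' alternative-allele read counts in each sequencing library. A library is
#' one (biological replicate, day of L1 starvation) sample of the pooled
#' culture. The wide layout has one row per variant and a pair of columns
#' `<replicate>_<day>_ref` / `<replicate>_<day>_alt` per library, the layout
#' used on disk (see [write_count_table()]).
#'
#' @param variants data frame with columns `chrom, pos, ref, alt` (a
#'   `strain` column, if present, is carried through).
#' @param libraries data frame with columns `replicate`, `day`.
#' @param ref_counts,alt_counts numeric matrices, variants x libraries,
#'   non-negative. Non-integer values are allowed so that expectation-valued
#'   (noise-free) tables can be represented.
#' @return a data frame of class `pooled_count_table` with attribute
#'   `libraries`.
#' @export
pooled_count_table <- function(variants, libraries, ref_counts, alt_counts) {
  stop_if_not_cols(variants, c("chrom", "pos", "ref", "alt"), "variants")
  stop_if_not_cols(libraries, c("replicate", "day"), "libraries")
  ref_counts <- as.matrix(ref_counts)
  alt_counts <- as.matrix(alt_counts)
  if (!all(dim(ref_counts) == c(nrow(variants), nrow(libraries))) ||
      !all(dim(alt_counts) == dim(ref_counts)))
    stop("count matrices must be variants x libraries")
  if (min(ref_counts, alt_counts) < 0) stop("read counts must be non-negative")
  if (any(libraries$day < 0)) stop("days of starvation must be non-negative")
  lab <- library_label(libraries$replicate, libraries$day)
  if (anyDuplicated(lab)) stop("duplicated (replicate, day) libraries")
  out <- data.frame(chrom = as.character(variants$chrom),
                    pos = as.integer(variants$pos),
                    ref = as.character(variants$ref),
                    alt = as.character(variants$alt),
                    stringsAsFactors = FALSE)
  if (!is.null(variants$strain)) out$strain <- as.character(variants$strain)
  for (j in seq_along(lab)) {
    out[[paste0(lab[j], "_ref")]] <- ref_counts[, j]
    out[[paste0(lab[j], "_alt")]] <- alt_counts[, j]
  }
  attr(out, "libraries") <- data.frame(replicate = as.character(libraries$replicate),
                                       day = as.numeric(libraries$day),
                                       stringsAsFactors = FALSE)
  class(out) <- c("pooled_count_table", "data.frame")
  out
}

#' List the libraries of a count table
#'
#' @param counts a `pooled_count_table` (or any data frame using the
#'   `<replicate>_<day>_ref/alt` column convention).
#' @return data frame with columns `replicate` (character), `day` (numeric)
#'   and `label`.
#' @export
count_table_libraries <- function(counts) {
  libs <- attr(counts, "libraries")
  if (is.null(libs)) {
    m <- regmatches(names(counts),
                    regexec("^(.*)_([0-9]+(?:\\.[0-9]+)?)_(ref|alt)$",
                            names(counts)))
    hit <- lengths(m) == 4L
    if (!any(hit)) stop("no <replicate>_<day>_ref/alt columns found")
    parts <- do.call(rbind, m[hit])
    libs <- unique(data.frame(replicate = parts[, 2],
                              day = as.numeric(parts[, 3]),
                              stringsAsFactors = FALSE))
  }
  libs$label <- library_label(libs$replicate, libs$day)
  rownames(libs) <- NULL
  libs
}

#' Read / write pooled count tables as TSV
#'
#' Tab-separated, UTF-8, `.` decimal separator. Columns: `chrom`, `pos`,
#' `ref`, `alt`, optionally `strain`, then one `<replicate>_<day>_ref` /
#' `<replicate>_<day>_alt` pair per library.
#'
#' @param path file path.
#' @return `read_count_table` returns a `pooled_count_table`;
#'   `write_count_table` invisibly returns `path`.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if_not_cols(df, c("chrom", "pos", "ref", "alt"), basename(path))
  libs <- count_table_libraries(df)
  keep <- c("chrom", "pos", "ref", "alt", intersect("strain", names(df)))
  variants <- df[, keep, drop = FALSE]
  ref_counts <- as.matrix(df[, paste0(libs$label, "_ref"), drop = FALSE])
  alt_counts <- as.matrix(df[, paste0(libs$label, "_alt"), drop = FALSE])
  pooled_count_table(variants, libs[, c("replicate", "day")],
                     ref_counts, alt_counts)
}

#' @rdname read_count_table
#' @param counts a `pooled_count_table`.
#' @export
write_count_table <- function(counts, path) {
  df <- as.data.frame(counts)
  # deterministic row order: chrom, pos, alt
  df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a count table to strain-unique SNVs
#'
#' Drops count-table rows whose variant is not assigned to a strain in the
#' unique-SNV map, and annotates the remaining rows with the owning strain.
#'
#' @param counts a `pooled_count_table`.
#' @param map a `unique_snv_map` from [identify_unique_snvs()].
#' @return a `pooled_count_table` with a `strain` column.
#' @export
filter_to_unique_snvs <- function(counts, map) {
  stopifnot(inherits(map, "unique_snv_map"))
  libs <- count_table_libraries(counts)
  key <- variant_key(counts$chrom, counts$pos, counts$ref, counts$alt)
  idx <- match(key, map$assignments$key)
  keep <- !is.na(idx)
  variants <- data.frame(chrom = counts$chrom[keep], pos = counts$pos[keep],
                         ref = counts$ref[keep], alt = counts$alt[keep],
                         strain = map$assignments$strain[idx[keep]],
                         stringsAsFactors = FALSE)
  pooled_count_table(
    variants, libs[, c("replicate", "day")],
    as.matrix(as.data.frame(counts)[keep, paste0(libs$label, "_ref"), drop = FALSE]),
    as.matrix(as.data.frame(counts)[keep, paste0(libs$label, "_alt"), drop = FALSE])
  )
}

#' Per-strain marker and coverage summary
#'
#' For each strain, reports the number of strain-unique SNVs it owns, and
#' the mean and standard error of total read coverage (`ref + alt`) over all
#' of its unique SNVs and all libraries pooled (one observation per SNV per
#' library).
#'
#' @param map a `unique_snv_map`.
#' @param counts a `pooled_count_table` restricted to unique SNVs (rows for
#'   variants absent from `map` are dropped).
#' @return data frame `strain, n_unique_snvs, avg_coverage, se_coverage`.
#'   Strains with no unique SNV get `n_unique_snvs = 0` and `NA` coverage;
#'   a single coverage observation gives `se_coverage = NA`.
#' @export
strain_marker_summary <- function(map, counts) {
  stopifnot(inherits(map, "unique_snv_map"))
  counts <- filter_to_unique_snvs(counts, map)
  libs <- count_table_libraries(counts)
  cov <- as.matrix(as.data.frame(counts)[, paste0(libs$label, "_ref"), drop = FALSE]) +
    as.matrix(as.data.frame(counts)[, paste0(libs$label, "_alt"), drop = FALSE])
  strains <- names(map$per_strain_count)
  res <- data.frame(strain = strains,
                    n_unique_snvs = as.integer(map$per_strain_count),
                    avg_coverage = NA_real_, se_coverage = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(strains)) {
    obs <- as.vector(cov[counts$strain == strains[i], , drop = FALSE])
    if (length(obs) == 0L) next
    res$avg_coverage[i] <- mean(obs)
    if (length(obs) > 1L)
      res$se_coverage[i] <- stats::sd(obs) / sqrt(length(obs))
  }
  rownames(res) <- NULL
  res
}

#' Panel-level summaries of a strain marker table
#'
#' Summarises a per-strain marker table (as produced by
#' [strain_marker_summary()] or shipped in the packaged strain table, see
#' [load_table1_fixture()]): the median and quartiles of the per-strain
#' unique-SNV counts, the total number of unique SNVs, the number of strains
#' at or above a marker-count threshold, and the median of the per-strain
#' mean coverages.
#'
#' Quantiles use R's default convention (`quantile()` type 7, linear
#' interpolation at index `(n - 1) q + 1`); the convention is exposed
#' because published summaries of marker tables do not always state theirs.
#'
#' @param table1 data frame with columns `n_unique_snvs` and `avg_coverage`.
#' @param min_snvs threshold for the strain count (default 16, the marker
#'   count below which the error model predicts >5% proportional error for
#'   a strain at frequency 0.01 at coverage 1691).
#' @param quantile_type passed to [stats::quantile()].
#' @return list with `median_unique_snvs`, `q25_unique_snvs`,
#'   `q75_unique_snvs`, `total_unique_snvs`, `n_strains_min_snvs`,
#'   `median_avg_coverage`.
#' @export
summary_statistics <- function(table1, min_snvs = 16, quantile_type = 7) {
  stop_if_not_cols(table1, c("n_unique_snvs", "avg_coverage"), "marker table")
  if (nrow(table1) < 1L) stop("marker table has no rows")
  x <- table1$n_unique_snvs
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  list(
    median_unique_snvs = q[2],
    q25_unique_snvs = q[1],
    q75_unique_snvs = q[3],
    total_unique_snvs = sum(x),
    n_strains_min_snvs = sum(x >= min_snvs),
    median_avg_coverage = stats::quantile(table1$avg_coverage, 0.5,
                                          type = quantile_type, names = FALSE)
  )
}
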