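#' Infer strain frequencies from pooled counts at unique SNVs
#'
#' The frequency of strain `s` in library `(r, d)` is estimated as the
#' unweighted mean, over `s`'s unique SNVs with total coverage at least
#' `min_total_reads`, of the per-SNV alternative-read fraction
#' `alt / (ref + alt)`. Each unique SNV gives an independent estimate of the
#' strain's proportion in the pool; averaging them is the estimator whose
#' precision the error model quantifies (see
#' [simulate_proportional_error()]). Estimates from fewer than 16 SNVs are
#' flagged low-confidence, the marker count below which proportional error
#' exceeds 5% for a strain at frequency 0.01 at coverage 1691.
#'
#' Frequencies are not renormalised to sum to 1 across strains; the raw
#' per-strain means are what feed the trait regression.
#'
#' @param map a `unique_snv_map` from [identify_unique_snvs()].
#' @param counts a `pooled_count_table`; rows for variants not in `map` are
#'   dropped.
#' @param min_total_reads minimum `ref + alt` for a SNV to contribute
#'   (default 1: zero-coverage SNVs are excluded rather than treated as
#'   frequency 0).
#' @param weight_by_coverage if `TRUE`, average per-SNV fractions weighted
#'   by total coverage instead of the default unweighted mean.
#' @return data frame of class `frequency_table` with one row per strain
#'   per library: `strain, replicate, day, frequency, n_snvs,
#'   low_confidence`. A strain with no usable SNV in a library gets
#'   `frequency = NA` (missing, not zero) and `n_snvs = 0`.
#' @export
infer_frequencies <- function(map, counts, min_total_reads = 1,
                              weight_by_coverage = FALSE) {
  stopifnot(inherits(map, "unique_snv_map"), min_total_reads >= 0)
  counts <- filter_to_unique_snvs(counts, map)
  libs <- count_table_libraries(counts)
  strains <- names(map$per_strain_count)
  grid <- expand.grid(strain = strains, lib = seq_len(nrow(libs)),
                      stringsAsFactors = FALSE)
  out <- data.frame(strain = grid$strain,
                    replicate = libs$replicate[grid$lib],
                    day = libs$day[grid$lib],
                    frequency = NA_real_, n_snvs = 0L,
                    low_confidence = TRUE, stringsAsFactors = FALSE)
  df <- as.data.frame(counts)
  for (j in seq_len(nrow(libs))) {
    ref <- df[[paste0(libs$label[j], "_ref")]]
    alt <- df[[paste0(libs$label[j], "_alt")]]
    tot <- ref + alt
    use <- tot >= max(min_total_reads, .Machine$double.eps)
    frac <- alt[use] / tot[use]
    by_strain <- factor(df$strain[use], levels = strains)
    n <- as.integer(table(by_strain))
    est <- if (weight_by_coverage) {
      num <- tapply(frac * tot[use], by_strain, sum)
      den <- tapply(tot[use], by_strain, sum)
      as.numeric(num / den)
    } else as.numeric(tapply(frac, by_strain, mean))
    rows <- out$replicate == libs$replicate[j] & out$day == libs$day[j]
    idx <- match(out$strain[rows], strains)
    out$frequency[rows] <- est[idx]
    out$n_snvs[rows] <- n[idx]
  }
  out$low_confidence <- is.na(out$frequency) | out$n_snvs < 16L
  bad <- !is.na(out$frequency) & (out$frequency < 0 | out$frequency > 1)
  if (any(bad)) stop("inferred frequency outside [0, 1]")
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Distribution of strain frequencies in one library
#'
#' Summarises the cross-strain frequency distribution of a single library:
#' the median and variance of the frequencies, and their natural logs
#' (zero and missing frequencies are excluded from the log table and
#' counted separately). The shift of this distribution over time -- falling
#' median, growing variance -- is the signature of selection during
#' starvation.
#'
#' @param freqs a `frequency_table` from [infer_frequencies()].
#' @param replicate,day identify the library.
#' @return list with `median`, `variance`, `log_frequencies` (data frame
#'   `strain, log_frequency`), `n_zero`, `n_missing`, `n_strains`.
#' @export
frequency_distribution_summary <- function(freqs, replicate, day) {
  sel <- freqs$replicate == as.character(replicate) & freqs$day == day
  if (!any(sel)) stop("no library (", replicate, ", ", day, ") in the table")
  f <- freqs$frequency[sel]
  pos <- !is.na(f) & f > 0
  list(
    median = stats::median(f, na.rm = TRUE),
    variance = stats::var(f, na.rm = TRUE),
    log_frequencies = data.frame(strain = freqs$strain[sel][pos],
                                 log_frequency = log(f[pos]),
                                 stringsAsFactors = FALSE),
    n_zero = sum(!is.na(f) & f == 0),
    n_missing = sum(is.na(f)),
    n_strains = sum(sel)
  )
}
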