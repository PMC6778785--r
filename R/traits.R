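#' Ordinary least-squares slope of frequency against day
#'
#' The slope, with intercept, of the regression of a strain's pool
#' frequency on the day of L1 starvation:
#' `sum((d - mean(d)) (f - mean(f))) / sum((d - mean(d))^2)`.
#' Pairs with a missing frequency are dropped.
#'
#' @param days numeric day values.
#' @param frequencies matching frequencies (may contain `NA`).
#' @param label optional strain/replicate label used in error messages.
#' @return the slope, in frequency units per day.
#' @export
regression_slope <- function(days, frequencies, label = NULL) {
  keep <- !is.na(days) & !is.na(frequencies)
  d <- days[keep]
  f <- frequencies[keep]
  who <- if (is.null(label)) "" else paste0(" for ", label)
  if (length(unique(d)) < 2L)
    stop("need >= 2 distinct days with non-missing frequencies", who)
  sum((d - mean(d)) * (f - mean(f))) / sum((d - mean(d))^2)
}

#' Convert strain frequencies into selection trait values
#'
#' For each strain and biological replicate, fits the least-squares slope
#' of frequency against day over that replicate's sampled days; the trait
#' value is the unweighted mean of the per-replicate slopes. A positive
#' trait value means the strain increased in relative frequency over the
#' starvation time course (relative starvation resistance); a negative
#' value, relative sensitivity.
#'
#' @param freqs a `frequency_table` from [infer_frequencies()].
#' @param replicate_day_map optional named list restricting each replicate
#'   to a set of days (e.g. `list("1" = c(16, 21), "2" = c(1, 7, 14, 21,
#'   24))`); by default all days present per replicate are used. Libraries
#'   where a strain has no usable SNVs are dropped from its regression, not
#'   imputed.
#' @return data frame of class `trait_table`: one row per strain with a
#'   `slope_<replicate>` column per replicate, `trait_value` (mean of the
#'   non-missing slopes) and `n_replicates_used`. Strains with no
#'   computable slope in any replicate are omitted, with a warning.
#' @export
compute_trait_values <- function(freqs, replicate_day_map = NULL) {
  stop_if_not_cols(freqs, c("strain", "replicate", "day", "frequency"),
                   "frequency table")
  reps <- unique(as.character(freqs$replicate))
  strains <- unique(freqs$strain)
  slopes <- matrix(NA_real_, length(strains), length(reps),
                   dimnames = list(strains, reps))
  for (r in reps) {
    sub <- freqs[freqs$replicate == r, , drop = FALSE]
    if (!is.null(replicate_day_map)) {
      wanted <- replicate_day_map[[r]]
      if (is.null(wanted)) next
      sub <- sub[sub$day %in% wanted, , drop = FALSE]
    }
    for (s in strains) {
      rows <- sub[sub$strain == s & !is.na(sub$frequency), , drop = FALSE]
      if (length(unique(rows$day)) >= 2L)
        slopes[s, r] <- regression_slope(rows$day, rows$frequency,
                                         label = paste0(s, "/rep", r))
    }
  }
  n_used <- rowSums(!is.na(slopes))
  dropped <- strains[n_used == 0L]
  if (length(dropped))
    warning("no computable slope in any replicate for: ",
            paste(dropped, collapse = ", "))
  keep <- n_used > 0L
  out <- data.frame(strain = strains[keep], stringsAsFactors = FALSE)
  for (r in reps) out[[paste0("slope_", r)]] <- slopes[keep, r]
  out$trait_value <- rowMeans(slopes[keep, , drop = FALSE], na.rm = TRUE)
  out$n_replicates_used <- as.integer(n_used[keep])
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Export trait values for association mapping
#'
#' Produces the two-column (strain, trait value) mapping file consumed by
#' association tools, dropping listed strains (e.g. duplicates of the same
#' isotype, which must appear once in a GWAS panel).
#'
#' @param traits a `trait_table` (or any data frame with `strain` and
#'   `trait_value`).
#' @param exclusions strain names to drop; names not present in `traits`
#'   produce a warning and are ignored.
#' @param path optional TSV output path.
#' @return data frame `strain, trait_value` (invisibly if `path` given).
#' @export
export_gwas_traits <- function(traits, exclusions = character(), path = NULL) {
  stop_if_not_cols(traits, c("strain", "trait_value"), "trait table")
  absent <- setdiff(exclusions, traits$strain)
  if (length(absent))
    warning("exclusion(s) not present: ", paste(absent, collapse = ", "))
  out <- traits[!traits$strain %in% exclusions, c("strain", "trait_value")]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out[order(out$strain), ], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
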