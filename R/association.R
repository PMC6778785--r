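#' Naive single-marker association scan
#'
#' Per-marker simple linear regression of trait values on allele count
#' (0 = reference, 1 = alternative; homozygous strains only), with a
#' Bonferroni significance line at `-log10(0.05 / M)` for `M` markers
#' tested. This is deliberately a *naive scan with no population-structure
#' correction*: it does not implement the kinship-corrected mixed-model
#' GWAS that panel services run, and its results must not be read as one.
#' Every result object carries that label.
#'
#' @param panel a [strain_panel].
#' @param traits data frame `strain, trait_value` (e.g. from
#'   [export_gwas_traits()]); at least 10 strains must carry both a
#'   genotype and a trait.
#' @param maf_min minor-allele-frequency threshold: markers whose minor
#'   allele count (among strains with a non-missing call and a trait) is
#'   below `maf_min * n` are excluded.
#' @return object of class `association_result`: list with `results` (data
#'   frame `chrom, pos, ref, alt, n, effect, t, p, neg_log10_p`),
#'   `n_markers_tested`, `n_markers_skipped` (monomorphic or below the MAF
#'   threshold), `bonferroni_line`, and `note`.
#' @export
marker_scan <- function(panel, traits, maf_min = 0.05) {
  stopifnot(inherits(panel, "strain_panel"))
  stop_if_not_cols(traits, c("strain", "trait_value"), "trait table")
  common <- intersect(panel$strains, traits$strain[!is.na(traits$trait_value)])
  if (length(common) < 10L)
    stop("need >= 10 strains with both genotype and trait (have ",
         length(common), ")")
  gt <- panel$genotypes[, common, drop = FALSE]
  y_all <- traits$trait_value[match(common, traits$strain)]
  nv <- nrow(gt)
  res <- data.frame(panel$variants[, c("chrom", "pos", "ref", "alt")],
                    n = NA_integer_, effect = NA_real_, t = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nv)) {
    g <- gt[i, ]
    ok <- !is.na(g)
    n <- sum(ok)
    mac <- min(sum(g[ok] == 1L), sum(g[ok] == 0L))
    if (n < 3L || mac < maf_min * n) next
    x <- as.numeric(g[ok])
    y <- y_all[ok]
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    rss <- sum((y - mean(y) - b * (x - mean(x)))^2)
    se <- sqrt(rss / (n - 2) / sxx)
    t <- if (se == 0) sign(b) * Inf else b / se
    p <- 2 * stats::pt(-abs(t), n - 2)
    res[i, c("n", "effect", "t", "p")] <-
      list(n, b, t, max(p, .Machine$double.xmin))
  }
  tested <- !is.na(res$p)
  m <- sum(tested)
  if (m == 0L) stop("no polymorphic markers passed the MAF filter")
  res <- res[tested, , drop = FALSE]
  res$neg_log10_p <- -log10(res$p)
  rownames(res) <- NULL
  structure(list(results = res,
                 n_markers_tested = m,
                 n_markers_skipped = nv - m,
                 bonferroni_line = bonferroni_line(m),
                 note = "naive scan, no population-structure correction"),
            class = "association_result")
}

#' Bonferroni-corrected significance line
#'
#' `-log10(alpha / m)` for `m` tested markers.
#'
#' @param m number of markers tested.
#' @param alpha family-wise error rate (default 0.05).
#' @return the threshold on the `-log10(p)` scale.
#' @export
bonferroni_line <- function(m, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  -log10(alpha / m)
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result (%s)\n", x$note))
  cat(sprintf("  %d markers tested (%d skipped), Bonferroni line %.2f\n",
              x$n_markers_tested, x$n_markers_skipped, x$bonferroni_line))
  top <- x$results[order(x$results$p), ][1, ]
  cat(sprintf("  top marker: %s:%d %s>%s  effect %.3g  -log10(p) %.2f\n",
              top$chrom, top$pos, top$ref, top$alt, top$effect,
              top$neg_log10_p))
  invisible(x)
}

#' Genotype-by-phenotype split at one marker
#'
#' Lists each strain's allele (REF/ALT) at a chosen marker together with
#' its trait value, the table behind a genotype-by-phenotype plot for a
#' significant association.
#'
#' @param panel a [strain_panel].
#' @param traits data frame `strain, trait_value`.
#' @param chrom,pos identify the marker (must exist in the panel).
#' @return data frame `strain, allele, trait_value` (strains with a missing
#'   call or trait omitted), with attribute `group_means` (data frame
#'   `allele, mean_trait, n`; empty groups carry `n = 0` and `NA` mean).
#' @export
genotype_phenotype_split <- function(panel, traits, chrom, pos) {
  stopifnot(inherits(panel, "strain_panel"))
  stop_if_not_cols(traits, c("strain", "trait_value"), "trait table")
  i <- which(panel$variants$chrom == chrom & panel$variants$pos == pos)
  if (length(i) != 1L)
    stop("marker ", chrom, ":", pos, " not found in panel")
  g <- panel$genotypes[i, ]
  tv <- traits$trait_value[match(panel$strains, traits$strain)]
  keep <- !is.na(g) & !is.na(tv)
  out <- data.frame(strain = panel$strains[keep],
                    allele = c("REF", "ALT")[g[keep] + 1L],
                    trait_value = tv[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  gm <- data.frame(allele = c("REF", "ALT"), stringsAsFactors = FALSE)
  gm$n <- c(sum(out$allele == "REF"), sum(out$allele == "ALT"))
  gm$mean_trait <- c(
    if (gm$n[1]) mean(out$trait_value[out$allele == "REF"]) else NA_real_,
    if (gm$n[2]) mean(out$trait_value[out$allele == "ALT"]) else NA_real_)
  attr(out, "group_means") <- gm
  out
}
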