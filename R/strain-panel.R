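#' Construct a strain panel
#'
#' A strain panel holds biallelic SNV genotype calls for a set of isogenic
#' (homozygous) strains. Genotypes are coded `0` (reference allele), `1`
#' (alternative allele) or `NA` (missing call). Variants are identified by
#' 1-based `(chrom, pos, ref, alt)` and must be unique.
#'
#' @param strains character vector of unique strain identifiers.
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   one row per biallelic SNV.
#' @param genotypes integer matrix, variants in rows and strains in columns,
#'   values in `{0, 1, NA}`.
#' @return an object of class `strain_panel`: a list with elements
#'   `strains`, `variants` (with a `key` column added) and `genotypes`.
#' @examples
#' panel <- strain_panel(
#'   strains = c("A", "B"),
#'   variants = data.frame(chrom = "I", pos = 100, ref = "A", alt = "T"),
#'   genotypes = matrix(c(1L, 0L), nrow = 1)
#' )
#' @export
strain_panel <- function(strains, variants, genotypes) {
  strains <- as.character(strains)
  if (anyDuplicated(strains)) stop("strain identifiers must be unique")
  stop_if_not_cols(variants, c("chrom", "pos", "ref", "alt"), "variants")
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(variants) || ncol(genotypes) != length(strains))
    stop("genotypes must be a variants x strains matrix")
  if (!all(genotypes %in% c(0L, 1L, NA_integer_)))
    stop("genotype calls must be 0 (ref), 1 (alt) or NA (missing)")
  bad <- nchar(as.character(variants$ref)) != 1L |
    nchar(as.character(variants$alt)) != 1L
  if (any(bad)) stop("only single-nucleotide variants are supported")
  variants <- data.frame(
    chrom = as.character(variants$chrom),
    pos = as.integer(variants$pos),
    ref = as.character(variants$ref),
    alt = as.character(variants$alt),
    stringsAsFactors = FALSE
  )
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  if (anyDuplicated(variants$key)) stop("duplicated variant records")
  colnames(genotypes) <- strains
  rownames(genotypes) <- variants$key
  structure(list(strains = strains, variants = variants,
                 genotypes = genotypes),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf("strain_panel: %d strains, %d biallelic SNVs, %.1f%% missing calls\n",
              length(x$strains), nrow(x$variants),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Read a strain panel from a multi-sample VCF
#'
#' Reads a VCF with one genotype column per strain and keeps biallelic SNV
#' records. Homozygous reference calls become `0`, homozygous alternative
#' calls `1`; missing and heterozygous calls become `NA` (strains are
#' expected to be isogenic, so heterozygous calls are treated as no-calls,
#' with a warning).
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return a [strain_panel].
#' @export
read_strain_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  if (!any(snv)) stop("no biallelic SNV records found in ", path)
  fix <- fix[snv, , drop = FALSE]
  gt <- gt[snv, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0")] <- 0L
    out[g %in% c("1/1", "1")] <- 1L
    out
  }
  calls <- apply(gt, 2, code)
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  if (any(het))
    warning(sum(het), " heterozygous call(s) treated as missing")
  strain_panel(
    strains = colnames(gt),
    variants = data.frame(chrom = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]),
                          ref = fix[, "REF"], alt = fix[, "ALT"],
                          stringsAsFactors = FALSE),
    genotypes = matrix(calls, nrow = nrow(fix),
                       dimnames = list(NULL, colnames(gt)))
  )
}

#' Identify strain-unique SNVs
#'
#' A variant is unique to strain `s` when `s` carries the alternative allele
#' and every other strain in the panel carries the reference allele. The
#' alternative-read fraction of such a variant in a pooled library estimates
#' the frequency of `s` in the pool.
#'
#' @param panel a [strain_panel].
#' @param missing_policy `"strict"` (default): a variant with any missing
#'   call is never unique; `"lenient"`: missing calls are treated as
#'   reference.
#' @return an object of class `unique_snv_map`: list with `assignments`
#'   (data frame `chrom, pos, ref, alt, key, strain`) and `per_strain_count`
#'   (named integer over all panel strains, zeros included).
#' @export
identify_unique_snvs <- function(panel, missing_policy = c("strict", "lenient")) {
  stopifnot(inherits(panel, "strain_panel"))
  missing_policy <- match.arg(missing_policy)
  if (length(panel$strains) == 0L || nrow(panel$variants) == 0L)
    stop("panel is empty")
  gt <- panel$genotypes
  if (missing_policy == "lenient") gt[is.na(gt)] <- 0L
  n_alt <- rowSums(gt == 1L, na.rm = TRUE)
  n_na <- rowSums(is.na(gt))
  unique_row <- n_alt == 1L & n_na == 0L
  owner <- rep(NA_character_, nrow(gt))
  if (any(unique_row)) {
    idx <- max.col(gt[unique_row, , drop = FALSE] == 1L, ties.method = "first")
    owner[unique_row] <- panel$strains[idx]
  }
  assignments <- cbind(
    panel$variants[unique_row, c("chrom", "pos", "ref", "alt", "key")],
    data.frame(strain = owner[unique_row], stringsAsFactors = FALSE)
  )
  rownames(assignments) <- NULL
  per_strain <- table(factor(assignments$strain, levels = panel$strains))
  per_strain_count <- stats::setNames(as.integer(per_strain), panel$strains)
  structure(list(assignments = assignments,
                 per_strain_count = per_strain_count),
            class = "unique_snv_map")
}

#' @export
print.unique_snv_map <- function(x, ...) {
  cat(sprintf("unique_snv_map: %d unique SNVs across %d strains (%d with >=1)\n",
              nrow(x$assignments), length(x$per_strain_count),
              sum(x$per_strain_count > 0)))
  invisible(x)
}
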