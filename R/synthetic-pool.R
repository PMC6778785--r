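#' Configuration for a synthetic pooled-selection experiment
#'
#' Builds the complete, concrete configuration of a simulated experiment:
#' a pool of homozygous strains, each with a set of strain-unique SNV
#' markers, starved together in one culture and sampled on given days, with
#' pooled sequencing read counts drawn at each unique SNV.
#'
#' Defaults emulate the real experiment's scale: 96 strains, per-strain
#' unique-SNV counts drawn from a log-normal matched to the observed spread
#' (median 33, quartiles roughly 22 and 67, clamped to at least 1), founder
#' frequencies from a symmetric Dirichlet (concentration 3, giving a day-1
#' median near 1/96 with substantial spread), per-day instantaneous
#' mortality rates from a gamma distribution with mean 0.1/day and
#' coefficient of variation 0.71 (enough heterogeneity that the frequency
#' distribution visibly spreads and its median falls over weeks), replicate
#' sampling days `{16, 21}` and `{1, 7, 14, 21, 24}`, and mean total
#' coverage 1691 reads per SNV.
#'
#' @param n_strains number of strains in the pool.
#' @param unique_snv_counts integer vector (length `n_strains`) of unique
#'   SNVs per strain, or `NULL` to sample from the log-normal law above.
#' @param initial_frequencies founder proportions summing to 1, or `NULL`
#'   to draw Dirichlet(`dirichlet_alpha`).
#' @param dirichlet_alpha symmetric Dirichlet concentration for founder
#'   frequencies.
#' @param mortality_rates per-strain per-day death rates (>= 0), or `NULL`
#'   to draw from the gamma law above.
#' @param recovery_weights per-strain multiplicative fitness on recovery
#'   (growth/fecundity proxy; default all 1). Folded into frequency as a
#'   single fitness term, mirroring how sampling after recovery integrates
#'   survival, growth and early fecundity.
#' @param sample_days named list, one numeric vector of days per replicate.
#' @param mean_total_coverage_per_snv expected total reads per SNV per
#'   library.
#' @param read_noise_model `"poisson_split"` (independent Poisson alt and
#'   ref counts; default), `"binomial_given_total"` (total ~ Poisson,
#'   alt | total ~ binomial), or `"expected"` (noise-free expectation-valued
#'   counts, the oracle used in tests).
#' @param demographic_n effective number of individuals sampled per library
#'   for finite-population demographic noise; `Inf` (default) gives
#'   deterministic infinite-population dynamics, appropriate for cultures of
#'   millions of larvae.
#' @param seed integer seed; all randomness in the generator derives from
#'   it explicitly.
#' @return an object of class `sim_config` (a list of the resolved fields,
#'   plus `strains`, the strain names `S001...`).
#' @export
sim_config <- function(n_strains = 96,
                       unique_snv_counts = NULL,
                       initial_frequencies = NULL,
                       dirichlet_alpha = 3,
                       mortality_rates = NULL,
                       recovery_weights = NULL,
                       sample_days = list("1" = c(16, 21),
                                          "2" = c(1, 7, 14, 21, 24)),
                       mean_total_coverage_per_snv = 1691,
                       read_noise_model = c("poisson_split",
                                            "binomial_given_total",
                                            "expected"),
                       demographic_n = Inf,
                       seed = 1L) {
  read_noise_model <- match.arg(read_noise_model)
  stopifnot(n_strains >= 1, mean_total_coverage_per_snv > 0)
  if (any(unlist(sample_days) < 0)) stop("sampling days must be >= 0")
  drawn <- with_seed(seed, {
    snvs <- unique_snv_counts %||%
      pmax(1L, as.integer(round(stats::rlnorm(n_strains,
                                              meanlog = log(33),
                                              sdlog = 0.83))))
    f0 <- initial_frequencies %||% {
      g <- stats::rgamma(n_strains, shape = dirichlet_alpha, rate = 1)
      g / sum(g)
    }
    m <- mortality_rates %||%
      stats::rgamma(n_strains, shape = 2, rate = 20)
    list(snvs = snvs, f0 = f0, m = m)
  })
  w <- recovery_weights %||% rep(1, n_strains)
  stopifnot(length(drawn$snvs) == n_strains, length(drawn$f0) == n_strains,
            length(drawn$m) == n_strains, length(w) == n_strains)
  if (abs(sum(drawn$f0) - 1) > 1e-12)
    stop("initial_frequencies must sum to 1 (tolerance 1e-12)")
  if (any(drawn$m < 0)) stop("mortality_rates must be >= 0")
  if (any(drawn$snvs < 1)) stop("unique_snv_counts must be >= 1")
  if (any(w < 0)) stop("recovery_weights must be >= 0")
  if (all(w * drawn$f0 == 0)) stop("pool is empty: all w * f0 are zero")
  structure(list(
    n_strains = as.integer(n_strains),
    strains = sprintf("S%03d", seq_len(n_strains)),
    unique_snv_counts = drawn$snvs,
    initial_frequencies = drawn$f0,
    mortality_rates = drawn$m,
    recovery_weights = w,
    sample_days = sample_days,
    mean_total_coverage_per_snv = mean_total_coverage_per_snv,
    read_noise_model = read_noise_model,
    demographic_n = demographic_n,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d strains, %d unique SNVs total, ",
                     "coverage %g, noise '%s', seed %d\n"),
              x$n_strains, sum(x$unique_snv_counts),
              x$mean_total_coverage_per_snv, x$read_noise_model, x$seed))
  invisible(x)
}

# library grid (replicate, day) from a config's sample_days
sim_libraries <- function(config) {
  do.call(rbind, lapply(names(config$sample_days), function(r)
    data.frame(replicate = r, day = config$sample_days[[r]],
               stringsAsFactors = FALSE)))
}

#' Simulate true strain-frequency trajectories under starvation
#'
#' Under heterogeneous mortality and recovery fitness, the frequency of
#' strain `s` on day `d` is
#' \deqn{f_s(d) = \frac{w_s f_s(0) e^{-m_s d}}{\sum_k w_k f_k(0) e^{-m_k d}}}
#' where `m_s` is the per-day mortality rate and `w_s` the recovery weight.
#' This is the deterministic infinite-population limit; with a finite
#' `demographic_n` a multinomial resample of that size is drawn per library.
#' Strains with above-average fitness increase in frequency over time, so
#' the cross-strain variance grows and the median falls, the qualitative
#' signature of selection in the pooled culture.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_truth`: list with `frequencies` (strains
#'   x libraries matrix, columns labelled `<replicate>_<day>`, each column
#'   summing to 1), `libraries`, `true_trait_values` (per-strain expected
#'   trait value, computed from the true frequencies with the same
#'   per-replicate regression as the pipeline, see [compute_trait_values()])
#'   and `config`.
#' @export
simulate_frequency_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  libs <- sim_libraries(config)
  if (any(libs$day < 0)) stop("sampling days must be >= 0")
  f0 <- config$initial_frequencies
  w <- config$recovery_weights
  m <- config$mortality_rates
  freq <- sapply(libs$day, function(d) {
    num <- w * f0 * exp(-m * d)
    tot <- sum(num)
    if (tot <= 0) stop("pool extinct at day ", d, ": denominator is zero")
    num / tot
  })
  if (is.finite(config$demographic_n)) {
    n <- as.integer(config$demographic_n)
    freq <- with_seed(config$seed + 10L,
      apply(freq, 2, function(p) as.numeric(stats::rmultinom(1, n, p)) / n))
  }
  dimnames(freq) <- list(config$strains,
                         library_label(libs$replicate, libs$day))
  truth <- structure(list(frequencies = freq, libraries = libs,
                          config = config),
                     class = "sim_truth")
  truth$true_trait_values <- true_trait_values(truth)
  truth
}

# expected trait value per strain: same per-replicate OLS slope, averaged,
# applied to the true frequencies; replicates sampled on < 2 distinct days
# cannot carry a slope and are skipped
true_trait_values <- function(truth) {
  libs <- truth$libraries
  slopes <- sapply(unique(libs$replicate), function(r) {
    sel <- libs$replicate == r
    if (length(unique(libs$day[sel])) < 2L)
      return(rep(NA_real_, nrow(truth$frequencies)))
    apply(truth$frequencies[, sel, drop = FALSE], 1, function(f)
      regression_slope(libs$day[sel], f))
  })
  slopes <- matrix(slopes, nrow = nrow(truth$frequencies))
  stats::setNames(rowMeans(slopes, na.rm = TRUE),
                  rownames(truth$frequencies))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d strains x %d libraries\n",
              nrow(x$frequencies), ncol(x$frequencies)))
  invisible(x)
}

#' Synthetic strain panel matching a simulation config
#'
#' Builds the genotype panel implied by a configuration: strain `i` carries
#' the alternative allele at its `unique_snv_counts[i]` marker SNVs and the
#' reference allele everywhere else, so [identify_unique_snvs()] recovers
#' the configured marker sets exactly. Variant coordinates are deterministic
#' (chromosomes I-V and X in rotation, positions on a fixed grid).
#'
#' @param config a [sim_config()].
#' @return a [strain_panel].
#' @export
sim_strain_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  variants <- sim_variants(config)
  n_var <- nrow(variants)
  gt <- matrix(0L, n_var, config$n_strains,
               dimnames = list(NULL, config$strains))
  gt[cbind(seq_len(n_var), match(variants$strain, config$strains))] <- 1L
  strain_panel(config$strains,
               variants[, c("chrom", "pos", "ref", "alt")], gt)
}

# deterministic unique-variant scaffold for a config
sim_variants <- function(config) {
  n <- sum(config$unique_snv_counts)
  chroms <- c("I", "II", "III", "IV", "V", "X")
  i <- seq_len(n) - 1L
  data.frame(
    chrom = chroms[(i %% 6L) + 1L],
    pos = 1000L + 50L * (i %/% 6L),
    ref = c("A", "C", "G", "T")[(i %% 4L) + 1L],
    alt = c("T", "G", "C", "A")[(i %% 4L) + 1L],
    strain = rep(config$strains, times = config$unique_snv_counts),
    stringsAsFactors = FALSE
  )
}

#' Simulate a pooled read-count table
#'
#' Draws per-SNV read counts for every library of a simulated experiment.
#' Under `"poisson_split"`, the alternative count at a unique SNV of strain
#' `s` in library `(r, d)` is Poisson with mean `lambda * f_s(r, d)` and the
#' reference count Poisson with mean `lambda * (1 - f_s(r, d))`, with
#' `lambda` the mean total coverage. Under `"binomial_given_total"` the
#' total is Poisson(`lambda`) and the alternative count binomial given the
#' total. Under `"expected"` the counts are the exact expectations
#' (non-integer), the noise-free oracle.
#'
#' @param truth a `sim_truth` from [simulate_frequency_trajectories()].
#' @param config a [sim_config()]; defaults to the one stored in `truth`.
#' @return a `pooled_count_table` with a `strain` column (the owning strain
#'   of each unique SNV).
#' @export
simulate_count_table <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  variants <- sim_variants(config)
  lam <- config$mean_total_coverage_per_snv
  f <- truth$frequencies[variants$strain, , drop = FALSE]  # SNV x library
  n <- length(f)
  counts <- with_seed(config$seed + 20L, switch(
    config$read_noise_model,
    poisson_split = list(alt = stats::rpois(n, lam * f),
                         ref = stats::rpois(n, lam * (1 - f))),
    binomial_given_total = {
      tot <- stats::rpois(n, lam)
      alt <- stats::rbinom(n, tot, as.vector(f))
      list(alt = alt, ref = tot - alt)
    },
    expected = list(alt = lam * f, ref = lam * (1 - f))
  ))
  dim(counts$alt) <- dim(f)
  dim(counts$ref) <- dim(f)
  pooled_count_table(variants, truth$libraries, counts$ref, counts$alt)
}

#' Simulate a manual starvation-survival assay
#'
#' Worms are sampled from a starving culture on given days and plated with
#' food; survivors are those that recover. The number alive out of
#' `plated_per_day` on day `d` is binomial with survival probability
#' `S(d) = 1 / (1 + exp(k (d - t50)))`, the logistic survival curve with
#' median survival time `t50` and steepness `k`.
#'
#' @param median_days per-strain `t50` in days (> 0); names, if any, become
#'   strain names.
#' @param steepness per-strain `k` (> 0), recycled to length of
#'   `median_days`.
#' @param days assay days (>= 0); default every other day out to day 29.
#' @param plated_per_day worms plated per strain per day.
#' @param n_replicates biological replicates per strain.
#' @param seed integer seed.
#' @return data frame of class `survival_dataset` with columns
#'   `strain, replicate, day, plated, alive`.
#' @export
simulate_survival_assay <- function(median_days, steepness,
                                    days = seq(1, 29, by = 2),
                                    plated_per_day = 150,
                                    n_replicates = 1,
                                    seed = 1L) {
  if (any(median_days <= 0)) stop("median_days must be > 0")
  if (any(steepness <= 0)) stop("steepness must be > 0")
  if (any(days < 0)) stop("assay days must be >= 0")
  strains <- names(median_days) %||% sprintf("S%03d", seq_along(median_days))
  steepness <- rep_len(steepness, length(median_days))
  grid <- expand.grid(day = days, replicate = as.character(seq_len(n_replicates)),
                      strain = strains, stringsAsFactors = FALSE)
  i <- match(grid$strain, strains)
  s <- 1 / (1 + exp(steepness[i] * (grid$day - median_days[i])))
  alive <- with_seed(seed, stats::rbinom(nrow(grid), plated_per_day, s))
  out <- data.frame(strain = grid$strain, replicate = grid$replicate,
                    day = grid$day, plated = plated_per_day, alive = alive,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_dataset", "data.frame")
  out
}
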