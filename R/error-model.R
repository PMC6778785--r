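#' Simulated proportional error of the pooled-frequency estimator
#'
#' Monte-Carlo estimate of the precision of the unique-SNV frequency
#' estimator. Each simulation draws `n_snvs` independent Poisson counts
#' with mean `lambda * f` (the expected number of alternative-allele reads
#' at one unique SNV for a strain at frequency `f` with total per-SNV
#' coverage `lambda`), estimates the frequency as the mean of
#' `count / lambda`, and records the absolute difference from `f`. The mean
#' proportional error is the average absolute difference divided by `f`.
#'
#' With `coverage = "random"` the per-SNV total is itself Poisson(`lambda`)
#' and the alternative count binomial given the total, with the per-SNV
#' estimate `alt / total` (zero-coverage SNVs dropped); the default keeps
#' the total fixed at `lambda`.
#'
#' In the normal regime (`lambda * f * n_snvs` large) the mean proportional
#' error approaches `sqrt(2 / (pi * n_snvs * lambda * f))`, the mean
#' absolute deviation of the normal approximation; the simulation is the
#' definitive value and the closed form a cross-check.
#'
#' @param lambda expected total reads per SNV (> 0).
#' @param n_snvs number of unique SNVs averaged (>= 1).
#' @param f true strain frequency, in (0, 1].
#' @param n_sim number of simulations (default 4000).
#' @param seed integer seed.
#' @param coverage `"fixed"` (default) or `"random"`, see above.
#' @return mean proportional error (dimensionless, >= 0).
#' @export
simulate_proportional_error <- function(lambda, n_snvs, f, n_sim = 4000,
                                        seed = NULL,
                                        coverage = c("fixed", "random")) {
  coverage <- match.arg(coverage)
  stopifnot(lambda > 0, n_snvs >= 1, n_sim >= 1)
  if (f <= 0 || f > 1)
    stop("true frequency must be in (0, 1]: proportional error is undefined at f = 0")
  with_seed(seed, {
    if (coverage == "fixed") {
      alt <- matrix(stats::rpois(n_sim * n_snvs, lambda * f), n_sim, n_snvs)
      fhat <- rowMeans(alt) / lambda
    } else {
      tot <- matrix(stats::rpois(n_sim * n_snvs, lambda), n_sim, n_snvs)
      alt <- matrix(stats::rbinom(length(tot), as.vector(tot), f),
                    n_sim, n_snvs)
      frac <- alt / tot  # NaN where total == 0; dropped from the mean
      fhat <- rowMeans(frac, na.rm = TRUE)
    }
    mean(abs(fhat - f), na.rm = TRUE) / f
  })
}

#' Proportional-error grid over coverage, marker count and frequency
#'
#' Evaluates [simulate_proportional_error()] on the full cross-product of
#' the supplied axes. Cell seeds are derived deterministically from `seed`
#' (cell `i` uses `seed + i - 1`), so a 1x1x1 grid reproduces a direct call
#' with the same seed and the whole grid is reproducible.
#'
#' @param lambdas,n_snvs,fs numeric axes (non-empty).
#' @param n_sim simulations per cell.
#' @param seed integer base seed.
#' @param coverage passed to [simulate_proportional_error()].
#' @return object of class `error_grid`: data frame `lambda, n_snvs, f,
#'   mean_prop_error` with attributes `n_sim` and `seed`.
#' @export
error_grid <- function(lambdas, n_snvs, fs, n_sim = 4000, seed = 1L,
                       coverage = c("fixed", "random")) {
  coverage <- match.arg(coverage)
  if (!length(lambdas) || !length(n_snvs) || !length(fs))
    stop("all grid axes must be non-empty")
  grid <- expand.grid(lambda = lambdas, n_snvs = n_snvs, f = fs,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mean_prop_error <- vapply(seq_len(nrow(grid)), function(i)
    simulate_proportional_error(grid$lambda[i], grid$n_snvs[i], grid$f[i],
                                n_sim = n_sim, seed = seed + i - 1L,
                                coverage = coverage),
    numeric(1))
  attr(grid, "n_sim") <- n_sim
  attr(grid, "seed") <- seed
  class(grid) <- c("error_grid", "data.frame")
  grid
}

#' Smallest marker count meeting a target error
#'
#' Inverts the error simulation: among candidate unique-SNV counts (sorted
#' ascending), returns the smallest whose simulated mean proportional error
#' is at or below `target_error` at the given coverage and frequency.
#'
#' @param target_error tolerated mean proportional error.
#' @param lambda expected total reads per SNV.
#' @param f true strain frequency.
#' @param n_snvs_candidates ascending candidate marker counts (non-empty).
#' @param n_sim,seed passed to [simulate_proportional_error()] (candidate
#'   `i` uses `seed + i - 1`).
#' @return the smallest qualifying candidate, or `NA` if none qualifies.
#' @export
minimum_requirements <- function(target_error, lambda, f, n_snvs_candidates,
                                 n_sim = 4000, seed = 1L) {
  if (!length(n_snvs_candidates)) stop("no candidate marker counts supplied")
  if (is.unsorted(n_snvs_candidates, strictly = TRUE))
    stop("candidates must be sorted strictly ascending")
  for (i in seq_along(n_snvs_candidates)) {
    err <- simulate_proportional_error(lambda, n_snvs_candidates[i], f,
                                       n_sim = n_sim, seed = seed + i - 1L)
    if (err <= target_error) return(n_snvs_candidates[i])
  }
  NA_real_
}
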