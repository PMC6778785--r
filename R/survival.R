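#' Fit a logistic survival curve to one strain/replicate
#'
#' Fits the three-parameter logistic
#' \deqn{S(d) = U / (1 + e^{k (d - t_{50})})}
#' to the per-day survival proportions `alive / plated` of one strain and
#' biological replicate by nonlinear least squares, weighting observations
#' by the number plated. `t50`, the day at which the curve reaches half its
#' upper asymptote `U`, is reported as the median survival time. Note that
#' when `U < 1` this differs from the day of absolute 50% survival.
#'
#' If the free-`U` fit fails or is non-identifiable, `U` is fixed to the
#' earliest-day survival proportion and the two-parameter fit retried
#' (`fix_upper = TRUE` forces this behaviour). Degenerate inputs (constant
#' survival, e.g. everything alive) yield a flagged, non-converged fit
#' rather than an error.
#'
#' @param obs data frame with columns `day, plated, alive` (and optionally
#'   `strain`, `replicate`, carried into the result) for one
#'   strain/replicate; at least 3 distinct days.
#' @param fix_upper fix the upper asymptote at the earliest-day survival
#'   proportion instead of estimating it.
#' @return one-row data frame of class `survival_fit`: `strain, replicate,
#'   t50, k, upper, rss, converged`.
#' @export
fit_logistic_survival <- function(obs, fix_upper = FALSE) {
  stop_if_not_cols(obs, c("day", "plated", "alive"), "survival observations")
  if (any(obs$alive > obs$plated) || any(obs$alive < 0))
    stop("need 0 <= alive <= plated")
  if (length(unique(obs$day)) < 3L)
    stop("need observations on >= 3 distinct days")
  p <- obs$alive / obs$plated
  strain <- as.character(obs$strain[1] %||% NA)
  replicate <- as.character(obs$replicate[1] %||% NA)
  fail <- function() {
    out <- data.frame(strain = strain, replicate = replicate,
                      t50 = NA_real_, k = NA_real_, upper = NA_real_,
                      rss = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE)
    class(out) <- c("survival_fit", "data.frame")
    out
  }
  if (stats::sd(p) == 0) return(fail())  # flat curve: t50 non-identifiable
  if (min(p) > max(p) / 2)
    warning("no observation below half the maximum survival; ",
            "t50 is an extrapolation")
  u0 <- min(max(p), 1)
  below <- obs$day[p <= u0 / 2]
  t50_0 <- if (length(below)) min(below) else max(obs$day)
  dat <- data.frame(day = obs$day, p = p, w = obs$plated)
  do_fit <- function(fix_u) {
    form <- if (fix_u) p ~ u0 / (1 + exp(k * (day - t50)))
            else p ~ upper / (1 + exp(k * (day - t50)))
    start <- if (fix_u) list(k = 0.5, t50 = t50_0)
             else list(upper = u0, k = 0.5, t50 = t50_0)
    lower <- if (fix_u) c(1e-8, 1e-8) else c(1e-8, 1e-8, 1e-8)
    upper_b <- if (fix_u) c(Inf, Inf) else c(1, Inf, Inf)
    tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start, weights = dat$w,
                        lower = lower, upper = upper_b,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- do_fit(fix_upper)
  used_fixed <- fix_upper
  if (is.null(fit) && !fix_upper) {
    fit <- do_fit(TRUE)
    used_fixed <- TRUE
  }
  if (is.null(fit)) return(fail())
  cf <- stats::coef(fit)
  out <- data.frame(
    strain = strain, replicate = replicate,
    t50 = unname(cf["t50"]), k = unname(cf["k"]),
    upper = if (used_fixed) u0 else unname(cf["upper"]),
    rss = sum(stats::residuals(fit)^2 * dat$w),
    converged = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("survival_fit", "data.frame")
  out
}

#' Fit logistic survival curves to every strain/replicate of a dataset
#'
#' @param data data frame with columns `strain, replicate, day, plated,
#'   alive` (e.g. from [simulate_survival_assay()] or
#'   [read_survival_tsv()]).
#' @param ... passed to [fit_logistic_survival()].
#' @return data frame of class `survival_fit`, one row per
#'   strain/replicate; failed fits carry `converged = FALSE`.
#' @export
fit_survival_dataset <- function(data, ...) {
  stop_if_not_cols(data, c("strain", "replicate", "day", "plated", "alive"),
                   "survival dataset")
  parts <- split(data, list(data$strain, data$replicate), drop = TRUE)
  out <- do.call(rbind, lapply(parts, fit_logistic_survival, ...))
  rownames(out) <- NULL
  out[order(out$strain, out$replicate), , drop = FALSE]
}

#' Compare median survival times across strains
#'
#' Takes per-replicate fitted median survival times (`t50`) and (i) tests
#' homogeneity of their variances across strains with Bartlett's test, and
#' (ii) computes pairwise two-sample t statistics using the variance pooled
#' across *all* strains (with the corresponding degrees of freedom), the
#' appropriate comparison when Bartlett's test finds no evidence of unequal
#' variances. A warning is issued if Bartlett's test rejects at
#' `alpha = 0.05`, since the pooled-variance comparisons then rest on a
#' violated assumption.
#'
#' @param fits data frame with columns `strain, replicate, t50` (e.g. from
#'   [fit_survival_dataset()]); non-converged fits (`NA` `t50`) are
#'   dropped. Strains with fewer than 2 usable replicates are excluded,
#'   with a warning.
#' @return list with `bartlett_statistic`, `bartlett_p`, `pooled_variance`,
#'   `df` (pooled degrees of freedom), `strain_means` (data frame `strain,
#'   mean_t50, n`), and `pairwise` (data frame `strain1, strain2,
#'   difference, t, p`).
#' @export
compare_median_survival <- function(fits) {
  stop_if_not_cols(fits, c("strain", "t50"), "survival fits")
  fits <- fits[!is.na(fits$t50), , drop = FALSE]
  n_rep <- table(fits$strain)
  small <- names(n_rep)[n_rep < 2]
  if (length(small)) {
    warning("excluded strain(s) with < 2 replicates: ",
            paste(small, collapse = ", "))
    fits <- fits[!fits$strain %in% small, , drop = FALSE]
  }
  if (length(unique(fits$strain)) < 2L)
    stop("need >= 2 strains with >= 2 replicates each")
  g <- factor(fits$strain)
  bt <- stats::bartlett.test(fits$t50, g)
  if (bt$p.value < 0.05)
    warning("Bartlett's test rejects equal variances (p = ",
            signif(bt$p.value, 3), "); pooled-variance t-tests may be invalid")
  ni <- tapply(fits$t50, g, length)
  mi <- tapply(fits$t50, g, mean)
  vi <- tapply(fits$t50, g, stats::var)
  df <- sum(ni - 1)
  sp2 <- sum((ni - 1) * vi) / df
  strains <- levels(g)
  pairs <- utils::combn(strains, 2)
  pw <- data.frame(strain1 = pairs[1, ], strain2 = pairs[2, ],
                   stringsAsFactors = FALSE)
  pw$difference <- mi[pw$strain1] - mi[pw$strain2]
  se <- sqrt(sp2 * (1 / ni[pw$strain1] + 1 / ni[pw$strain2]))
  pw$t <- ifelse(se == 0, ifelse(pw$difference == 0, 0, Inf),
                 pw$difference / se)
  pw$p <- 2 * stats::pt(-abs(pw$t), df)
  rownames(pw) <- NULL
  list(bartlett_statistic = unname(bt$statistic),
       bartlett_p = bt$p.value,
       pooled_variance = sp2, df = df,
       strain_means = data.frame(strain = strains,
                                 mean_t50 = as.numeric(mi),
                                 n = as.integer(ni),
                                 stringsAsFactors = FALSE),
       pairwise = pw)
}

#' Normalise starvation-recovery measurements to the one-day baseline
#'
#' Recovery assays (total brood size, early fecundity, body length) are
#' measured after one and after eight days of L1 starvation; the effect of
#' extended starvation is isolated by dividing each measurement by the
#' same strain's mean one-day value for the same assay. One-day rows are
#' normalised too, so their per-strain mean is 1 by construction.
#'
#' @param measurements data frame with columns `strain, replicate,
#'   days_starved, assay, value` (`value >= 0`).
#' @return the input with a `normalized` column appended.
#' @export
normalize_recovery <- function(measurements) {
  stop_if_not_cols(measurements,
                   c("strain", "replicate", "days_starved", "assay", "value"),
                   "recovery measurements")
  if (any(measurements$value < 0)) stop("values must be >= 0")
  key <- interaction(measurements$strain, measurements$assay, drop = TRUE)
  out <- measurements
  out$normalized <- NA_real_
  for (k in levels(key)) {
    rows <- key == k
    base <- measurements$value[rows & measurements$days_starved == 1]
    if (!length(base))
      stop("no one-day baseline for ", sub("\\.", " / ", k))
    if (mean(base) == 0)
      stop("one-day baseline mean is zero for ", sub("\\.", " / ", k))
    out$normalized[rows] <- measurements$value[rows] / mean(base)
  }
  out
}

#' Correlate sequencing-derived trait values with median survival
#'
#' Regresses each strain's mean fitted median survival time (across
#' replicates) on its pooled-sequencing trait value, the validation that
#' strains which rose in frequency in the pool really survive starvation
#' longer in individual assays.
#'
#' @param traits a `trait_table` (columns `strain, trait_value`).
#' @param fits survival fits (columns `strain, t50`); non-converged fits
#'   dropped.
#' @return list with `data` (data frame `strain, trait_value, mean_t50`),
#'   `slope`, `intercept`, `r_squared`, `p_value` (slope t-test).
#' @export
correlate_trait_with_survival <- function(traits, fits) {
  stop_if_not_cols(traits, c("strain", "trait_value"), "trait table")
  stop_if_not_cols(fits, c("strain", "t50"), "survival fits")
  fits <- fits[!is.na(fits$t50), , drop = FALSE]
  mean_t50 <- tapply(fits$t50, fits$strain, mean)
  common <- intersect(traits$strain, names(mean_t50))
  if (length(common) < 3L)
    stop("need >= 3 strains with both a trait value and a survival fit")
  dat <- data.frame(strain = common,
                    trait_value = traits$trait_value[match(common, traits$strain)],
                    mean_t50 = as.numeric(mean_t50[common]),
                    stringsAsFactors = FALSE)
  fit <- stats::lm(mean_t50 ~ trait_value, data = dat)
  sm <- summary(fit)
  list(data = dat,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4])
}

#' Read survival / recovery assay TSVs
#'
#' `read_survival_tsv` expects columns `strain, replicate, day, plated,
#' alive`; `read_recovery_tsv` expects `strain, replicate, days_starved,
#' assay, value`.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not_cols(df, c("strain", "replicate", "day", "plated", "alive"),
                   basename(path))
  if (any(df$alive > df$plated | df$alive < 0))
    stop("need 0 <= alive <= plated in ", basename(path))
  df$replicate <- as.character(df$replicate)
  df
}

#' @rdname read_survival_tsv
#' @export
read_recovery_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not_cols(df, c("strain", "replicate", "days_starved", "assay", "value"),
                   basename(path))
  df
}
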