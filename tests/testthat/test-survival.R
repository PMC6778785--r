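logistic_obs <- function(t50, k, upper = 1, days = seq(1, 29, 2),
                         plated = 200) {
  data.frame(strain = "A", replicate = "1", day = days, plated = plated,
             alive = plated * upper / (1 + exp(k * (days - t50))))
}

test_that("the logistic fit is self-consistent on exact model data", {
  fit <- fit_logistic_survival(logistic_obs(14, 0.5))
  expect_true(fit$converged)
  expect_equal(fit$t50, 14, tolerance = 1e-6)
  expect_equal(fit$k, 0.5, tolerance = 1e-5)
  expect_equal(fit$upper, 1, tolerance = 1e-6)
  # free upper asymptote recovered when survival plateaus below 1
  fit2 <- fit_logistic_survival(logistic_obs(12, 0.8, upper = 0.7))
  expect_equal(fit2$t50, 12, tolerance = 1e-5)
  expect_equal(fit2$upper, 0.7, tolerance = 1e-5)
  # fixed-upper variant pins the asymptote at the earliest-day proportion
  fit3 <- fit_logistic_survival(logistic_obs(12, 0.8, upper = 0.7),
                                fix_upper = TRUE)
  expect_equal(fit3$upper, max(0.7 / (1 + exp(0.8 * (seq(1, 29, 2) - 12)))))
})

test_that("degenerate survival data yields a flagged fit, not a crash", {
  flat <- data.frame(strain = "A", replicate = "1", day = c(1, 5, 9),
                     plated = 100, alive = 100)
  fit <- fit_logistic_survival(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$t50))
  expect_error(fit_logistic_survival(flat[1:2, ]), "3 distinct days")
  expect_error(fit_logistic_survival(transform(flat, alive = 200)),
               "alive <= plated")
  expect_warning(
    fit_logistic_survival(data.frame(strain = "A", replicate = "1",
                                     day = c(1, 3, 5), plated = 100,
                                     alive = c(100, 95, 90))),
    "extrapolation")
})

test_that("median survival is invariant to rescaling the plated counts", {
  sv <- simulate_survival_assay(c(A = 15), 0.5, plated_per_day = 150, seed = 4)
  f1 <- fit_logistic_survival(sv)
  sv2 <- transform(sv, plated = plated * 3, alive = alive * 3)
  f2 <- fit_logistic_survival(sv2)
  expect_equal(f1$t50, f2$t50, tolerance = 1e-9)
})

test_that("strains with identical mean medians give t = 0, p = 1", {
  fits <- data.frame(strain = rep(c("A", "B"), each = 2),
                     replicate = c("1", "2", "1", "2"),
                     t50 = c(10, 12, 10, 12))
  cmp <- compare_median_survival(fits)
  expect_equal(cmp$pairwise$t, 0)
  expect_equal(cmp$pairwise$p, 1)
  expect_equal(cmp$df, 2)
  # a strain with a single replicate is excluded with a warning
  fits2 <- rbind(fits, data.frame(strain = "C", replicate = "1", t50 = 9))
  expect_warning(cmp2 <- compare_median_survival(fits2), "C")
  expect_equal(nrow(cmp2$strain_means), 2L)
})

test_that("Bartlett's test holds its nominal type-I error under the null", {
  set.seed(31)
  reject <- vapply(seq_len(2000), function(i) {
    fits <- data.frame(strain = rep(c("A", "B", "C"), each = 4),
                       replicate = rep(1:4, 3),
                       t50 = rnorm(12, mean = 15, sd = 1))
    suppressWarnings(compare_median_survival(fits)$bartlett_p) < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("a 5-day difference in median survival is detected reliably", {
  # t50 15 vs 10, 4 replicates, binomial scoring noise at 150 worms/day
  hits <- vapply(seq_len(100), function(seed) {
    sv <- simulate_survival_assay(c(A = 15, B = 10), steepness = 0.5,
                                  plated_per_day = 150, n_replicates = 4,
                                  seed = seed)
    fits <- fit_survival_dataset(sv)
    suppressWarnings(compare_median_survival(fits)$pairwise$p) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("recovery measurements normalise to the one-day strain mean", {
  m <- data.frame(strain = c("A", "A", "A", "B", "B"),
                  replicate = 1,
                  days_starved = c(1, 1, 8, 1, 8),
                  assay = "brood_total",
                  value = c(100, 100, 50, 200, 200))
  out <- normalize_recovery(m)
  expect_equal(out$normalized, c(1, 1, 0.5, 1, 1))
  # per-strain mean of normalised one-day values is 1 by construction
  set.seed(12)
  r <- data.frame(strain = rep(c("X", "Y"), each = 8), replicate = 1,
                  days_starved = rep(c(1, 8), 8),
                  assay = rep(c("brood_total", "body_length"), each = 4),
                  value = runif(16, 10, 300))
  rn <- normalize_recovery(r)
  one <- rn[rn$days_starved == 1, ]
  means <- tapply(one$normalized, interaction(one$strain, one$assay,
                                              drop = TRUE), mean)
  expect_equal(unname(as.numeric(means)), rep(1, length(means)))
  expect_error(normalize_recovery(transform(m, value = 0)), "zero")
  expect_error(
    normalize_recovery(data.frame(strain = "A", replicate = 1,
                                  days_starved = 8, assay = "x", value = 1)),
    "baseline")
})

test_that("trait values correlate with median survival as expected", {
  traits <- data.frame(strain = c("A", "B", "C", "D"),
                       trait_value = c(-0.001, 0, 0.001, 0.002))
  fits <- data.frame(strain = c("A", "B", "C", "D"),
                     t50 = 10 + 2000 * traits$trait_value)
  # exactly collinear inputs trip lm's perfect-fit warning; expected here
  r <- suppressWarnings(correlate_trait_with_survival(traits, fits))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2000)
  expect_equal(r$intercept, 10)
  expect_error(correlate_trait_with_survival(traits[1:2, ], fits[1:2, ]),
               ">= 3 strains")
  # permutation null: E[R^2] = 1 / (n - 1)
  set.seed(55)
  n <- 20
  tr <- data.frame(strain = sprintf("S%02d", 1:n), trait_value = rnorm(n))
  sv <- data.frame(strain = sprintf("S%02d", 1:n), t50 = rnorm(n, 12))
  r2 <- vapply(seq_len(1000), function(i) {
    sv$t50 <- sample(sv$t50)
    correlate_trait_with_survival(tr, sv)$r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.01)
})

test_that("survival and recovery TSVs round-trip through the readers", {
  sv <- simulate_survival_assay(c(A = 12, B = 9), 0.5, n_replicates = 2,
                                seed = 3)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write.table(sv, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_survival_tsv(p1), as.data.frame(sv), ignore_attr = TRUE)
  rec <- data.frame(strain = "A", replicate = 1, days_starved = c(1, 8),
                    assay = "brood_total", value = c(250, 120))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_recovery_tsv(p2), rec, ignore_attr = TRUE)
})
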