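test_that("equal selection leaves frequencies unchanged at every day", {
  cfg <- sim_config(n_strains = 5, mortality_rates = rep(0.2, 5),
                    recovery_weights = rep(2, 5), seed = 1)
  truth <- simulate_frequency_trajectories(cfg)
  for (j in seq_len(ncol(truth$frequencies)))
    expect_equal(truth$frequencies[, j], cfg$initial_frequencies,
                 ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(truth$true_trait_values), rep(0, 5), tolerance = 1e-12)
})

test_that("two-strain trajectory matches the hand-computed renormalisation", {
  # f0 = (1/2, 1/2), m = (0, ln 2): at day 1 the second strain halves,
  # leaving 0.5 : 0.25, i.e. (2/3, 1/3) after renormalisation
  cfg <- sim_config(n_strains = 2, initial_frequencies = c(0.5, 0.5),
                    mortality_rates = c(0, log(2)),
                    unique_snv_counts = c(1, 1),
                    sample_days = list("1" = 1), seed = 1)
  truth <- simulate_frequency_trajectories(cfg)
  expect_equal(unname(truth$frequencies[, 1]), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("degenerate pools are rejected", {
  expect_error(sim_config(n_strains = 2, sample_days = list("1" = c(-1, 5))),
               ">= 0")
  expect_error(sim_config(n_strains = 2, recovery_weights = c(0, 0)),
               "empty")
  expect_error(sim_config(n_strains = 2, initial_frequencies = c(0.6, 0.5)),
               "sum to 1")
  expect_error(sim_config(n_strains = 2, mortality_rates = c(-0.1, 0.2)),
               ">= 0")
  # pool numerically extinct at a late day
  cfg <- sim_config(n_strains = 2, mortality_rates = c(1e5, 1e5),
                    sample_days = list("1" = c(1, 20)), seed = 1)
  expect_error(simulate_frequency_trajectories(cfg), "extinct")
})

test_that("library frequencies always sum to 1 and variance grows under selection", {
  # from equal founder proportions, heterogeneous mortality can only spread
  # the distribution: variance is non-decreasing day by day
  for (seed in 1:6) {
    cfg <- sim_config(n_strains = 24, seed = seed,
                      initial_frequencies = rep(1 / 24, 24),
                      sample_days = list("1" = c(0, 5, 10, 20)))
    truth <- simulate_frequency_trajectories(cfg)
    expect_true(all(abs(colSums(truth$frequencies) - 1) < 1e-9))
    v <- apply(truth$frequencies, 2, var)
    expect_true(all(diff(v) >= -1e-12),
                label = sprintf("non-decreasing variance (seed %d)", seed))
  }
  # at the default study scale (96 strains, unequal founders), the day-24
  # distribution is wider and lower-centred than the day-1 one
  for (seed in 1:3) {
    truth <- simulate_frequency_trajectories(sim_config(seed = seed))
    f <- truth$frequencies
    expect_true(all(abs(colSums(f) - 1) < 1e-9))
    expect_gt(var(f[, "2_24"]), var(f[, "2_1"]))
    expect_lt(median(f[, "2_24"]), median(f[, "2_1"]))
  }
})

test_that("count tables are deterministic given the seed", {
  cfg <- sim_config(n_strains = 6, seed = 11)
  truth <- simulate_frequency_trajectories(cfg)
  expect_identical(simulate_count_table(truth), simulate_count_table(truth))
})

test_that("absent strains yield zero alternative reads", {
  cfg <- sim_config(n_strains = 2, initial_frequencies = c(1, 0),
                    mortality_rates = c(0, 0),
                    unique_snv_counts = c(3, 3),
                    sample_days = list("1" = c(1, 7)), seed = 5)
  truth <- simulate_frequency_trajectories(cfg)
  ct <- as.data.frame(simulate_count_table(truth))
  s2 <- ct$strain == "S002"
  expect_true(all(ct[s2, c("1_1_alt", "1_7_alt")] == 0))
})

test_that("simulated alt counts have the analytic Poisson mean", {
  # 4000 unique SNVs of one strain at f = 0.01, lambda = 1691:
  # mean alt count should be within 3 standard errors of 16.91
  cfg <- sim_config(n_strains = 2, initial_frequencies = c(0.01, 0.99),
                    mortality_rates = c(0, 0),
                    unique_snv_counts = c(4000, 1),
                    sample_days = list("1" = 0), seed = 42)
  truth <- simulate_frequency_trajectories(cfg)
  ct <- as.data.frame(simulate_count_table(truth))
  alt <- ct[ct$strain == "S001", "1_0_alt"]
  se <- sqrt(16.91 / 4000)
  expect_lt(abs(mean(alt) - 16.91), 3 * se)
})

test_that("binomial-given-total noise model conditions alt on the drawn total", {
  cfg <- sim_config(n_strains = 3, seed = 2,
                    read_noise_model = "binomial_given_total")
  truth <- simulate_frequency_trajectories(cfg)
  ct <- as.data.frame(simulate_count_table(truth))
  expect_true(all(ct$`2_1_alt` >= 0 & ct$`2_1_ref` >= 0))
  expect_identical(simulate_count_table(truth), simulate_count_table(truth))
})

test_that("survival assay draws binomial deaths around the logistic curve", {
  # at d = t50 the survival probability is exactly 1/2
  sv <- simulate_survival_assay(c(A = 15), steepness = 0.5, days = 15,
                                plated_per_day = 100000, seed = 1)
  expect_lt(abs(sv$alive / sv$plated - 0.5), 3 * sqrt(0.25 / 1e5))
  # steep limit: step function around t50
  sv2 <- simulate_survival_assay(c(A = 10), steepness = 1000,
                                 days = c(1, 5, 9, 11, 15),
                                 plated_per_day = 50, seed = 1)
  expect_equal(sv2$alive, c(50, 50, 50, 0, 0))
  expect_error(simulate_survival_assay(c(A = 10), 0.5, days = c(-1, 3)),
               ">= 0")
  expect_error(simulate_survival_assay(c(A = -1), 0.5), "> 0")
})

test_that("logistic fits recover the simulated median survival time", {
  # parameter recovery at t50 = 15, k = 0.5, scoring every other day
  for (plated in c(150, 500)) {
    t50s <- vapply(1:20, function(seed) {
      sv <- simulate_survival_assay(c(A = 15), steepness = 0.5,
                                    days = seq(1, 29, 2),
                                    plated_per_day = plated, seed = seed)
      fit_logistic_survival(sv)$t50
    }, numeric(1))
    expect_lt(abs(mean(t50s) - 15), 1)
  }
})
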