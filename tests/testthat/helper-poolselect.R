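# shared fixture builders (everything generated in code)

# tiny panel from an explicit genotype matrix (variants x strains)
tiny_panel <- function(gt, strains = paste0("S", seq_len(ncol(gt)))) {
  gt <- as.matrix(gt)
  strain_panel(
    strains = strains,
    variants = data.frame(chrom = "I", pos = 100L * seq_len(nrow(gt)),
                          ref = "A", alt = "T"),
    genotypes = gt
  )
}

# one-library count table for a set of unique SNVs owned by given strains
tiny_counts <- function(strains, ref, alt, replicate = "1", day = 1) {
  n <- length(strains)
  pooled_count_table(
    variants = data.frame(chrom = "I", pos = 100L * seq_len(n),
                          ref = "A", alt = "T", strain = strains),
    libraries = data.frame(replicate = replicate, day = day),
    ref_counts = matrix(ref, ncol = 1),
    alt_counts = matrix(alt, ncol = 1)
  )
}

# map owning the variants of tiny_counts / tiny_panel
tiny_map <- function(strains, all_strains = sort(unique(strains))) {
  n <- length(strains)
  assignments <- data.frame(
    chrom = "I", pos = 100L * seq_len(n), ref = "A", alt = "T",
    key = paste("I", 100L * seq_len(n), "A", "T", sep = ":"),
    strain = strains, stringsAsFactors = FALSE)
  per <- table(factor(strains, levels = all_strains))
  structure(list(assignments = assignments,
                 per_strain_count = stats::setNames(as.integer(per),
                                                    all_strains)),
            class = "unique_snv_map")
}

# noise-free simulated experiment: config, truth, counts, map
oracle_experiment <- function(n_strains = 8, seed = 3, ...) {
  cfg <- sim_config(n_strains = n_strains, seed = seed,
                    read_noise_model = "expected", ...)
  truth <- simulate_frequency_trajectories(cfg)
  list(config = cfg, truth = truth,
       counts = simulate_count_table(truth),
       map = identify_unique_snvs(sim_strain_panel(cfg)))
}

# true frequency matched to the rows of a frequency_table
truth_frequencies_for <- function(truth, freqs) {
  truth$frequencies[cbind(freqs$strain,
                          paste(freqs$replicate, freqs$day, sep = "_"))]
}
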