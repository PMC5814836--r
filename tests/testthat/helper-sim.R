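# Shared fixture builders (everything is generated in code).

# One labelled gradient with a single fully labelled OTU chosen at a
# target relative abundance.
spiked_experiment <- function(target_abundance, seed, n_otus = 300,
                              n_control = 0) {
  p0 <- gradient_sim_params(n_otus = n_otus, seed = seed)
  pick <- pick_otu_near_abundance(p0, target_abundance)
  p <- gradient_sim_params(n_otus = n_otus,
                           labelled_otu_ids = pick$otu_id, seed = seed)
  ex <- simulate_gradient_experiment(p, n_labelled = 1,
                                     n_control = n_control)
  list(experiment = ex, otu_id = pick$otu_id,
       relative_abundance = pick$relative_abundance)
}

null_experiment <- function(seed, n_otus = 300, n_control = 0, ...) {
  p <- gradient_sim_params(n_otus = n_otus, seed = seed, ...)
  simulate_gradient_experiment(p, n_labelled = 1, n_control = n_control)
}

# Small spectra set: `n_full` strains with the full indicative-peak
# pattern plus optionally one cyanobacteria-like strain.
small_spectra <- function(seed, n_full = 3, cyano = FALSE,
                          cells_per_level = 8,
                          at_levels = c(0, 5, 10, 25, 50, 100),
                          shift_scale = 1, noise_sd = 0.02) {
  strains <- paste0("strain", seq_len(n_full))
  profiles <- rep("full", n_full)
  if (cyano) {
    strains <- c(strains, "cyanoX")
    profiles <- c(profiles, "cyano")
  }
  peaks <- strain_peak_table(strains, profiles)
  peaks <- lapply(peaks, function(tab) {
    tab$shift_at_full_label <- tab$shift_at_full_label * shift_scale
    tab
  })
  p <- spectra_sim_params(strain_peaks = peaks, at_levels = at_levels,
                          cells_per_level = cells_per_level,
                          noise_sd = noise_sd, seed = seed)
  simulate_spectra(p)
}
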