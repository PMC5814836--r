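# Gradient experiment generator: conservation laws, labelling shifts,
# determinism and parameter validation.

test_that("per-fraction counts and qPCR profile satisfy conservation", {
  p <- gradient_sim_params(n_otus = 40, reads_per_fraction = 1500, seed = 3)
  ex <- simulate_gradient_experiment(p)
  for (g in ex$gradients) {
    expect_equal(unname(rowSums(g$counts)), rep(1500, 20))
    expect_equal(sum(g$qpcr_profile), 1, tolerance = 1e-9)
    expect_true(all(g$counts >= 0))
    expect_equal(sum(normalize_copy_profile(g$copy_quant)), 1,
                 tolerance = 1e-9)
  }
  # per-fraction read vector is honoured
  rv <- seq(500, 2400, length.out = 20)
  p2 <- gradient_sim_params(n_otus = 10, reads_per_fraction = rv, seed = 3)
  g2 <- simulate_gradient_experiment(p2)$gradients[[1]]
  expect_equal(unname(rowSums(g2$counts)), rv)
})

test_that("without label the 15N and control gradients share one distribution", {
  p <- gradient_sim_params(n_otus = 30, seed = 8)  # no labelled OTUs
  ex <- simulate_gradient_experiment(p, n_labelled = 1, n_control = 1)
  g15 <- ex$gradients$G15N_1; g14 <- ex$gradients$G14N_1
  # expected template mass along density is identical
  expect_identical(g15$qpcr_profile, g14$qpcr_profile)
  expect_identical(g15$densities, g14$densities)
  expect_identical(ex$truth, character(0))
})

test_that("a fully labelled OTU bands 0.015 g/ml above the unlabelled centre", {
  # Monte-Carlo oracle: the template-mass-weighted mean density of the
  # labelled OTU (within-fraction read proportion weighted by the qPCR
  # copy profile, the density estimator used for fractionated
  # gradients) recovers, across replicate simulations, the expected
  # profile mean computed independently from Gaussian bin masses.
  shift <- 0.015; sd_d <- 0.008; center <- 1.773 + shift
  p <- gradient_sim_params(n_otus = 5, labelled_otu_ids = "OTU_1",
                           background_spread_fraction = 0, dispersion = 0,
                           reads_per_fraction = 4000, density_sd = sd_d,
                           seed = 1)
  # oracle expectation: truncated-Gaussian mass per equal-width bin
  edges <- seq(1.740, 1.835, length.out = 21)
  mass <- diff(pnorm(edges, center, sd_d))
  mids <- (edges[-1] + edges[-21]) / 2
  expected <- sum(mids * mass) / sum(mass)
  draws <- vapply(1:1000, function(s) {
    p$seed <- s
    g <- simulate_gradient_experiment(p, n_labelled = 1,
                                      n_control = 0)$gradients[[1]]
    w <- g$qpcr_profile * g$counts[, "OTU_1"] / rowSums(g$counts)
    sum(g$densities * w) / sum(w)
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
  # and the expected centre itself sits one full-label shift up
  expect_equal(expected, center, tolerance = 1e-3)
})

test_that("heavy-window mass share rises strictly with label fraction", {
  heavy <- function(lf) {
    p <- gradient_sim_params(n_otus = 1, labelled_otu_ids = "OTU_1",
                             label_fraction_per_otu = lf, seed = 1)
    g <- simulate_gradient_experiment(p, n_labelled = 1,
                                      n_control = 0)$gradients[[1]]
    sum(g$qpcr_profile[g$densities >= 1.785 & g$densities <= 1.820])
  }
  shares <- vapply(seq(0, 1, by = 0.2), heavy, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("fully uniform communities yield no enrichment calls", {
  zero_calls <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    ex <- null_experiment(200 + s, n_otus = 150,
                          background_spread_fraction = 1)
    fit <- sip_enrichment(ex)
    if (length(confirmed_otus(fit)) == 0) zero_calls <- zero_calls + 1
  }
  expect_gte(zero_calls, ceiling(0.9 * n_seeds))
})

test_that("generation is seed-deterministic and validates inputs", {
  p <- gradient_sim_params(n_otus = 25, labelled_otu_ids = "OTU_2", seed = 77)
  a <- simulate_gradient_experiment(p)
  b <- simulate_gradient_experiment(p)
  expect_identical(a$gradients$G15N_1$counts, b$gradients$G15N_1$counts)
  expect_identical(a$gradients$G14N_1$counts, b$gradients$G14N_1$counts)

  bad <- gradient_sim_params(n_otus = 5, labelled_otu_ids = "OTU_99")
  expect_error(simulate_gradient_experiment(bad), "subset")
  expect_error(gradient_sim_params(reads_per_fraction = c(10, 20)),
               "per fraction")
  expect_error(gradient_sim_params(density_range = c(1.8, 1.7)))
  expect_error(gradient_sim_params(label_fraction_per_otu = 1.2))
})

test_that("DNA mode recovers labelled template in the light window", {
  p0 <- gradient_sim_params(n_otus = 150, medium = "DNA", seed = 21)
  pick <- pick_otu_near_abundance(p0, 0.01)
  p <- gradient_sim_params(n_otus = 150, medium = "DNA",
                           labelled_otu_ids = pick$otu_id, seed = 21)
  ex <- simulate_gradient_experiment(p, n_labelled = 1, n_control = 0)
  g <- ex$gradients[[1]]
  prof <- g$counts[, pick$otu_id] / rowSums(g$counts)
  peak_density <- g$densities[which.max(prof)]
  expect_true(peak_density >= 1.665 && peak_density <= 1.695)
  fit <- sip_enrichment(ex)
  expect_true(pick$otu_id %in% confirmed_otus(fit))
})

test_that("experiments round-trip through the TSV writer", {
  p <- gradient_sim_params(n_otus = 15, labelled_otu_ids = "OTU_3", seed = 5)
  ex <- simulate_gradient_experiment(p)
  dir <- withr::local_tempdir()
  paths <- write_sip_experiment(ex, dir)
  ex2 <- read_sip_experiment(paths[["counts"]])
  for (id in names(ex$gradients)) {
    expect_equal(unname(ex2$gradients[[id]]$counts),
                 unname(ex$gradients[[id]]$counts))
    expect_equal(ex2$gradients[[id]]$densities, ex$gradients[[id]]$densities)
  }
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$labelled_otu_ids, "OTU_3")
})
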