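# Isotope-ratio arithmetic: delta notation, atom percent, spike
# unmixing and the acetylene-reduction equivalence.

test_that("delta/ratio/atom-percent conversions are exact and round-trip", {
  expect_equal(delta_from_ratio(N15_REFERENCE_RATIO), 0)
  expect_equal(delta_from_ratio(2 * N15_REFERENCE_RATIO), 1000)
  expect_equal(delta_from_ratio(0), -1000)
  expect_error(delta_from_ratio(-0.1), "non-negative")
  expect_error(ratio_from_delta(-1001), "-1000")

  # closed-form value at natural abundance (delta = 0)
  expect_equal(atom_percent_from_delta(0),
               100 * 0.0036765 / 1.0036765, tolerance = 1e-12)

  # mutual consistency over a wide range, to 1e-12 relative
  deltas <- c(-999, -500, -1, 0, 0.11, 26.5, 1264, 1e5)
  r <- ratio_from_delta(deltas)
  expect_equal(delta_from_ratio(r), deltas, tolerance = 1e-12)
  ap <- atom_percent_from_ratio(r)
  expect_equal(ratio_from_atom_percent(ap), r, tolerance = 1e-12)
  expect_equal(atom_percent_from_delta(deltas), ap, tolerance = 1e-12)
})

test_that("APE matches an independent direct-ratio computation", {
  expect_equal(atom_percent_excess(5, 5), 0)
  # day-5 scale soil enrichment vs natural-abundance control: oracle
  # path computes each atom percent directly from raw ratios
  ref <- N15_REFERENCE_RATIO
  r_s <- (26.5 / 1000 + 1) * ref
  r_c <- (0.5 / 1000 + 1) * ref
  oracle <- 100 * r_s / (1 + r_s) - 100 * r_c / (1 + r_c)
  expect_equal(atom_percent_excess(26.5, 0.5), oracle, tolerance = 1e-10)
  expect_gt(oracle, 0)
  expect_warning(atom_percent_excess(0.1, 0.5), "negative APE")
  # not clamped
  expect_lt(suppressWarnings(atom_percent_excess(0.1, 0.5)), 0)
})

test_that("spike unmixing matches hand arithmetic and inverts mixing", {
  expect_equal(unmix_spike(100, 2.11),
               (100 * 2.11 - 0.11 * 1.11) / 1.00, tolerance = 1e-12)
  expect_equal(unmix_spike(100, 2.11), 210.8779, tolerance = 1e-7)
  # equal-source identity
  expect_equal(unmix_spike(0.11, 5), 0.11)
  # algebraic inverse at assorted masses/deltas
  for (d in c(-50, 0, 835, 1264)) {
    for (nt in c(1.5, 2.11, 10)) {
      ds <- unmix_spike(d, nt)
      expect_equal(mix_with_spike(ds, nt), d, tolerance = 1e-12)
    }
  }
  expect_error(unmix_spike(100, 1.0), "exceed")
})

test_that("ARA equivalence reproduces the worked example and is linear", {
  out <- ara_equivalent(soil_n_content = 500, ape = 0.01,
                        incubation_time = 120, conversion_factor = 3,
                        soil_dry_mass = 1.1, headspace_volume = 13,
                        molar_volume = 24.465, window_h = 4)
  expect_equal(out$n2_fix_rate, 4.1667e-4, tolerance = 1e-4)
  expect_equal(out$ethylene_rate, 1.25e-3, tolerance = 1e-10)
  expect_equal(out$ethylene_ppmv, 10.35, tolerance = 1e-3)

  zero <- ara_equivalent(500, 0, 120, soil_dry_mass = 1.1)
  expect_equal(unlist(zero), c(n2_fix_rate = 0, ethylene_rate = 0,
                               ethylene_ppmv = 0))
  # linear in APE and soil N, inversely linear in time
  dbl <- ara_equivalent(500, 0.02, 120, soil_dry_mass = 1.1,
                        headspace_volume = 13)
  expect_equal(dbl$ethylene_ppmv, 2 * out$ethylene_ppmv, tolerance = 1e-12)
  half_t <- ara_equivalent(500, 0.01, 60, soil_dry_mass = 1.1,
                           headspace_volume = 13)
  expect_equal(half_t$n2_fix_rate, 2 * out$n2_fix_rate, tolerance = 1e-12)
  expect_error(ara_equivalent(500, 0.01, 0), "incubation_time")
})

test_that("isotope time-course simulator honours mean/SEM structure", {
  tc <- data.frame(pool = "RNA", day = 3, mean = 1264, sem = 0)
  sim <- simulate_isotope_timecourse(tc, n_replicates = 5, seed = 1)
  expect_equal(sim$delta_permil, rep(1264, 5))

  # law of large numbers: n = 10000 sample mean within 1% of the mean
  tc2 <- data.frame(pool = "x", day = 1, mean = 100, sem = 10)
  sim2 <- simulate_isotope_timecourse(tc2, n_replicates = 10000, seed = 2)
  expect_lt(abs(mean(sim2$delta_permil) - 100), 1)

  # day-3 biomolecule ranking RNA > protein > bulk > DNA holds in
  # >= 95% of seeds at triplicate replication
  day3 <- data.frame(pool = c("RNA", "protein", "bulk", "DNA"), day = 3,
                     mean = c(1264, 194, 118, 5), sem = c(370, 9, 6, 3))
  ok <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    sim3 <- simulate_isotope_timecourse(day3, n_replicates = 3, seed = s)
    m <- tapply(sim3$delta_permil, sim3$pool, mean)
    if (m["RNA"] > m["protein"] && m["protein"] > m["bulk"] &&
        m["bulk"] > m["DNA"]) ok <- ok + 1
  }
  expect_gte(ok, ceiling(0.95 * n_seeds) - 1)
  expect_error(simulate_isotope_timecourse(
    data.frame(pool = "a", day = 1, mean = 1, sem = -1)), "non-negative")
})
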