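# The NB enrichment caller: agreement with reference fits, error
# calibration, power, and the two comparison modes.

test_that("the NB Wald fit matches a glm with fixed NB family", {
  set.seed(9)
  n <- 16
  grp <- rep(c("labelled", "unlabelled"), each = 8)
  for (k in 1:5) {
    s <- exp(rnorm(n, 0, 0.2))
    alpha <- runif(1, 0.05, 0.5)
    mu <- runif(1, 5, 40) * ifelse(grp == "labelled", runif(1, 1, 2), 1)
    y <- MASS::rnegbin(n, mu = mu * s, theta = 1 / alpha)
    if (sum(y[grp == "labelled"]) == 0 || sum(y[grp == "unlabelled"]) == 0)
      next
    res <- test_enrichment(matrix(y, ncol = 1, dimnames = list(NULL, "o")),
                           grp, s, alpha)
    g <- stats::glm(y ~ I(grp == "labelled") + offset(log(s)),
                    family = MASS::negative.binomial(theta = 1 / alpha))
    co <- summary(g, dispersion = 1)$coefficients
    expect_equal(res$wald_stat, co[2, 1] / co[2, 2], tolerance = 1e-5)
    expect_equal(res$wald_p, pnorm(co[2, 1] / co[2, 2], lower.tail = FALSE),
                 tolerance = 1e-4)
  }
})

test_that("Wald p-values agree with a parametric bootstrap oracle", {
  set.seed(42)
  n <- 16
  grp <- rep(c("labelled", "unlabelled"), each = 8)
  B <- 4000
  checked <- 0
  for (k in 1:10) {
    s <- exp(rnorm(n, 0, 0.2))
    alpha <- runif(1, 0.05, 0.4)
    y <- MASS::rnegbin(n, mu = runif(1, 8, 40) * s *
                         ifelse(grp == "labelled", runif(1, 1, 1.5), 1),
                       theta = 1 / alpha)
    obs <- test_enrichment(matrix(y, ncol = 1, dimnames = list(NULL, "o")),
                           grp, s, alpha)
    if (is.na(obs$wald_p) || obs$wald_p < 0.02 || obs$wald_p > 0.9) next
    mu0 <- sum(y) / sum(s)  # H0 fit: one common mean
    Y <- matrix(MASS::rnegbin(B * n, mu = rep(s * mu0, B),
                              theta = 1 / alpha), nrow = n)
    colnames(Y) <- paste0("b", seq_len(B))
    zs <- test_enrichment(Y, grp, s, rep(alpha, B))$wald_stat
    p_boot <- mean(zs >= obs$wald_stat)
    expect_lt(abs(obs$wald_p - p_boot),
              0.1 * p_boot + 3 * sqrt(p_boot * (1 - p_boot) / B))
    checked <- checked + 1
  }
  expect_gte(checked, 4)
})

test_that("null gradients produce (almost) no calls at FDR 0.1", {
  zero_runs <- 0
  any_enriched <- 0
  n_seeds <- 15
  for (s in seq_len(n_seeds)) {
    fit <- sip_enrichment(null_experiment(500 + s, n_otus = 200))
    r <- fit$results[[1]]
    if (sum(r$model_enriched) > 0) any_enriched <- any_enriched + 1
    if (length(confirmed_otus(fit)) == 0) zero_runs <- zero_runs + 1
  }
  expect_gte(zero_runs, ceiling(0.9 * n_seeds))
  # seeds with any model-enriched OTU stay near the BH nominal level
  expect_lte(any_enriched / n_seeds, 0.25)
})

test_that("an abundant strongly-shifted OTU is recovered reliably", {
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    sp <- spiked_experiment(0.01, 700 + s, n_otus = 200)
    fit <- sip_enrichment(sp$experiment)
    r <- fit$results[[1]]
    if (sp$otu_id %in% confirmed_otus(fit)) hits <- hits + 1
    # specificity: spiked OTU dominates the call set
    expect_lte(sum(r$model_enriched), 3)
  }
  expect_gte(hits, 9)
})

test_that("fold-change threshold corresponds to ~1.19-fold enrichment", {
  expect_equal(round(2^0.25, 2), 1.19)
})

test_that("degenerate inputs raise informative errors", {
  cnt <- matrix(rpois(40, 10), 4, 10,
                dimnames = list(NULL, paste0("o", 1:10)))
  sf <- rep(1, 4)
  disp <- rep(0.1, 10)
  expect_error(test_enrichment(cnt, c("labelled", rep("unlabelled", 3)),
                               sf, disp), "fewer than 2")
  z <- cnt; z[1:2, ] <- 0L
  expect_error(test_enrichment(z, rep(c("labelled", "unlabelled"), each = 2),
                               sf, disp), "all-zero")
  expect_error(test_enrichment(cnt, rep(c("heavy", "light"), each = 2),
                               sf, disp), "labelled")
})

test_that("reported log2 fold change stays finite via the pseudo-mean", {
  cnt <- cbind(o1 = c(10L, 12L, 0L, 0L), o2 = c(0L, 0L, 8L, 9L))
  grp <- rep(c("labelled", "unlabelled"), each = 2)
  res <- test_enrichment(cnt, grp, rep(1, 4), c(0.1, 0.1))
  expect_true(all(is.finite(res$log2_fold_change)))
  expect_gt(res$log2_fold_change[1], 0)
  expect_lt(res$log2_fold_change[2], 0)
  # an OTU absent from labelled fractions can never be called enriched
  expect_equal(res$wald_p[2], 1)
})

test_that("vs-control mode recovers spikes and is null on self-comparison", {
  hits <- 0
  n_seeds <- 8
  for (s in seq_len(n_seeds)) {
    sp <- spiked_experiment(0.01, 900 + s, n_otus = 150, n_control = 1)
    fit <- sip_enrichment(sp$experiment, mode = "vs-control")
    if (sp$otu_id %in% confirmed_otus(fit)) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.8 * n_seeds))

  # comparing a control gradient against itself yields no calls
  ex <- null_experiment(999, n_otus = 150, n_control = 1)
  ex$gradients$G15N_1$counts <- ex$gradients$G14N_1$counts
  fit0 <- sip_enrichment(ex, mode = "vs-control")
  expect_equal(sum(fit0$results[[1]]$model_enriched), 0)
})

test_that("consolidation applies abundance and hump gates across gradients", {
  base <- data.frame(otu_id = c("a", "b", "c"),
                     base_mean = c(0.8, 50, 30),
                     log2_fold_change = c(2, 1.5, 0.1),
                     wald_stat = 3, wald_p = 0.001, padj = 0.01,
                     model_enriched = c(TRUE, TRUE, FALSE),
                     hump_pass = c(TRUE, TRUE, TRUE),
                     peak_density = 1.79,
                     abundance_pass = c(FALSE, TRUE, TRUE),
                     confirmed = NA,
                     gradient_id = "G1", label_status = "15N")
  out <- consolidate_calls(list(G1 = base), min_base_mean = 1.25)
  expect_equal(out$confirmed, "b")   # "a" fails abundance despite enrichment
  expect_equal(nrow(out$summary), 3)
  none <- base; none$model_enriched <- FALSE
  expect_equal(consolidate_calls(list(G1 = none))$confirmed, character(0))
})

test_that("fit object methods expose the expected views", {
  sp <- spiked_experiment(0.01, 31, n_otus = 100, n_control = 1)
  fit <- sip_enrichment(sp$experiment)
  expect_s3_class(fit, "sip_fit")
  cf <- coef(fit)
  expect_equal(rownames(cf), names(fit$results))
  expect_true(sp$otu_id %in% colnames(cf))
  s <- summary(fit)
  expect_s3_class(s, "summary.sip_fit")
  expect_true(sp$otu_id %in% s$confirmed)
  expect_output(print(fit), "confirmed")
  expect_output(print(s), "Per-gradient")
  # plotting runs silently to a null device
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
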