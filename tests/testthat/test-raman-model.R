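# Random-forest labelling models: confusion metrics, OOB behaviour,
# leave-one-strain-out generalisation.

test_that("confusion metrics reproduce the reference two-class matrix", {
  cm <- label_confusion(885, 20, 101, 371)
  m <- confusion_metrics(cm)
  expect_equal(m$overall_error, 121 / 1377, tolerance = 1e-12)
  expect_equal(round(100 * m$overall_error, 2), 8.79)
  expect_equal(unname(m$per_class_error["labelled"]), 20 / 905,
               tolerance = 1e-12)
  expect_equal(unname(m$per_class_error["unlabelled"]), 101 / 472,
               tolerance = 1e-12)
  expect_equal(round(unname(m$per_class_error), 2), c(0.02, 0.21))
  # rate definitions divide by the *predicted* class totals
  expect_equal(m$false_pos_rate, 101 / 986, tolerance = 1e-12)
  expect_equal(m$false_neg_rate, 20 / 391, tolerance = 1e-12)
  expect_equal(m$sensitivity, 885 / 905, tolerance = 1e-12)
  expect_equal(m$specificity, 371 / 472, tolerance = 1e-12)
})

test_that("metric identities and degenerate denominators behave", {
  cm <- label_confusion(42, 0, 0, 17)
  m <- confusion_metrics(cm)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$overall_error, 0)
  # complements: class error + matching accuracy = 1
  cm2 <- label_confusion(30, 10, 5, 55)
  m2 <- confusion_metrics(cm2)
  expect_equal(unname(m2$per_class_error["labelled"]) + m2$sensitivity, 1)
  expect_equal(unname(m2$per_class_error["unlabelled"]) + m2$specificity, 1)
  # nothing predicted labelled: FPR undefined, flagged not crashed
  m3 <- confusion_metrics(label_confusion(0, 10, 0, 20))
  expect_true(is.na(m3$false_pos_rate))
  expect_true("false_pos_rate" %in% m3$undefined)
  expect_error(label_confusion(-1, 0, 0, 5), "non-negative")
})

test_that("two-class OOB error tracks the simulated peak shift", {
  # strong shifts: nearly separable
  sim_big <- small_spectra(seed = 5, n_full = 3, cells_per_level = 6)
  big <- train_two_class_model(preprocess_spectra(sim_big),
                               n_trees = 250, seed = 2)
  expect_lte(big$oob_error, 0.10)

  # no shift, balanced classes: chance level
  sim0 <- small_spectra(seed = 5, n_full = 3, cells_per_level = 6,
                        at_levels = c(0, 5, 10, 25), shift_scale = 0)
  m0 <- train_two_class_model(preprocess_spectra(sim0),
                              n_trees = 250, seed = 2)
  expect_gt(m0$oob_error, 0.40)
  expect_lt(m0$oob_error, 0.60)

  # determinism under a fixed seed
  rep1 <- train_two_class_model(preprocess_spectra(sim_big),
                                n_trees = 100, seed = 7)
  rep2 <- train_two_class_model(preprocess_spectra(sim_big),
                                n_trees = 100, seed = 7)
  expect_identical(rep1$oob_confusion, rep2$oob_confusion)

  one_class <- sim_big
  keep <- one_class$meta$at_percent >= 10
  one_class$meta <- one_class$meta[keep, ]
  one_class$intensity <- one_class$intensity[keep, ]
  expect_error(train_two_class_model(one_class), "both")
})

test_that("multilevel model confuses adjacent levels most, 0 vs 5 worst", {
  sim <- small_spectra(seed = 6, n_full = 3, cells_per_level = 6)
  ml <- train_multilevel_model(preprocess_spectra(sim), n_trees = 250,
                               seed = 3)
  conf <- ml$oob_confusion
  lv <- as.numeric(rownames(conf))
  off <- conf; diag(off) <- 0
  if (sum(off) > 0) {
    # distance-1-in-rank confusions dominate the off-diagonal
    rankdist <- abs(outer(rank(lv), rank(lv), "-"))
    adjacent <- sum(off[rankdist == 1]) / sum(off)
    expect_gte(adjacent, 0.5)
    # the 0 vs 5 at% pair (sub-grid shift difference) is the worst pair
    pairsum <- conf["0", "5"] + conf["5", "0"]
    other <- off; other["0", "5"] <- 0; other["5", "0"] <- 0
    expect_gte(pairsum, max(other))
  }
  expect_error(train_multilevel_model(
    small_spectra(seed = 1, n_full = 1, cells_per_level = 2,
                  at_levels = 0)), "two labelling levels")
})

test_that("leave-one-strain-out degrades for a peak-deficient strain", {
  sim <- small_spectra(seed = 8, n_full = 3, cyano = TRUE,
                       cells_per_level = 6)
  pre <- preprocess_spectra(sim)
  full <- loso_evaluate(pre, "strain1", n_trees = 250, seed = 4)
  expect_gte(full$metrics$sensitivity, 0.85)
  expect_gte(full$metrics$specificity, 0.85)

  cy <- loso_evaluate(pre, "cyanoX", n_trees = 250, seed = 4)
  expect_lt(min(cy$metrics$sensitivity, cy$metrics$specificity), 0.60)

  expect_error(loso_evaluate(pre, "nope"), "unknown strain")
})

test_that("the LOSO harness returns one confusion matrix per strain", {
  sim <- small_spectra(seed = 12, n_full = 3, cells_per_level = 3,
                       at_levels = c(0, 100))
  res <- loso_evaluate_all(preprocess_spectra(sim), n_trees = 100, seed = 1)
  expect_equal(nrow(res), 3)
  confs <- attr(res, "confusions")
  expect_equal(length(confs), 3)
  expect_true(all(vapply(confs, inherits, TRUE, "label_confusion")))
})
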