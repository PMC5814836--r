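# Random-forest classification of 15N labelling from single-cell Raman
# spectra, with out-of-bag confusion matrices, leave-one-strain-out
# evaluation and the metric definitions used for SIP-Raman screening.

# Two-class mapping of cultivation labelling levels: 0 and 5 at% 15N are
# operationally unlabelled, 10-100 at% labelled.
label_class <- function(at_percent) {
  factor(ifelse(at_percent >= 10, "labelled", "unlabelled"),
         levels = c("labelled", "unlabelled"))
}

#' Build a 2x2 labelling confusion matrix
#'
#' @param tp labelled cells predicted labelled.
#' @param fn labelled cells predicted unlabelled.
#' @param fp unlabelled cells predicted labelled.
#' @param tn unlabelled cells predicted unlabelled.
#' @return object of class `label_confusion`.
#' @export
label_confusion <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (sum(counts) == 0) stop("confusion matrix is empty")
  structure(as.list(counts), class = "label_confusion")
}

#' @export
print.label_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("labelled", "unlabelled"),
                              predicted = c("labelled", "unlabelled")))
  print(m)
  mets <- confusion_metrics(x)
  cat(sprintf("overall error: %.2f%%\n", 100 * mets$overall_error))
  invisible(x)
}

#' Classification metrics of a labelling confusion matrix
#'
#' Definitions follow single-cell SIP-Raman screening practice:
#' the false-positive rate divides the falsely-labelled calls by all
#' cells *predicted* labelled, and the false-negative rate divides the
#' falsely-unlabelled calls by all cells *predicted* unlabelled (a
#' false-omission rate; the conventional miss rate is additionally
#' reported as `miss_rate`). Sensitivity and specificity are the usual
#' per-actual-class accuracies, and the per-class errors their
#' complements. Metrics whose denominator is zero are returned as `NA`
#' with the affected names listed in `undefined`.
#'
#' @param cm a [label_confusion()] object.
#' @return list of class `label_metrics` with `false_pos_rate`,
#'   `false_neg_rate`, `miss_rate`, `sensitivity`, `specificity`,
#'   `per_class_error` (named: labelled, unlabelled), `overall_error`,
#'   `undefined`.
#' @export
#' @examples
#' confusion_metrics(label_confusion(885, 20, 101, 371))$overall_error
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "label_confusion"))
  div <- function(num, den) if (den > 0) num / den else NA_real_
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  out <- list(
    false_pos_rate = div(fp, tp + fp),
    false_neg_rate = div(fn, fn + tn),
    miss_rate = div(fn, tp + fn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    per_class_error = c(labelled = div(fn, tp + fn),
                        unlabelled = div(fp, fp + tn)),
    overall_error = (fn + fp) / (tp + fn + fp + tn))
  flat <- unlist(out)
  out$undefined <- names(flat)[is.na(flat)]
  class(out) <- "label_metrics"
  out
}

#' @export
print.label_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("false-pos rate %.1f%%, false-neg rate %.1f%% (miss rate %.1f%%)\n",
              100 * x$false_pos_rate, 100 * x$false_neg_rate,
              100 * x$miss_rate))
  cat(sprintf("overall error %.2f%%\n", 100 * x$overall_error))
  invisible(x)
}

.rf_matrix <- function(spectra) {
  x <- spectra$intensity
  colnames(x) <- paste0("wn", spectra$wavenumbers)
  x
}

#' Train the two-class (labelled vs unlabelled) random forest
#'
#' Cells at 0 and 5 at% 15N form the unlabelled class, cells at 10-100
#' at% the labelled class. Returns the forest together with its
#' out-of-bag confusion matrix and metrics.
#'
#' @param spectra a preprocessed `raman_spectra` object.
#' @param n_trees trees in the forest (default 500).
#' @param seed integer seed (forests are seeded for reproducibility).
#' @return list of class `raman_rf2` with `model`, `oob_confusion`
#'   (a `label_confusion`), `oob_metrics`, `oob_error`.
#' @export
train_two_class_model <- function(spectra, n_trees = 500, seed = 1L) {
  stopifnot(inherits(spectra, "raman_spectra"))
  y <- label_class(spectra$meta$at_percent)
  if (nlevels(droplevels(y)) < 2)
    stop("both labelled and unlabelled cells are required")
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(.rf_matrix(spectra), y, ntree = n_trees)
  cmat <- rf$confusion
  cm <- label_confusion(tp = cmat["labelled", "labelled"],
                        fn = cmat["labelled", "unlabelled"],
                        fp = cmat["unlabelled", "labelled"],
                        tn = cmat["unlabelled", "unlabelled"])
  mets <- confusion_metrics(cm)
  structure(list(model = rf, oob_confusion = cm, oob_metrics = mets,
                 oob_error = mets$overall_error),
            class = "raman_rf2")
}

#' Train the multi-level (at% 15N) random forest
#'
#' Classifies cells into their labelling level (0, 5, 10, 25, 50, 100
#' at% 15N, or whichever levels are present).
#'
#' @inheritParams train_two_class_model
#' @return list of class `raman_rf_multi` with `model`,
#'   `oob_confusion` (levels x levels count matrix) and `oob_error`.
#' @export
train_multilevel_model <- function(spectra, n_trees = 500, seed = 1L) {
  stopifnot(inherits(spectra, "raman_spectra"))
  y <- factor(spectra$meta$at_percent)
  if (nlevels(droplevels(y)) < 2)
    stop("at least two labelling levels are required")
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(.rf_matrix(spectra), y, ntree = n_trees)
  conf <- rf$confusion[, levels(y), drop = FALSE]
  structure(list(model = rf, oob_confusion = conf,
                 oob_error = sum(conf[row(conf) != col(conf)]) / sum(conf)),
            class = "raman_rf_multi")
}

#' Leave-one-strain-out labelling prediction
#'
#' Trains the two-class model on all strains except `held_out_strain`
#' and predicts the labelling of every cell of that strain — the test of
#' whether the classifier generalises to a taxon it has never seen.
#'
#' @param spectra a preprocessed `raman_spectra` object with >= 2
#'   strains besides the held-out one.
#' @param held_out_strain strain id to exclude from training.
#' @inheritParams train_two_class_model
#' @return list with `strain`, `confusion` (a `label_confusion`) and
#'   `metrics`.
#' @export
loso_evaluate <- function(spectra, held_out_strain, n_trees = 500, seed = 1L) {
  stopifnot(inherits(spectra, "raman_spectra"))
  strains <- spectra$meta$strain
  if (!held_out_strain %in% strains)
    stop("unknown strain: ", held_out_strain)
  if (length(unique(strains[strains != held_out_strain])) < 2)
    stop("need at least 2 other strains to train on")
  train_idx <- strains != held_out_strain
  y_train <- label_class(spectra$meta$at_percent[train_idx])
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(.rf_matrix(spectra)[train_idx, ],
                                   y_train, ntree = n_trees)
  test_idx <- !train_idx
  pred <- stats::predict(rf, .rf_matrix(spectra)[test_idx, , drop = FALSE])
  actual <- label_class(spectra$meta$at_percent[test_idx])
  cm <- label_confusion(
    tp = sum(actual == "labelled" & pred == "labelled"),
    fn = sum(actual == "labelled" & pred == "unlabelled"),
    fp = sum(actual == "unlabelled" & pred == "labelled"),
    tn = sum(actual == "unlabelled" & pred == "unlabelled"))
  list(strain = held_out_strain, confusion = cm,
       metrics = confusion_metrics(cm))
}

#' Leave-one-strain-out evaluation across every strain
#'
#' @inheritParams train_two_class_model
#' @return data frame with one row per strain (sensitivity, specificity,
#'   false-pos/false-neg rates, overall error); the per-strain
#'   confusion matrices are attached as the `confusions` attribute.
#' @export
loso_evaluate_all <- function(spectra, n_trees = 500, seed = 1L) {
  strains <- unique(spectra$meta$strain)
  evals <- lapply(strains, function(s)
    loso_evaluate(spectra, s, n_trees = n_trees, seed = seed))
  out <- do.call(rbind, lapply(evals, function(e) {
    m <- e$metrics
    data.frame(strain = e$strain, sensitivity = m$sensitivity,
               specificity = m$specificity,
               false_pos_rate = m$false_pos_rate,
               false_neg_rate = m$false_neg_rate,
               overall_error = m$overall_error)
  }))
  attr(out, "confusions") <- stats::setNames(lapply(evals, `[[`, "confusion"),
                                             strains)
  out
}
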