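# Per-gradient negative-binomial differential-abundance calling of
# isotope-labelled OTUs.
#
# Fractions inside the labelled and unlabelled density windows are
# treated as replicate observations of their class. For every OTU a
# two-group NB log-link model (fixed, pre-estimated dispersion) is fitted
# by Fisher scoring; a one-sided Wald test asks whether the OTU is more
# abundant in the labelled fractions, and Benjamini-Hochberg correction
# is applied across OTUs within each gradient.

# Vectorised per-group NB mean fit: solves, for each OTU, the score
# equation sum_j (y_ij - s_j mu_i) / (1 + alpha_i s_j mu_i) = 0 by Newton
# iteration on eta = log(mu). Returns eta and the Fisher information
# I = sum_j s_j mu_i / (1 + alpha_i s_j mu_i) in eta.
.nb_group_fit <- function(Y, s, alpha, max_iter = 50, tol = 1e-10) {
  n_otu <- ncol(Y)
  tot <- colSums(Y)
  zero <- tot == 0
  eta <- log(pmax(tot, 0.5) / sum(s))   # Poisson MLE start (pseudo for 0)
  for (it in seq_len(max_iter)) {
    mu <- outer(s, exp(eta))                         # samples x OTUs
    amu <- sweep(mu, 2, alpha, "*")
    f <- colSums((Y - mu) / (1 + amu))
    aY <- sweep(Y, 2, alpha, "*")
    fp <- -colSums(mu * (1 + aY) / (1 + amu)^2)
    step <- f / fp
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 2), -2)                  # damped Newton
    eta <- eta - step
    if (it > 1 && (!any(!zero) || max(abs(step[!zero])) < tol)) break
  }
  eta[zero] <- log(0.5 / mean(s))  # pseudo-mean for all-zero groups
  mu <- outer(s, exp(eta))
  amu <- sweep(mu, 2, alpha, "*")
  info <- colSums(mu / (1 + amu))
  list(eta = eta, info = info, zero = zero)
}

#' One-sided NB Wald test of labelled-fraction enrichment for each OTU
#'
#' Low-level engine behind [sip_enrichment()]. Fits, per OTU, a
#' two-group negative-binomial model with log link and size-factor
#' offsets (dispersion fixed at its pre-estimated value) and tests
#' H0: log2 fold change (labelled / unlabelled) <= 0 against > 0 with a
#' Wald test based on the expected information. P-values are BH-adjusted
#' across OTUs. The reported `log2_fold_change` adds a pseudo-mean of
#' 0.5 normalised counts to both group means so it stays finite; the
#' test statistic itself uses the NB likelihood.
#'
#' @param counts fractions x OTUs matrix (only fractions belonging to
#'   one of the two classes).
#' @param classes character vector (`"labelled"`/`"unlabelled"`), one
#'   per row of `counts`.
#' @param size_factors per-fraction size factors.
#' @param dispersions per-OTU final dispersions (NA marks untestable
#'   OTUs).
#' @param lfc_threshold post-hoc log2 fold-change filter (default 0.25,
#'   i.e. ~1.19-fold enrichment).
#' @param alpha BH false discovery rate (default 0.1).
#' @return data frame (one row per OTU): `otu_id`, `base_mean`,
#'   `log2_fold_change`, `wald_stat`, `wald_p`, `padj`,
#'   `model_enriched`.
#' @export
test_enrichment <- function(counts, classes, size_factors, dispersions,
                            lfc_threshold = 0.25, alpha = 0.1) {
  stopifnot(is.matrix(counts), length(classes) == nrow(counts),
            length(size_factors) == nrow(counts),
            length(dispersions) == ncol(counts))
  if (!all(classes %in% c("labelled", "unlabelled")))
    stop("classes must be 'labelled' or 'unlabelled'")
  for (cl in c("labelled", "unlabelled")) {
    idx <- classes == cl
    if (sum(idx) < 2) stop("class '", cl, "' has fewer than 2 fractions")
    if (all(counts[idx, , drop = FALSE] == 0))
      stop("class '", cl, "' has all-zero counts for every OTU")
  }
  a <- dispersions
  testable <- is.finite(a)
  a_fit <- ifelse(testable, a, 1e-8)
  iL <- classes == "labelled"; iU <- classes == "unlabelled"
  fitL <- .nb_group_fit(counts[iL, , drop = FALSE], size_factors[iL], a_fit)
  fitU <- .nb_group_fit(counts[iU, , drop = FALSE], size_factors[iU], a_fit)
  norm <- sweep(counts, 1, size_factors, "/")
  base_mean <- colMeans(norm)
  muL <- exp(fitL$eta); muU <- exp(fitU$eta)
  lfc <- log2((muL + 0.5) / (muU + 0.5))
  se <- sqrt(1 / fitL$info + 1 / fitU$info)
  z <- (fitL$eta - fitU$eta) / se
  p <- stats::pnorm(z, lower.tail = FALSE)
  p[fitL$zero] <- 1          # no evidence of enrichment without labelled reads
  p[!testable] <- NA
  padj <- rep(NA_real_, length(p))
  padj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(otu_id = colnames(counts), base_mean = base_mean,
             log2_fold_change = lfc, wald_stat = z, wald_p = p,
             padj = padj,
             model_enriched = !is.na(padj) & padj < alpha &
               lfc > lfc_threshold,
             row.names = NULL)
}

#' Hump-shape confirmation of a candidate labelled OTU
#'
#' Formalises the visual check that a truly labelled OTU shows a
#' unimodal ("hump-shaped") normalised-abundance profile peaking inside
#' the labelled density window: the maximum of a `smooth`-fraction
#' moving average must lie inside the labelled window and exceed the
#' profile's median across the whole gradient by at least
#' `prominence_factor`.
#'
#' @param profile normalised abundance per fraction (>= 5 fractions).
#' @param densities fraction densities (g/ml), same order as `profile`.
#' @param windows a [density_windows()] object.
#' @param smooth moving-average width in fractions (odd; default 3).
#' @param prominence_factor required peak/median ratio (default 2).
#' @return list with `pass`, `peak_density` and `reason`.
#' @export
hump_shape_diagnostic <- function(profile, densities, windows, smooth = 3,
                                  prominence_factor = 2) {
  stopifnot(length(profile) == length(densities), length(profile) >= 5,
            inherits(windows, "density_windows"))
  if (all(profile == 0))
    return(list(pass = FALSE, peak_density = NA_real_,
                reason = "all-zero profile"))
  k <- min(smooth, length(profile))
  sm <- stats::filter(profile, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  # edges keep the raw values where the window does not fit
  sm[is.na(sm)] <- profile[is.na(sm)]
  peak_i <- which.max(sm)
  peak_density <- densities[peak_i]
  wl <- windows$labelled
  in_window <- peak_density >= wl[1] & peak_density <= wl[2]
  med <- stats::median(profile)
  prominent <- if (med > 0) sm[peak_i] >= prominence_factor * med
               else sm[peak_i] > 0
  pass <- in_window && prominent
  reason <- if (pass) "ok"
            else if (!in_window) "peak outside labelled window"
            else "peak not prominent over gradient median"
  list(pass = pass, peak_density = peak_density, reason = reason)
}

#' Fit the SIP enrichment model to every gradient of an experiment
#'
#' The central fitting function: filters sparse OTUs jointly across all
#' fractions, then for each gradient classifies fractions by density,
#' estimates size factors and dispersions from that gradient's usable
#' fractions, fits the two-group NB model per OTU, applies the one-sided
#' Wald test with BH correction, and runs the hump-shape and abundance
#' confirmations. In `"vs-control"` mode, the labelled-window fractions
#' of each 15N gradient are instead compared against the labelled-window
#' fractions of a control gradient.
#'
#' @param experiment a `sip_experiment` (from
#'   [simulate_gradient_experiment()] or [read_sip_experiment()]).
#' @param windows a [density_windows()] object; defaults to
#'   [rna_windows()] or [dna_windows()] according to the experiment's
#'   medium.
#' @param mode `"within-gradient"` (labelled vs unlabelled fractions of
#'   the same gradient; default) or `"vs-control"` (labelled-window
#'   fractions of 15N vs control gradients).
#' @param alpha BH false discovery rate (default 0.1).
#' @param lfc_threshold log2 fold-change filter (default 0.25).
#' @param min_total,min_prevalence sparse-OTU filter thresholds
#'   (defaults 10 reads, 20% of samples).
#' @param min_base_mean minimum mean normalised count for a confirmed
#'   call (default 1.25).
#' @param hump_smooth,hump_prominence hump-diagnostic parameters.
#' @param control_id (vs-control mode) id of the control gradient;
#'   defaults to the first `14N-control` gradient.
#' @return an object of class `sip_fit`; see [summary.sip_fit()],
#'   [confirmed_otus()], [coef.sip_fit()], [plot.sip_fit()].
#' @export
#' @examples
#' p <- gradient_sim_params(n_otus = 60, labelled_otu_ids = "OTU_1",
#'                          reads_per_fraction = 2000, seed = 42)
#' fit <- sip_enrichment(simulate_gradient_experiment(p))
#' confirmed_otus(fit)
sip_enrichment <- function(experiment, windows = NULL,
                           mode = c("within-gradient", "vs-control"),
                           alpha = 0.1, lfc_threshold = 0.25,
                           min_total = 10, min_prevalence = 0.20,
                           min_base_mean = 1.25,
                           hump_smooth = 3, hump_prominence = 2,
                           control_id = NULL) {
  stopifnot(inherits(experiment, "sip_experiment"))
  mode <- match.arg(mode)
  grads <- experiment$gradients
  if (is.null(windows)) {
    medium <- grads[[1]]$medium
    windows <- if (identical(medium, "DNA")) dna_windows() else rna_windows()
  }
  all_counts <- do.call(rbind, lapply(grads, `[[`, "counts"))
  filt <- filter_sparse_otus(all_counts, min_total, min_prevalence)
  keep <- filt$kept
  if (!length(keep)) stop("no OTU survives the sparsity filter")

  fit_one <- function(g, counts2, classes2, sf, disp) {
    res <- test_enrichment(counts2, classes2, sf, disp$final_dispersion,
                           lfc_threshold, alpha)
    # per-OTU library-size-normalised profile over the whole gradient
    libsize <- pmax(rowSums(g$counts), 1)
    hump <- vapply(keep, function(o) {
      prof <- g$counts[, o] / libsize
      hd <- hump_shape_diagnostic(prof, g$densities, windows,
                                  hump_smooth, hump_prominence)
      c(pass = as.numeric(hd$pass), peak = hd$peak_density)
    }, numeric(2))
    res$hump_pass <- hump["pass", ] > 0
    res$peak_density <- hump["peak", ]
    res$abundance_pass <- res$base_mean >= min_base_mean
    res$confirmed <- res$model_enriched & res$abundance_pass & res$hump_pass
    res$gradient_id <- g$gradient_id
    res$label_status <- g$label_status
    res
  }

  results <- list()
  if (mode == "within-gradient") {
    for (g in grads) {
      cls <- assign_fraction_classes(g$densities, windows, g$gradient_id)
      use <- cls != "excluded"
      counts2 <- g$counts[use, keep, drop = FALSE]
      sf <- estimate_size_factors(counts2)
      disp <- estimate_dispersions(counts2, sf)
      results[[g$gradient_id]] <- fit_one(g, counts2, cls[use], sf, disp)
    }
  } else {
    is_ctrl <- vapply(grads, function(g) g$label_status == "14N-control",
                      logical(1))
    if (is.null(control_id)) {
      if (!any(is_ctrl)) stop("vs-control mode needs a 14N-control gradient")
      control_id <- names(grads)[which(is_ctrl)[1]]
    }
    ctrl <- grads[[control_id]]
    cls_c <- assign_fraction_classes(ctrl$densities, windows, control_id)
    for (g in grads[names(grads) != control_id & !is_ctrl]) {
      cls_g <- assign_fraction_classes(g$densities, windows, g$gradient_id)
      if (!any(cls_g == "labelled") || !any(cls_c == "labelled"))
        stop("empty labelled window in ", g$gradient_id, " or ", control_id)
      counts2 <- rbind(g$counts[cls_g == "labelled", keep, drop = FALSE],
                       ctrl$counts[cls_c == "labelled", keep, drop = FALSE])
      classes2 <- c(rep("labelled", sum(cls_g == "labelled")),
                    rep("unlabelled", sum(cls_c == "labelled")))
      sf <- estimate_size_factors(counts2)
      disp <- estimate_dispersions(counts2, sf)
      results[[g$gradient_id]] <- fit_one(g, counts2, classes2, sf, disp)
    }
  }

  structure(list(results = results, windows = windows, mode = mode,
                 alpha = alpha, lfc_threshold = lfc_threshold,
                 min_base_mean = min_base_mean,
                 filter_report = filt$report, kept_otus = keep,
                 experiment = experiment,
                 call = match.call()),
            class = "sip_fit")
}

#' Consolidate per-gradient enrichment results into confirmed calls
#'
#' An OTU is confirmed if, in at least one gradient, it is
#' model-enriched AND its mean normalised count passes `min_base_mean`
#' AND its density profile passes the hump-shape check. Also returns the
#' mean log2 fold change of each OTU across gradients (and per-phylum
#' means when a taxonomy is supplied).
#'
#' @param results list of per-gradient result data frames (as inside a
#'   `sip_fit`).
#' @param min_base_mean abundance threshold (default 1.25).
#' @param taxonomy optional data frame with columns `otu_id`, `phylum`.
#' @return list with `confirmed` (character vector), `summary` (per-OTU
#'   mean log2FC and flags) and optionally `phylum_summary`.
#' @export
consolidate_calls <- function(results, min_base_mean = 1.25, taxonomy = NULL) {
  stopifnot(length(results) >= 1)
  all_res <- do.call(rbind, results)
  conf_rows <- all_res$model_enriched & all_res$hump_pass &
    all_res$base_mean >= min_base_mean
  confirmed <- sort(unique(all_res$otu_id[conf_rows]))
  summary <- stats::aggregate(
    cbind(mean_log2fc = log2_fold_change, base_mean = base_mean) ~ otu_id,
    data = all_res, FUN = mean)
  summary$n_gradients_enriched <-
    as.integer(stats::aggregate(model_enriched ~ otu_id, data = all_res,
                                FUN = sum)$model_enriched)
  summary$confirmed <- summary$otu_id %in% confirmed
  out <- list(confirmed = confirmed, summary = summary)
  if (!is.null(taxonomy)) {
    m <- merge(summary, taxonomy[, c("otu_id", "phylum")], by = "otu_id",
               all.x = TRUE)
    out$phylum_summary <- stats::aggregate(mean_log2fc ~ phylum, data = m,
                                           FUN = mean)
  }
  out
}

#' Confirmed labelled OTUs of a fitted SIP model
#' @param fit a `sip_fit`.
#' @param labelled_only consider only 15N gradients (default TRUE);
#'   control gradients are a negative control and should contribute no
#'   calls.
#' @return character vector of confirmed OTU ids.
#' @export
confirmed_otus <- function(fit, labelled_only = TRUE) {
  stopifnot(inherits(fit, "sip_fit"))
  res <- fit$results
  if (labelled_only)
    res <- Filter(function(r) r$label_status[1] == "15N", res)
  if (!length(res)) return(character())
  consolidate_calls(res, fit$min_base_mean)$confirmed
}

#' @export
print.sip_fit <- function(x, ...) {
  cat("SIP enrichment fit (", x$mode, " mode)\n", sep = "")
  cat("  OTUs tested: ", length(x$kept_otus), " (",
      sum(x$filter_report$removed), " removed by sparsity filter)\n", sep = "")
  cat("  FDR ", x$alpha, ", log2FC > ", x$lfc_threshold,
      " (~", round(2^x$lfc_threshold, 2), "-fold), base mean >= ",
      x$min_base_mean, "\n", sep = "")
  for (id in names(x$results)) {
    r <- x$results[[id]]
    cat("  ", id, " [", r$label_status[1], "]: ",
        sum(r$model_enriched), " model-enriched, ",
        sum(r$confirmed), " confirmed\n", sep = "")
  }
  conf <- confirmed_otus(x)
  cat("  confirmed labelled OTUs: ",
      if (length(conf)) paste(conf, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' Summary of a fitted SIP enrichment model
#' @param object a `sip_fit`.
#' @param ... unused.
#' @return a list of class `summary.sip_fit` with the consolidated call
#'   table and per-gradient counts.
#' @export
summary.sip_fit <- function(object, ...) {
  cons <- consolidate_calls(
    Filter(function(r) r$label_status[1] == "15N", object$results),
    object$min_base_mean)
  per_gradient <- data.frame(
    gradient_id = names(object$results),
    label_status = vapply(object$results, function(r) r$label_status[1], ""),
    model_enriched = vapply(object$results,
                            function(r) sum(r$model_enriched), 0L),
    confirmed = vapply(object$results, function(r) sum(r$confirmed), 0L),
    row.names = NULL)
  structure(list(per_gradient = per_gradient, calls = cons$summary,
                 confirmed = cons$confirmed, mode = object$mode),
            class = "summary.sip_fit")
}

#' @export
print.summary.sip_fit <- function(x, ...) {
  cat("Per-gradient calls:\n")
  print(x$per_gradient)
  cat("\nConfirmed labelled OTUs:",
      if (length(x$confirmed)) paste(x$confirmed, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Log2 fold changes of a fitted SIP model
#' @param object a `sip_fit`.
#' @param ... unused.
#' @return matrix gradients x OTUs of log2 fold changes.
#' @export
coef.sip_fit <- function(object, ...) {
  do.call(rbind, lapply(object$results, function(r) {
    stats::setNames(r$log2_fold_change, r$otu_id)
  }))
}

#' Plot density profiles of selected OTUs along each gradient
#'
#' Draws the per-fraction proportion of each selected OTU against
#' buoyant density, one panel per gradient, with the labelled window
#' shaded — the plot used to spot non-hump-shaped false positives.
#'
#' @param x a `sip_fit`.
#' @param otus OTU ids (default: the confirmed ones, else the top OTU
#'   by fold change).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, `x`.
#' @export
plot.sip_fit <- function(x, otus = NULL, ...) {
  if (is.null(otus)) otus <- confirmed_otus(x)
  if (!length(otus)) {
    r1 <- x$results[[1]]
    otus <- r1$otu_id[which.max(r1$log2_fold_change)]
  }
  grads <- x$experiment$gradients[names(x$results)]
  old <- graphics::par(mfrow = c(1, length(grads)))
  on.exit(graphics::par(old))
  for (g in grads) {
    prof <- sapply(otus, function(o)
      g$counts[, o] / pmax(sum(g$counts[, o]), 1))
    graphics::matplot(g$densities, prof, type = "b", pch = 1,
                      xlab = "buoyant density (g/ml)",
                      ylab = "proportion of OTU reads",
                      main = g$gradient_id, ...)
    wl <- x$windows$labelled
    graphics::rect(wl[1], -1, wl[2], 2, col = grDevices::adjustcolor("red", 0.1),
                   border = NA)
  }
  invisible(x)
}
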