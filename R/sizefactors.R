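# Sparse-OTU filtering, median-of-ratios size factors and gene-wise
# negative-binomial dispersion estimation with trend shrinkage.

#' Remove sparse OTUs across the whole dataset
#'
#' An OTU is removed if its total count across all samples is below
#' `min_total` reads OR it appears (count > 0) in fewer than
#' `min_prevalence` of the samples. Both boundaries pass: an OTU with
#' exactly `min_total` reads or exactly `min_prevalence` prevalence is
#' kept. The filter is applied jointly across all samples (fractions of
#' every gradient) before any per-gradient modelling.
#'
#' @param counts samples x OTUs integer matrix.
#' @param min_total minimum total read count (default 10).
#' @param min_prevalence minimum fraction of samples with a non-zero
#'   count (default 0.20).
#' @return list with `counts` (filtered matrix), `kept`, `removed`
#'   (character ids) and `report` (per-OTU data frame with the totals,
#'   prevalences and the rule(s) that fired).
#' @export
filter_sparse_otus <- function(counts, min_total = 10, min_prevalence = 0.20) {
  stopifnot(is.matrix(counts), nrow(counts) >= 1)
  totals <- colSums(counts)
  prev <- colMeans(counts > 0)
  fail_total <- totals < min_total
  fail_prev <- prev < min_prevalence
  drop <- fail_total | fail_prev
  report <- data.frame(otu_id = colnames(counts), total = totals,
                       prevalence = prev, fail_total = fail_total,
                       fail_prevalence = fail_prev, removed = drop,
                       row.names = NULL)
  list(counts = counts[, !drop, drop = FALSE],
       kept = colnames(counts)[!drop],
       removed = colnames(counts)[drop],
       report = report)
}

#' Median-of-ratios size factors
#'
#' Library-size normalisation for count tables: each sample's factor is
#' the median, over reference OTUs, of the ratio of its counts to the
#' OTU's geometric mean across samples (the median is taken on the log
#' scale, the convention of the standard RNA-seq implementations);
#' factors are rescaled to have geometric mean 1. Reference OTUs are those with non-zero counts in
#' every sample; if none exists, geometric means are computed over
#' positive counts only (with a warning).
#'
#' @param counts samples x OTUs matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
#' @examples
#' m <- rbind(a = c(10, 20, 30), b = c(30, 60, 90))
#' estimate_size_factors(m)  # ratio 3 between samples
estimate_size_factors <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) >= 2)
  all_pos <- colSums(counts > 0) == nrow(counts)
  if (any(all_pos)) {
    ref <- counts[, all_pos, drop = FALSE]
    geo <- colMeans(log(ref))
    logratios <- sweep(log(ref), 2, geo, "-")
  } else {
    warning("no OTU has positive counts in all samples; ",
            "using positive-count geometric means")
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    geo <- colMeans(logc, na.rm = TRUE)
    ok <- is.finite(geo)
    if (!any(ok)) stop("cannot estimate size factors: no usable OTU")
    logratios <- sweep(logc[, ok, drop = FALSE], 2, geo[ok], "-")
  }
  # geometric median-of-ratios (median taken on the log scale)
  sf <- exp(apply(logratios, 1, stats::median, na.rm = TRUE))
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor estimated; check for empty samples")
  sf / exp(mean(log(sf)))
}

#' Gene-wise NB dispersion with mean-trend shrinkage
#'
#' Per-OTU method-of-moments dispersion on size-factor-normalised counts,
#' \eqn{\hat\alpha = \max(0, (s^2 - \bar m)/\bar m^2)}, shrunk toward a
#' fitted mean-dispersion trend \eqn{\alpha(\mu) = a/\mu + b} (least
#' squares on the raw estimates) by geometric averaging:
#' \eqn{\alpha_{final} = \exp(w \log\hat\alpha + (1-w)\log\alpha(\mu))},
#' floored at `floor`.
#'
#' @param counts samples x OTUs matrix (>= 3 samples).
#' @param size_factors per-sample factors from [estimate_size_factors()].
#' @param shrinkage weight `w` on the gene-wise estimate (default 0.5).
#' @param floor lower bound on dispersions (default 1e-8).
#' @return data frame with `otu_id`, `mean_norm` (normalised mean),
#'   `raw_dispersion`, `trend_dispersion`, `final_dispersion`, and
#'   `usable` (FALSE for zero-mean OTUs, which cannot be tested).
#' @export
estimate_dispersions <- function(counts, size_factors, shrinkage = 0.5,
                                 floor = 1e-8) {
  stopifnot(is.matrix(counts), nrow(counts) >= 3,
            length(size_factors) == nrow(counts), all(size_factors > 0),
            shrinkage >= 0, shrinkage <= 1)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU_", seq_len(ncol(counts)))
  norm <- sweep(counts, 1, size_factors, "/")
  m <- colMeans(norm)
  v <- apply(norm, 2, stats::var)
  raw <- ifelse(m > 0, pmax(0, (v - m) / m^2), NA_real_)
  usable <- m > 0
  # trend alpha(mu) = a/mu + b on the usable raw estimates
  ok <- usable & is.finite(raw)
  if (sum(ok) >= 2 && stats::var(1 / m[ok]) > 0) {
    fit <- stats::lm.fit(cbind(1, 1 / m[ok]), raw[ok])
    b <- fit$coefficients[1]; a <- fit$coefficients[2]
  } else {
    b <- mean(raw[ok]); a <- 0
    if (!is.finite(b)) b <- floor
  }
  trend <- pmax(a / m + b, floor)
  final <- exp(shrinkage * log(pmax(raw, floor)) +
               (1 - shrinkage) * log(trend))
  final <- pmax(final, floor)
  final[!usable] <- NA_real_
  data.frame(otu_id = colnames(counts), mean_norm = m,
             raw_dispersion = raw, trend_dispersion = trend,
             final_dispersion = final, usable = usable, row.names = NULL)
}
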