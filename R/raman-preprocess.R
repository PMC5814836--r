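# Raman spectral preprocessing: wavenumber alignment check, iterative
# polynomial baseline correction and absolute-sum normalisation.
# Preprocessing order is fixed: alignment check -> baseline correction
# -> normalisation.

#' Check spectral alignment against the phenylalanine reference peak
#'
#' The phenylalanine ring-breathing mode at 1003 cm^-1 carries no
#' nitrogen and therefore never shifts with 15N labelling, making it a
#' wavenumber-calibration reference: a correctly aligned spectrum shows
#' a local maximum within `tolerance_cm` of 1003 cm^-1.
#'
#' @param wavenumbers ascending grid (must cover 990-1016 cm^-1).
#' @param intensities spectrum intensities.
#' @param reference_cm reference position (default 1003).
#' @param tolerance_cm allowed deviation (default 3 cm^-1).
#' @param search_halfwidth half-width of the search window around the
#'   reference (default 13 cm^-1).
#' @return list with `pass`, `peak_position` (cm^-1, NA if no local
#'   maximum found) and `reason`.
#' @export
check_alignment <- function(wavenumbers, intensities, reference_cm = 1003,
                            tolerance_cm = 3, search_halfwidth = 13) {
  stopifnot(length(wavenumbers) == length(intensities),
            all(diff(wavenumbers) > 0))
  if (min(wavenumbers) > reference_cm - search_halfwidth ||
      max(wavenumbers) < reference_cm + search_halfwidth)
    stop("wavenumber grid must cover the search window around ",
         reference_cm, " cm^-1")
  win <- which(abs(wavenumbers - reference_cm) <= search_halfwidth)
  y <- intensities[win]
  # local maxima strictly above both neighbours within the window
  is_max <- c(FALSE, y[-c(1, length(y))] > y[-c(length(y) - 1, length(y))] &
                     y[-c(1, length(y))] >= y[-c(1, 2)], FALSE)
  if (!any(is_max))
    return(list(pass = FALSE, peak_position = NA_real_,
                reason = "no local maximum in search window"))
  cand <- wavenumbers[win][is_max]
  peak <- cand[which.min(abs(cand - reference_cm))]
  pass <- abs(peak - reference_cm) <= tolerance_cm
  list(pass = pass, peak_position = peak,
       reason = if (pass) "ok" else "nearest local maximum outside tolerance")
}

#' Iterative modified-polyfit baseline correction
#'
#' Fluorescence background removal: a polynomial of degree `degree` is
#' fitted to the spectrum; intensities above the fit are replaced by the
#' fit and the procedure repeats until the relative RMS change of the
#' fitted baseline falls below `tol` or `max_iter` iterations are
#' reached. The peaks, which always exceed the running baseline, are
#' thereby excluded from the background estimate.
#'
#' @param wavenumbers,intensities the spectrum (finite intensities).
#' @param degree polynomial degree (default 6).
#' @param tol relative RMS convergence tolerance (default 0.01).
#' @param max_iter maximum iterations (default 100).
#' @return list with `corrected` (intensities minus baseline),
#'   `baseline` and `iterations`.
#' @export
baseline_correct <- function(wavenumbers, intensities, degree = 6,
                             tol = 0.01, max_iter = 100) {
  stopifnot(length(wavenumbers) == length(intensities),
            length(intensities) >= degree + 2)
  if (any(!is.finite(intensities)))
    stop("intensities must be finite")
  x <- (wavenumbers - min(wavenumbers)) /
    max(max(wavenumbers) - min(wavenumbers), 1)
  X <- stats::poly(x, degree = degree, raw = TRUE)
  work <- intensities
  baseline <- rep(0, length(intensities))
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(cbind(1, X), work)
    new_baseline <- drop(cbind(1, X) %*% fit$coefficients)
    iterations <- it
    rel <- sqrt(mean((new_baseline - baseline)^2))
    scale <- sqrt(mean(new_baseline^2))
    baseline <- new_baseline
    work <- pmin(work, baseline)
    if (scale == 0 || rel / max(scale, .Machine$double.eps) < tol) break
  }
  list(corrected = intensities - baseline, baseline = baseline,
       iterations = iterations)
}

#' Normalise a spectrum to unit absolute-intensity sum
#'
#' Divides by \eqn{\sum_i |I_i|} so spectra from different acquisitions
#' become comparable; idempotent and invariant to positive scaling.
#'
#' @param intensities spectrum intensities (not all zero).
#' @return intensities with `sum(abs(.)) == 1`.
#' @export
normalize_spectrum <- function(intensities) {
  s <- sum(abs(intensities))
  if (s == 0) stop("cannot normalise an all-zero spectrum")
  intensities / s
}

#' Preprocess a set of spectra for classification
#'
#' Applies, per cell: alignment check (failing cells are dropped with a
#' message), baseline correction and absolute-sum normalisation.
#'
#' @param spectra a `raman_spectra` object.
#' @param degree,tol,max_iter see [baseline_correct()].
#' @param tolerance_cm see [check_alignment()].
#' @param alignment_gate logical; skip the alignment check if FALSE
#'   (e.g. for simulated strains lacking the reference peak region).
#' @return a `raman_spectra` object with preprocessed intensities and a
#'   `dropped` attribute naming cells that failed alignment.
#' @export
preprocess_spectra <- function(spectra, degree = 6, tol = 0.01,
                               max_iter = 100, tolerance_cm = 3,
                               alignment_gate = TRUE) {
  stopifnot(inherits(spectra, "raman_spectra"))
  wn <- spectra$wavenumbers
  keep <- rep(TRUE, nrow(spectra$meta))
  if (alignment_gate) {
    for (i in seq_len(nrow(spectra$meta))) {
      al <- check_alignment(wn, spectra$intensity[i, ],
                            tolerance_cm = tolerance_cm)
      keep[i] <- al$pass
    }
    if (any(!keep))
      message(sum(!keep), " spectra failed the alignment check and were dropped")
  }
  out <- spectra
  out$meta <- spectra$meta[keep, , drop = FALSE]
  out$intensity <- spectra$intensity[keep, , drop = FALSE]
  for (i in seq_len(nrow(out$meta))) {
    bc <- baseline_correct(wn, out$intensity[i, ], degree, tol, max_iter)
    out$intensity[i, ] <- normalize_spectrum(bc$corrected)
  }
  attr(out, "dropped") <- spectra$meta$cell_id[!keep]
  out
}
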