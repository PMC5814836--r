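# Buoyant-density windows and fraction classification.

#' Density windows locating labelled and unlabelled template
#'
#' In an RNA/CsTFA gradient 15N-labelled RNA bands heavy (default
#' labelled window 1.785-1.820 g/ml, unlabelled 1.740-1.785 g/ml); in a
#' secondary CsCl/bis-benzimide DNA gradient labelled DNA is recovered
#' light (default labelled window 1.665-1.695 g/ml).
#'
#' @param labelled,unlabelled numeric length-2 `(lo, hi)` in g/ml.
#' @param orientation `"labelled-is-heavy"` (RNA) or
#'   `"labelled-is-light"` (secondary DNA).
#' @return object of class `density_windows`.
#' @export
density_windows <- function(labelled, unlabelled,
                            orientation = c("labelled-is-heavy",
                                            "labelled-is-light")) {
  orientation <- match.arg(orientation)
  stopifnot(length(labelled) == 2, length(unlabelled) == 2,
            labelled[1] < labelled[2], unlabelled[1] < unlabelled[2])
  lo <- max(labelled[1], unlabelled[1]); hi <- min(labelled[2], unlabelled[2])
  if (hi > lo)
    stop("labelled and unlabelled windows may only touch, not overlap")
  structure(list(labelled = labelled, unlabelled = unlabelled,
                 orientation = orientation),
            class = "density_windows")
}

#' Default windows for RNA-SIP CsTFA gradients
#' @export
rna_windows <- function() {
  density_windows(labelled = c(1.785, 1.820), unlabelled = c(1.740, 1.785),
                  orientation = "labelled-is-heavy")
}

#' Default windows for secondary DNA-SIP CsCl gradients
#' @export
dna_windows <- function() {
  density_windows(labelled = c(1.665, 1.695), unlabelled = c(1.695, 1.750),
                  orientation = "labelled-is-light")
}

#' Classify gradient fractions by buoyant density
#'
#' Each fraction is `"labelled"` if its density falls in the labelled
#' window, `"unlabelled"` if in the unlabelled window, else
#' `"excluded"`. Windows are half-open `[lo, hi)` except that the
#' outermost boundary in the orientation's direction is closed (the
#' heavy edge of the labelled window for RNA, the light edge for
#' secondary DNA), so a fraction sitting exactly on the extreme edge is
#' still used.
#'
#' @param densities numeric vector of fraction densities (g/ml), strictly
#'   monotone in collection order.
#' @param windows a [density_windows()] object.
#' @param gradient_id used in error messages.
#' @return character vector of classes, one per fraction.
#' @export
#' @examples
#' assign_fraction_classes(c(1.80, 1.75, 1.90), rna_windows())
assign_fraction_classes <- function(densities, windows, gradient_id = "gradient") {
  stopifnot(inherits(windows, "density_windows"))
  d <- diff(densities)
  if (!(all(d > 0) || all(d < 0)))
    stop("fraction densities must be strictly monotone (", gradient_id, ")")
  # all windows are [lo, hi); for the heavy orientation the outermost
  # (heavy) edge of the labelled window is additionally closed, so the
  # extreme usable fraction is never dropped (for the light orientation
  # the outermost edge is the labelled lo, closed already)
  heavy_oriented <- windows$orientation == "labelled-is-heavy"
  wl <- windows$labelled; wu <- windows$unlabelled
  lab <- densities >= wl[1] &
    (densities < wl[2] | (heavy_oriented & densities <= wl[2]))
  unl <- densities >= wu[1] & densities < wu[2] & !lab
  cls <- ifelse(lab, "labelled", ifelse(unl, "unlabelled", "excluded"))
  for (side in c("labelled", "unlabelled"))
    if (sum(cls == side) < 2)
      stop("fewer than 2 ", side, " fractions in ", gradient_id)
  cls
}

#' Per-fraction share of total template copies in a gradient
#'
#' qPCR quantifications of rRNA copies per fraction, expressed as the
#' proportion of the total copies of the entire gradient.
#'
#' @param copy_quant non-negative per-fraction copy quantification.
#' @return proportions summing to 1.
#' @export
normalize_copy_profile <- function(copy_quant) {
  if (any(copy_quant < 0)) stop("copy quantifications must be non-negative")
  tot <- sum(copy_quant)
  if (tot <= 0) stop("all-zero copy quantification: cannot normalise")
  copy_quant / tot
}
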