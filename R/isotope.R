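# Isotope-ratio arithmetic for 15N tracer experiments.
#
# All conversions are defined against the 15N/14N ratio of atmospheric N2
# (the international delta-notation standard for nitrogen).

#' Atmospheric nitrogen reference isotope ratio
#'
#' The \eqn{^{15}N/^{14}N} ratio of atmospheric N2, the standard against
#' which delta values are expressed.
#' @export
N15_REFERENCE_RATIO <- 0.0036765

#' Convert an isotope ratio to delta notation
#'
#' \eqn{\delta^{15}N = (R_{sample}/R_{ref} - 1) \times 1000} in per mille.
#'
#' @param ratio_sample numeric, \eqn{^{15}N/^{14}N} ratio(s) of the sample;
#'   must be non-negative.
#' @param reference_ratio reference \eqn{^{15}N/^{14}N} ratio (atmospheric
#'   N2 by default).
#' @return delta value(s) in per mille (permil).
#' @seealso [ratio_from_delta()], [atom_percent_from_ratio()]
#' @export
#' @examples
#' delta_from_ratio(2 * N15_REFERENCE_RATIO)  # +1000 permil
delta_from_ratio <- function(ratio_sample, reference_ratio = N15_REFERENCE_RATIO) {
  stopifnot(is.numeric(ratio_sample), is.numeric(reference_ratio),
            reference_ratio > 0)
  if (any(ratio_sample < 0, na.rm = TRUE))
    stop("isotope ratios must be non-negative")
  (ratio_sample / reference_ratio - 1) * 1000
}

#' Convert a delta value to an isotope ratio
#'
#' Inverse of [delta_from_ratio()].
#'
#' @param delta_permil delta value(s) in per mille; must be >= -1000.
#' @inheritParams delta_from_ratio
#' @return \eqn{^{15}N/^{14}N} ratio(s).
#' @export
ratio_from_delta <- function(delta_permil, reference_ratio = N15_REFERENCE_RATIO) {
  stopifnot(is.numeric(delta_permil), reference_ratio > 0)
  if (any(delta_permil < -1000, na.rm = TRUE))
    stop("delta values below -1000 permil imply a negative isotope ratio")
  (delta_permil / 1000 + 1) * reference_ratio
}

#' Atom percent 15N from an isotope ratio
#'
#' \eqn{at\% = 100 R / (1 + R)}: the share of 15N among all N atoms.
#'
#' @param ratio_sample \eqn{^{15}N/^{14}N} ratio(s), non-negative.
#' @return atom percent 15N in \[0, 100).
#' @export
atom_percent_from_ratio <- function(ratio_sample) {
  if (any(ratio_sample < 0, na.rm = TRUE))
    stop("isotope ratios must be non-negative")
  100 * ratio_sample / (1 + ratio_sample)
}

#' Isotope ratio from atom percent 15N
#'
#' Inverse of [atom_percent_from_ratio()].
#' @param atom_percent atom percent 15N in \[0, 100).
#' @return \eqn{^{15}N/^{14}N} ratio(s).
#' @export
ratio_from_atom_percent <- function(atom_percent) {
  if (any(atom_percent < 0 | atom_percent >= 100, na.rm = TRUE))
    stop("atom percent must lie in [0, 100)")
  atom_percent / (100 - atom_percent)
}

#' Atom percent 15N from a delta value
#'
#' Composition of [ratio_from_delta()] and [atom_percent_from_ratio()].
#' @inheritParams ratio_from_delta
#' @return atom percent 15N.
#' @export
atom_percent_from_delta <- function(delta_permil,
                                    reference_ratio = N15_REFERENCE_RATIO) {
  atom_percent_from_ratio(ratio_from_delta(delta_permil, reference_ratio))
}

#' Atom percent excess (APE) of a labelled sample over a control
#'
#' APE is the atom-percent 15N of the labelled sample minus that of the
#' natural-abundance control; it measures tracer incorporation. Inputs may
#' be given either as delta values (per mille) or as atom percent.
#' A negative APE (possible through measurement noise) is returned as-is
#' with a warning rather than clamped, so that control distributions stay
#' unbiased.
#'
#' @param sample,control numeric values for the labelled sample and the
#'   natural-abundance control, in the unit named by `unit`.
#' @param unit `"delta_permil"` (default) or `"atom_percent"`.
#' @inheritParams delta_from_ratio
#' @return APE in atom percent.
#' @export
#' @examples
#' atom_percent_excess(26.5, 0.5)  # day-5 scale soil enrichment
atom_percent_excess <- function(sample, control, unit = c("delta_permil", "atom_percent"),
                                reference_ratio = N15_REFERENCE_RATIO) {
  unit <- match.arg(unit)
  if (unit == "delta_permil") {
    sample <- atom_percent_from_delta(sample, reference_ratio)
    control <- atom_percent_from_delta(control, reference_ratio)
  }
  ape <- sample - control
  if (any(ape < 0, na.rm = TRUE))
    warning("negative APE encountered; reported as-is (not clamped)")
  ape
}

#' Remove the contribution of an internal spike from a measured delta value
#'
#' Biomolecule extracts measured by EA-IRMS are spiked with a carrier of
#' known mass and isotopic composition; the sample's own delta value is
#' recovered with a two-source mixing model:
#' \deqn{\delta_{sample} = (\delta_{total} N_{total} - \delta_{spike} N_{spike}) / (N_{total} - N_{spike})}
#'
#' @param delta_total measured delta (per mille) of spike + sample.
#' @param n_total total N mass (spike + sample), e.g. in ug N.
#' @param delta_spike delta (per mille) of the spike (default 0.11, a
#'   proline-sucrose carrier).
#' @param n_spike N mass of the spike in the same unit as `n_total`
#'   (default 1.11 ug N).
#' @return delta value (per mille) of the sample alone.
#' @export
#' @examples
#' unmix_spike(100, 2.11)  # 210.8779 permil
unmix_spike <- function(delta_total, n_total, delta_spike = 0.11, n_spike = 1.11) {
  stopifnot(is.numeric(delta_total), is.numeric(n_total))
  if (any(n_spike <= 0)) stop("spike mass must be positive")
  if (any(n_total <= n_spike))
    stop("total N mass must exceed the spike N mass")
  (delta_total * n_total - delta_spike * n_spike) / (n_total - n_spike)
}

#' Mix a sample with a spike (forward model of [unmix_spike()])
#'
#' @param delta_sample delta (per mille) of the sample alone.
#' @inheritParams unmix_spike
#' @return delta (per mille) of the mixture.
#' @export
mix_with_spike <- function(delta_sample, n_total, delta_spike = 0.11, n_spike = 1.11) {
  if (any(n_total <= n_spike))
    stop("total N mass must exceed the spike N mass")
  (delta_sample * (n_total - n_spike) + delta_spike * n_spike) / n_total
}

#' Express a 15N2 tracer incorporation rate as its acetylene-reduction
#' equivalent
#'
#' Converts the 15N incorporation measured in an incubation into the
#' ethylene production the acetylene reduction assay (ARA) would have had
#' to detect, assuming the nominal 3:1 acetylene:N stoichiometry of
#' nitrogenase. Used to judge whether ARA could have seen the activity.
#'
#' @param soil_n_content soil N content, umol N per g dry weight.
#' @param ape atom percent excess of the incubated soil (atom %).
#' @param incubation_time incubation time in hours.
#' @param conversion_factor mol C2H2 reduced per mol N fixed (default 3).
#' @param soil_dry_mass soil dry mass in the vial, g.
#' @param headspace_volume vial headspace, ml.
#' @param molar_volume gas molar volume, L/mol (default 24.465, ideal gas
#'   at 25 degrees C and 1 atm).
#' @param window_h assay window (hours) over which the ppmv figure is
#'   accumulated (default 4, a typical ARA measurement interval).
#' @return list with `n2_fix_rate` (umol 15N /g/h), `ethylene_rate`
#'   (umol C2H4 /g/h) and `ethylene_ppmv` (mole fraction x 1e6 reached in
#'   the headspace after `window_h` hours).
#' @export
#' @examples
#' ara_equivalent(soil_n_content = 500, ape = 0.01, incubation_time = 120,
#'                soil_dry_mass = 1.1, headspace_volume = 13)
ara_equivalent <- function(soil_n_content, ape, incubation_time,
                           conversion_factor = 3, soil_dry_mass = 1,
                           headspace_volume = 13, molar_volume = 24.465,
                           window_h = 4) {
  stopifnot(soil_n_content > 0, incubation_time > 0, conversion_factor > 0,
            soil_dry_mass > 0, headspace_volume > 0, molar_volume > 0,
            window_h > 0, ape >= 0)
  fix_rate <- soil_n_content * (ape / 100) / incubation_time
  ethylene_rate <- fix_rate * conversion_factor
  ethylene_umol <- ethylene_rate * soil_dry_mass * window_h
  headspace_umol <- headspace_volume / 1000 / molar_volume * 1e6
  list(n2_fix_rate = fix_rate,
       ethylene_rate = ethylene_rate,
       ethylene_ppmv = ethylene_umol / headspace_umol * 1e6)
}
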