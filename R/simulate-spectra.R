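# Seeded simulator of single-cell Raman spectra with known 15N labelling.
#
# Spectra are sums of Gaussian peaks on a regular wavenumber grid.
# Peaks from N-containing moieties shift to lower wavenumbers in
# proportion to the cell's 15N content; the 1003 cm^-1 phenylalanine
# ring-breathing peak carries no N and never shifts (it is the alignment
# reference). A polynomial baseline emulates fluorescence background and
# Gaussian noise emulates shot/detector noise.

# Indicative peaks that shift with 15N labelling (positions in cm^-1,
# assignments: 728 adenine ring breathing, 783 O-P-O/cytosine/uracil,
# 1174 C-H bending Tyr/Phe, 1247 amide III, 1340 CH adenine, 1480 purine
# bases, 1577 guanine/adenine ring stretch) plus the unshifted 1003
# phenylalanine reference.
.default_peaks <- function(centers = c(728, 783, 1003, 1174, 1247, 1340, 1480, 1577)) {
  full <- data.frame(
    center = c(728, 783, 1003, 1174, 1247, 1340, 1480, 1577),
    width  = c(6, 7, 5, 8, 9, 8, 8, 7),
    height = c(1.0, 0.8, 1.2, 0.5, 0.7, 0.9, 0.8, 0.6),
    shift_at_full_label = c(-10, -8, 0, -6, -7, -9, -8, -7))
  full[full$center %in% centers, , drop = FALSE]
}

#' Per-strain Raman peak tables for the spectra simulator
#'
#' Returns a named list of peak tables (columns `center`, `width`,
#' `height`, `shift_at_full_label`, all in cm^-1 except the unitless
#' height). `"full"` strains carry all eight indicative peaks (the
#' E. coli-like pattern); `"cyano"` strains carry only 1247, 1340 and
#' 1480 cm^-1 plus the phenylalanine reference, emulating cyanobacteria
#' that lack most indicative peaks.
#'
#' @param strains character vector of strain names.
#' @param profile `"full"` or `"cyano"`, recycled along `strains`.
#' @return named list of data frames.
#' @export
strain_peak_table <- function(strains, profile = "full") {
  profile <- rep_len(profile, length(strains))
  out <- lapply(profile, function(p) {
    switch(p,
           full = .default_peaks(),
           cyano = .default_peaks(c(1003, 1247, 1340, 1480)),
           stop("unknown peak profile: ", p))
  })
  names(out) <- strains
  out
}

#' Parameters for the Raman spectra simulator
#'
#' @param wavenumber_grid cm^-1 grid (default 400-1914 in steps of 2).
#' @param strain_peaks named list of per-strain peak tables, e.g. from
#'   [strain_peak_table()].
#' @param baseline_poly_coeffs coefficients (intercept first) of the
#'   additive polynomial baseline evaluated on a \[0,1\]-rescaled grid;
#'   degree at most 6.
#' @param noise_sd sd of additive Gaussian noise (intensity units).
#' @param at_levels 15N labelling levels (atom %) to simulate; default
#'   the cultivation series 0, 5, 10, 25, 50, 100.
#' @param cells_per_level spectra per strain per level (default 30).
#' @param seed integer seed.
#' @return object of class `spectra_sim_params`.
#' @export
spectra_sim_params <- function(wavenumber_grid = seq(400, 1914, by = 2),
                               strain_peaks = strain_peak_table("strainA"),
                               baseline_poly_coeffs = c(0.2, 0.5, -0.3),
                               noise_sd = 0.02,
                               at_levels = c(0, 5, 10, 25, 50, 100),
                               cells_per_level = 30,
                               seed = 1L) {
  if (!length(strain_peaks)) stop("strain_peaks must not be empty")
  stopifnot(is.list(strain_peaks), !is.null(names(strain_peaks)),
            all(diff(wavenumber_grid) > 0),
            length(baseline_poly_coeffs) <= 7,
            noise_sd >= 0, cells_per_level >= 1,
            all(at_levels >= 0 & at_levels <= 100))
  for (tab in strain_peaks) {
    if (!all(c("center", "width", "height", "shift_at_full_label") %in% names(tab)))
      stop("each peak table needs center/width/height/shift_at_full_label")
    if (any(tab$center < min(wavenumber_grid) | tab$center > max(wavenumber_grid)))
      stop("peak centers must lie within the wavenumber grid")
  }
  structure(list(wavenumber_grid = wavenumber_grid,
                 strain_peaks = strain_peaks,
                 baseline_poly_coeffs = baseline_poly_coeffs,
                 noise_sd = noise_sd, at_levels = at_levels,
                 cells_per_level = as.integer(cells_per_level),
                 seed = as.integer(seed)),
            class = "spectra_sim_params")
}

# Deterministic noiseless spectrum: sum of Gaussian peaks with centers
# shifted in proportion to the labelling level.
peak_spectrum <- function(grid, peaks, at_percent) {
  centers <- peaks$center + peaks$shift_at_full_label * at_percent / 100
  intens <- numeric(length(grid))
  for (k in seq_len(nrow(peaks)))
    intens <- intens + peaks$height[k] *
      exp(-0.5 * ((grid - centers[k]) / peaks$width[k])^2)
  intens
}

#' Simulate single-cell Raman spectra with known strain and labelling
#'
#' For every strain x labelling level, `cells_per_level` spectra are
#' drawn: shifted Gaussian peaks + polynomial baseline + Gaussian noise.
#'
#' @param params a [spectra_sim_params()] object.
#' @return a `raman_spectra` object: list with `wavenumbers` (common
#'   grid) and `spectra`, a data frame of metadata (`cell_id`, `strain`,
#'   `at_percent`) alongside an `intensity` matrix (cells x wavenumbers).
#' @export
#' @examples
#' p <- spectra_sim_params(cells_per_level = 2, at_levels = c(0, 100))
#' sim <- simulate_spectra(p)
#' dim(sim$intensity)
simulate_spectra <- function(params) {
  stopifnot(inherits(params, "spectra_sim_params"))
  p <- params
  set.seed(p$seed)
  grid <- p$wavenumber_grid
  x01 <- (grid - min(grid)) / (max(grid) - min(grid))
  baseline <- drop(outer(x01, seq_along(p$baseline_poly_coeffs) - 1, `^`) %*%
                   p$baseline_poly_coeffs)
  combos <- expand.grid(strain = names(p$strain_peaks),
                        at_percent = p$at_levels,
                        cell = seq_len(p$cells_per_level),
                        stringsAsFactors = FALSE)
  combos <- combos[order(combos$strain, combos$at_percent, combos$cell), ]
  n <- nrow(combos)
  intens <- matrix(0, n, length(grid))
  for (i in seq_len(n)) {
    pure <- peak_spectrum(grid, p$strain_peaks[[combos$strain[i]]],
                          combos$at_percent[i])
    noise <- if (p$noise_sd > 0) stats::rnorm(length(grid), 0, p$noise_sd) else 0
    intens[i, ] <- pure + baseline + noise
  }
  meta <- data.frame(cell_id = sprintf("%s_at%03d_c%02d", combos$strain,
                                       combos$at_percent, combos$cell),
                     strain = combos$strain, at_percent = combos$at_percent,
                     stringsAsFactors = FALSE)
  rownames(intens) <- meta$cell_id
  structure(list(wavenumbers = grid, meta = meta, intensity = intens),
            class = "raman_spectra")
}

#' @export
print.raman_spectra <- function(x, ...) {
  cat("Raman spectra: ", nrow(x$meta), " cells, ",
      length(x$wavenumbers), " wavenumbers (",
      min(x$wavenumbers), "-", max(x$wavenumbers), " cm^-1)\n", sep = "")
  cat("  strains: ", paste(unique(x$meta$strain), collapse = ", "), "\n", sep = "")
  cat("  at% levels: ", paste(sort(unique(x$meta$at_percent)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write spectra as a long-format CSV
#'
#' Columns: cell_id, strain, at_percent, wavenumber, intensity.
#' @param spectra a `raman_spectra` object.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "raman_spectra"))
  n_wn <- length(spectra$wavenumbers)
  long <- data.frame(
    cell_id = rep(spectra$meta$cell_id, each = n_wn),
    strain = rep(spectra$meta$strain, each = n_wn),
    at_percent = rep(spectra$meta$at_percent, each = n_wn),
    wavenumber = rep(spectra$wavenumbers, times = nrow(spectra$meta)),
    intensity = as.vector(t(spectra$intensity)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read long-format spectra CSV written by [write_spectra_csv()]
#' @param path CSV path.
#' @return a `raman_spectra` object.
#' @export
read_spectra_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "strain", "at_percent", "wavenumber", "intensity")
  if (!all(need %in% names(long)))
    stop("missing columns: ", paste(setdiff(need, names(long)), collapse = ", "))
  grid <- sort(unique(long$wavenumber))
  cells <- unique(long$cell_id)
  intens <- matrix(NA_real_, length(cells), length(grid),
                   dimnames = list(cells, NULL))
  for (cid in cells) {
    d <- long[long$cell_id == cid, ]
    intens[cid, ] <- d$intensity[order(d$wavenumber)]
  }
  meta <- unique(long[, c("cell_id", "strain", "at_percent")])
  meta <- meta[match(cells, meta$cell_id), ]
  rownames(meta) <- NULL
  structure(list(wavenumbers = grid, meta = meta, intensity = intens),
            class = "raman_spectra")
}
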