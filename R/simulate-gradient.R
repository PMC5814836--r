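# Seeded simulator for isopycnic SIP gradient experiments.
#
# The generator emulates the statistical structure of a fractionated
# density gradient: each OTU's template mass follows a Gaussian along
# buoyant density, isotope labelling shifts the centre upward (RNA/CsTFA)
# or re-centres it into the light recovery window (secondary DNA/CsCl),
# a uniform background spreads part of every OTU across the whole
# gradient, and sequencing draws multinomial reads per fraction with an
# optional per-OTU Gamma overdispersion multiplier so that downstream
# negative-binomial modelling is well specified.

#' Parameters for a simulated SIP gradient experiment
#'
#' Defaults describe an RNA-SIP CsTFA gradient cut into 20 equal-volume
#' fractions: unlabelled RNA concentrates around 1.760-1.786 g/ml and
#' fully 15N-labelled RNA bands about 0.015 g/ml denser.
#'
#' @param n_fractions number of equal-volume fractions (default 20).
#' @param density_range numeric length-2, min/max buoyant density (g/ml)
#'   spanned by the recovered fractions. RNA/CsTFA default 1.740-1.835;
#'   for `medium = "DNA"` the default becomes 1.650-1.750 (secondary
#'   CsCl/bis-benzimide recovery range).
#' @param n_otus number of OTUs.
#' @param community_lognormal `c(mu, sigma)` of the log-normal from which
#'   relative abundances are drawn (then normalised to sum to 1).
#' @param reads_per_fraction scalar or length-`n_fractions` vector of read
#'   depths (default 3000, the scale of a typical amplicon-sequenced SIP
#'   fraction).
#' @param unlabelled_density_mean banding centre (g/ml) of unlabelled
#'   template (RNA default 1.773).
#' @param density_sd Gaussian banding spread, g/ml (default 0.008).
#' @param full_label_shift density shift (g/ml) of fully labelled
#'   template (RNA default +0.015).
#' @param labelled_otu_ids character vector of OTU ids that carry label
#'   (subset of the generated ids `OTU_1..OTU_n`); default none.
#' @param label_fraction_per_otu labelling degree in \[0,1\] for each
#'   labelled OTU (recycled).
#' @param gc_content_per_otu G+C percentages (DNA mode only); default
#'   drawn uniformly in 35-65%.
#' @param background_spread_fraction portion of every OTU's mass spread
#'   uniformly across the gradient (default 0.1).
#' @param dispersion per-OTU-per-fraction Gamma overdispersion of expected
#'   counts (variance mu + dispersion*mu^2 marginally; default 0.1;
#'   0 disables the multiplier).
#' @param medium `"RNA"` (CsTFA, labelled template is heavy) or `"DNA"`
#'   (secondary CsCl gradient, labelled template recovered light).
#' @param seed integer seed; the generator is bit-reproducible.
#' @return an object of class `gradient_sim_params` (a validated list).
#' @seealso [simulate_gradient_experiment()]
#' @export
gradient_sim_params <- function(n_fractions = 20,
                                density_range = NULL,
                                n_otus = 300,
                                community_lognormal = c(0, 1.5),
                                reads_per_fraction = 3000,
                                unlabelled_density_mean = 1.773,
                                density_sd = 0.008,
                                full_label_shift = 0.015,
                                labelled_otu_ids = character(),
                                label_fraction_per_otu = 1,
                                gc_content_per_otu = NULL,
                                background_spread_fraction = 0.1,
                                dispersion = 0.1,
                                medium = c("RNA", "DNA"),
                                seed = 1L) {
  medium <- match.arg(medium)
  if (is.null(density_range))
    density_range <- if (medium == "RNA") c(1.740, 1.835) else c(1.650, 1.750)
  stopifnot(length(density_range) == 2, density_range[1] < density_range[2],
            n_fractions >= 2, n_otus >= 1,
            all(label_fraction_per_otu >= 0 & label_fraction_per_otu <= 1),
            all(reads_per_fraction > 0),
            background_spread_fraction >= 0, background_spread_fraction <= 1,
            density_sd > 0, dispersion >= 0)
  if (!length(reads_per_fraction) %in% c(1L, n_fractions))
    stop("reads_per_fraction must be scalar or one value per fraction")
  structure(list(
    n_fractions = as.integer(n_fractions), density_range = density_range,
    n_otus = as.integer(n_otus), community_lognormal = community_lognormal,
    reads_per_fraction = reads_per_fraction,
    unlabelled_density_mean = unlabelled_density_mean,
    density_sd = density_sd, full_label_shift = full_label_shift,
    labelled_otu_ids = as.character(labelled_otu_ids),
    label_fraction_per_otu = label_fraction_per_otu,
    gc_content_per_otu = gc_content_per_otu,
    background_spread_fraction = background_spread_fraction,
    dispersion = dispersion, medium = medium, seed = as.integer(seed)),
    class = "gradient_sim_params")
}

# Midpoints of equal-width density bins (equal-volume fractions along a
# linear gradient). Heaviest fraction first, matching how gradients are
# typically collected (bottom of the tube first).
fraction_densities <- function(density_range, n_fractions) {
  edges <- seq(density_range[1], density_range[2], length.out = n_fractions + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  list(mids = rev(mids), lo = rev(edges[-length(edges)]), hi = rev(edges[-1]))
}

# Expected mass weight of one OTU in each fraction: Gaussian mass
# integrated over the bin, plus a uniform background component.
otu_fraction_weights <- function(center, sd, bins, background) {
  gauss <- stats::pnorm(bins$hi, center, sd) - stats::pnorm(bins$lo, center, sd)
  unif <- (bins$hi - bins$lo) / sum(bins$hi - bins$lo)
  w <- (1 - background) * gauss + background * unif
  w / sum(w)
}

# Banding centre for each OTU given its labelling degree.
otu_band_centers <- function(p, label_fraction) {
  if (p$medium == "RNA") {
    p$unlabelled_density_mean + p$full_label_shift * label_fraction
  } else {
    # Secondary CsCl gradient with bis-benzimide: unlabelled DNA spreads
    # with G+C (classic linear buoyant-density relation, compressed into
    # the heavy part of the recovery range); labelled DNA is re-centred
    # into the light 1.665-1.695 g/ml window.
    gc <- p$gc_content_per_otu
    raw <- 1.660 + 0.00098 * gc
    rr <- range(1.660 + 0.00098 * c(20, 80))
    rel <- (raw - rr[1]) / diff(rr)
    c_unlab <- 1.700 + rel * (1.748 - 1.700)
    c_lab <- 1.665 + rel * (1.695 - 1.665)
    (1 - label_fraction) * c_unlab + label_fraction * c_lab
  }
}

#' Simulate a fractionated SIP gradient experiment with known ground truth
#'
#' Generates one or more gradients (e.g. a 15N-labelled gradient and its
#' 14N control) from the same underlying community. In control gradients
#' every OTU is unlabelled; in labelled gradients the OTUs named in
#' `params$labelled_otu_ids` band at a density shifted according to their
#' labelling degree, so they show a higher-than-average proportion in the
#' fractions where labelled template is expected.
#'
#' @param params a [gradient_sim_params()] object.
#' @param n_labelled,n_control number of labelled / control gradients.
#' @param timepoints optional numeric vector (days) recycled across
#'   gradients, recorded in the metadata.
#' @return an object of class `sip_experiment`: a list with
#'   `gradients` (named list; each has `gradient_id`, `label_status`
#'   (`"15N"`/`"14N-control"`), `timepoint`, `medium`, `densities`,
#'   `counts` fractions x OTUs integer matrix, `copy_quant`,
#'   `qpcr_profile` summing to 1), `truth` (labelled OTU ids), and
#'   `params`.
#' @export
#' @examples
#' p <- gradient_sim_params(n_otus = 50, labelled_otu_ids = "OTU_1", seed = 7)
#' ex <- simulate_gradient_experiment(p)
#' ex$truth
simulate_gradient_experiment <- function(params, n_labelled = 1, n_control = 1,
                                         timepoints = NULL) {
  stopifnot(inherits(params, "gradient_sim_params"),
            n_labelled + n_control >= 1)
  p <- params
  otu_ids <- paste0("OTU_", seq_len(p$n_otus))
  if (!all(p$labelled_otu_ids %in% otu_ids))
    stop("labelled_otu_ids must be a subset of the generated OTU ids")
  set.seed(p$seed)
  rel <- stats::rlnorm(p$n_otus, p$community_lognormal[1], p$community_lognormal[2])
  rel <- rel / sum(rel)
  names(rel) <- otu_ids
  if (p$medium == "DNA" && is.null(p$gc_content_per_otu))
    p$gc_content_per_otu <- stats::runif(p$n_otus, 35, 65)
  bins <- fraction_densities(p$density_range, p$n_fractions)
  reads <- rep_len(p$reads_per_fraction, p$n_fractions)

  lf <- numeric(p$n_otus)
  names(lf) <- otu_ids
  if (length(p$labelled_otu_ids))
    lf[p$labelled_otu_ids] <- rep_len(p$label_fraction_per_otu,
                                      length(p$labelled_otu_ids))

  make_gradient <- function(id, labelled, tp) {
    lab <- if (labelled) lf else numeric(p$n_otus)
    centers <- otu_band_centers(p, lab)
    W <- vapply(seq_len(p$n_otus), function(i)
      otu_fraction_weights(centers[i], p$density_sd, bins,
                           p$background_spread_fraction),
      numeric(p$n_fractions))           # fractions x OTUs
    mass <- sweep(W, 2, rel, "*")       # expected template mass
    counts <- matrix(0L, p$n_fractions, p$n_otus,
                     dimnames = list(NULL, otu_ids))
    for (f in seq_len(p$n_fractions)) {
      pr <- mass[f, ]
      if (p$dispersion > 0) {
        shape <- 1 / p$dispersion
        pr <- pr * stats::rgamma(p$n_otus, shape = shape, rate = shape)
      }
      counts[f, ] <- as.integer(stats::rmultinom(1, reads[f], prob = pr))
    }
    qpcr <- rowSums(mass) / sum(mass)
    list(gradient_id = id,
         label_status = if (labelled) "15N" else "14N-control",
         timepoint = tp, medium = p$medium,
         densities = bins$mids, counts = counts,
         copy_quant = qpcr * sum(reads), qpcr_profile = qpcr)
  }

  ids <- c(if (n_labelled) paste0("G15N_", seq_len(n_labelled)),
           if (n_control) paste0("G14N_", seq_len(n_control)))
  labelled_flag <- c(rep(TRUE, n_labelled), rep(FALSE, n_control))
  tps <- if (is.null(timepoints)) rep(NA_real_, length(ids))
         else rep_len(timepoints, length(ids))
  grads <- Map(make_gradient, ids, labelled_flag, tps)
  names(grads) <- ids
  structure(list(gradients = grads, truth = p$labelled_otu_ids,
                 relative_abundance = rel, params = p),
            class = "sip_experiment")
}

#' @export
print.sip_experiment <- function(x, ...) {
  cat("SIP gradient experiment (", x$params$medium, " mode)\n", sep = "")
  cat("  gradients: ", paste(names(x$gradients), collapse = ", "), "\n", sep = "")
  cat("  fractions per gradient: ", x$params$n_fractions,
      ", OTUs: ", x$params$n_otus, "\n", sep = "")
  cat("  labelled OTUs (truth): ",
      if (length(x$truth)) paste(x$truth, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Write simulated gradients as plain-text tables
#'
#' Each gradient becomes rows of a single TSV (gradient_id, fraction_id,
#' density_g_ml, label_status, timepoint, copy_quant, then one column per
#' OTU); the ground truth is written as JSON next to it.
#'
#' @param experiment a `sip_experiment`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sip_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sip_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(experiment$gradients, function(g) {
    data.frame(gradient_id = g$gradient_id,
               fraction_id = paste0("F", seq_along(g$densities)),
               density_g_ml = g$densities,
               label_status = g$label_status,
               timepoint = g$timepoint,
               copy_quant = g$copy_quant,
               g$counts, check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  counts_path <- file.path(dir, "fraction_counts.tsv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(labelled_otu_ids = experiment$truth,
                            seed = experiment$params$seed),
                       truth_path, auto_unbox = FALSE, pretty = TRUE)
  invisible(c(counts = counts_path, truth = truth_path))
}

#' Read a fraction count table written by [write_sip_experiment()]
#'
#' @param path TSV path (columns gradient_id, fraction_id, density_g_ml,
#'   label_status, timepoint, copy_quant, then OTU columns).
#' @return a `sip_experiment` (without simulation parameters or truth).
#' @export
read_sip_experiment <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("gradient_id", "fraction_id", "density_g_ml",
                 "label_status", "timepoint", "copy_quant")
  if (!all(meta_cols %in% names(tab)))
    stop("missing metadata columns: ",
         paste(setdiff(meta_cols, names(tab)), collapse = ", "))
  otu_cols <- setdiff(names(tab), meta_cols)
  grads <- lapply(split(tab, tab$gradient_id), function(d) {
    d <- d[order(-d$density_g_ml), ]
    list(gradient_id = d$gradient_id[1],
         label_status = d$label_status[1],
         timepoint = d$timepoint[1], medium = NA_character_,
         densities = d$density_g_ml,
         counts = as.matrix(d[, otu_cols, drop = FALSE]),
         copy_quant = d$copy_quant,
         qpcr_profile = d$copy_quant / sum(d$copy_quant))
  })
  structure(list(gradients = grads, truth = NULL, params = NULL),
            class = "sip_experiment")
}

#' Pick the simulated OTU whose relative abundance is nearest a target
#'
#' The community relative abundances drawn by
#' [simulate_gradient_experiment()] depend only on `seed`, `n_otus` and
#' `community_lognormal`, so the choice can be made before deciding
#' which OTU carries label. Useful for spike-recovery studies at a
#' controlled abundance (e.g. 0.5% vs 0.01% of the community).
#'
#' @param params a [gradient_sim_params()] object.
#' @param target relative abundance aimed for (e.g. 0.005).
#' @return list with `otu_id` and `relative_abundance`.
#' @export
pick_otu_near_abundance <- function(params, target) {
  stopifnot(inherits(params, "gradient_sim_params"), target > 0)
  set.seed(params$seed)
  rel <- stats::rlnorm(params$n_otus, params$community_lognormal[1],
                       params$community_lognormal[2])
  rel <- rel / sum(rel)
  i <- which.min(abs(log(rel) - log(target)))
  list(otu_id = paste0("OTU_", i), relative_abundance = rel[i])
}
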