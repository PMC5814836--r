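---
title: "Detecting active diazotrophs from 15N-SIP data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting active diazotrophs from 15N-SIP data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazosip)
```

## The problem

Free-living diazotrophs — bacteria and archaea that reduce atmospheric
N~2~ to ammonia — are typically a minor, tightly regulated fraction of a
soil community, so the presence of nitrogenase genes or transcripts says
little about who is actually fixing nitrogen. Stable isotope probing
(SIP) addresses this directly: a sample is incubated under ^15^N~2~,
organisms that fix nitrogen build ^15^N into their RNA (or DNA), and
isopycnic density-gradient ultracentrifugation separates the isotopically
heavier nucleic acids from the unlabelled background. The catch for
^15^N is quantitative: fully ^15^N-labelled RNA is only about 0.015 g/ml
denser than unlabelled RNA (roughly half the shift obtainable with
^13^C), so labelled and unlabelled template never separate into visibly
distinct peaks. Detection therefore has to be statistical: sequence
every fraction of the gradient and ask, per taxon, whether its reads are
over-represented in the fractions where labelled template is expected.

`diazosip` implements that inference — together with the isotope-tracer
arithmetic used to quantify fixation activity, a single-cell Raman
classification harness, and seeded simulators that generate all of these
data types with known ground truth.

## The enrichment model

### Fraction classification

A gradient is collected as 20 equal-volume fractions, each with a
measured buoyant density. Fractions are classified by density window:
for RNA/CsTFA gradients the labelled ("heavy") window is 1.785–1.820
g/ml and the unlabelled ("light") window 1.740–1.785 g/ml; in the
secondary CsCl (bis-benzimide) DNA gradient the orientation reverses and
labelled DNA is expected light (1.665–1.695 g/ml). Windows are half-open
`[lo, hi)` with the outermost boundary in the labelled direction closed,
so the extreme usable fraction is never dropped; fractions outside both
windows are excluded. The defaults are exposed via `rna_windows()` /
`dna_windows()` and fully configurable.

### Sparse filtering

Before any modelling, OTUs with fewer than 10 reads in total across all
samples, or present in fewer than 20% of samples, are removed
(`filter_sparse_otus()`). Both thresholds pass at the boundary (exactly
10 reads, exactly 20% prevalence is kept), and the filter is applied
once across the whole dataset, not per gradient — prevalence in these
designs was not stated per nucleic-acid type, so the joint convention is
the default.

### The count model

Within one gradient, the fractions of each window are treated as
replicate observations of their class; no density covariate enters the
model. For OTU $i$ with counts $y_{ij}$ in fraction $j$:

$$y_{ij} \sim \mathrm{NB}(\mu_{ij},\, \alpha_i), \qquad
  \log \mu_{ij} = \log s_j + \beta_{0,i} + \beta_{1,i}\,
  \mathbb{1}[j \in \text{labelled}]$$

* **Size factors** $s_j$ are median-of-ratios estimates
  (`estimate_size_factors()`), with the median taken on the log scale
  (the convention of the standard RNA-seq implementations, against
  which the estimator is cross-checked in the tests). When no OTU is
  present in every fraction, geometric means over positive counts only
  are used, with a warning.
* **Dispersions** $\alpha_i$ are method-of-moments estimates on
  normalised counts, $\hat\alpha_i = \max\{0, (s^2_i - \bar m_i)/\bar
  m_i^2\}$, shrunk toward a fitted mean–dispersion trend
  $\alpha(\mu) = a/\mu + b$ by geometric averaging with weight 0.5, and
  floored at $10^{-8}$ (`estimate_dispersions()`). This is a deliberate,
  documented stand-in for the heavier empirical-Bayes machinery of
  dedicated differential-expression packages: it is monotone,
  desk-scale, and sufficient for two-group designs with ~16 usable
  fractions. OTUs with zero mean are flagged untestable.
* **Fitting and testing**: with $\alpha_i$ fixed, the two group means
  have a one-dimensional score equation each, solved by damped Newton
  iteration vectorised across OTUs; the Wald statistic uses the expected
  (Fisher) information. The test is one-sided
  ($H_0\!: \beta_1 \le 0$), because only enrichment in the labelled
  window is biologically meaningful, and p-values are
  Benjamini–Hochberg-adjusted within each gradient. The fit is verified
  in the test suite against `glm()` with a fixed-theta negative-binomial
  family and against a parametric bootstrap of the null.

An OTU is **model-enriched** when its BH-adjusted p-value is below 0.1
*and* its log~2~ fold change exceeds 0.25 (about a 1.19-fold
enrichment). The fold-change condition is applied as a post-hoc filter
on the estimate, not folded into a composite null — the two criteria
are stated as separate thresholds, and the filter reading keeps the
p-value calibrated. For reporting, a pseudo-mean of 0.5 normalised
counts is added to both group means so the fold change stays finite for
group-absent OTUs; the test itself uses the NB likelihood (an OTU with
no reads in the labelled fractions is assigned p = 1 outright).

### Confirmation

Model calls are confirmed by two further gates, applied per gradient and
consolidated across gradients (`consolidate_calls()`):

* **Abundance**: mean normalised count of at least 1.25 — low-count
  OTUs can reach large fold changes on sequencing noise alone.
* **Hump shape** (`hump_shape_diagnostic()`): a genuinely labelled OTU
  shows a unimodal profile along density peaking inside the labelled
  window. The visual inspection used in practice is formalised as: the
  maximum of a 3-fraction moving average lies in the labelled window and
  exceeds the profile median across the gradient by a factor of 2. Both
  parameters (smoothing width, prominence factor) are configuration
  options; the defaults were fixed once, before any calibration runs,
  as the mildest rule that rejects flat and monotone profiles.

An OTU is **confirmed** if it passes all three gates in at least one
gradient. Control (^14^N) gradients run through the identical pipeline
and are expected to produce zero confirmed calls; the run report counts
them explicitly.

### The alternative comparison mode

`sip_enrichment(mode = "vs-control")` reproduces the older design in
which the labelled-window fractions of the ^15^N gradient are compared
against the labelled-window fractions of a control gradient, using the
same NB/Wald machinery with gradient identity as the group factor. The
within-gradient mode is the default because it is immune to the "bottle
effect" — stochastic community differences between incubation vessels
that the cross-gradient comparison can mistake for labelling.

### Beta diversity

`morisita_horn_matrix()` (Morisita–Horn dissimilarities, computed via
`vegan`) and `pcoa()` (classical scaling via `cmdscale`) provide the
ordination diagnostic: in a labelled RNA gradient the heavy-window
fraction communities drift away from the light-window ones.

## Isotope arithmetic

The tracer module implements the delta-notation algebra against the
atmospheric ^15^N/^14^N reference ratio 0.0036765 (configurable; the
standard is "atmospheric air", for which this constant is the
conventional value):

* $\delta^{15}\mathrm{N} = (R_{sample}/R_{ref} - 1)\times 1000$ (permil),
  with exact inverses and atom-percent conversions
  ($at\% = 100R/(1+R)$); round-trips hold to $10^{-12}$ relative.
* **APE** (atom percent excess) subtracts the natural-abundance control
  atom percent from the labelled sample's. Negative APE from
  measurement noise is reported as-is with a warning, not clamped, so
  control distributions remain unbiased.
* **Spike unmixing** (`unmix_spike()`): biomolecule extracts measured
  by EA-IRMS are spiked with a proline–sucrose carrier (1.11 µg N,
  δ^15^N 0.11‰ by default); the sample delta is recovered by the
  two-source mixing model
  $\delta_{sample} = (\delta_{tot}N_{tot} - \delta_{spk}N_{spk}) /
  (N_{tot}-N_{spk})$, the exact algebraic inverse of forward mixing.
* **ARA equivalence** (`ara_equivalent()`): converts a measured ^15^N
  incorporation (soil N content × APE / incubation time) into the
  ethylene production an acetylene reduction assay would have had to
  detect, under the nominal 3:1 C~2~H~2~:N stoichiometry. The headspace
  ppmv figure depends on constants an assay report rarely states
  (headspace volume, dry- vs wet-mass basis, gas temperature, whether
  the stoichiometry is per N or per N~2~); all are exposed as
  parameters with ideal-gas defaults (24.465 L/mol at 25 °C), and the
  output is order-of-magnitude context rather than a calibrated
  prediction.

## Raman classification harness

Single-cell Raman microspectroscopy offers a sequencing-free route to
the same question: peaks arising from N-containing moieties (728, 783,
1174, 1247, 1340, 1480, 1577 cm^-1^) shift to lower wavenumbers as
^15^N replaces ^14^N, while the phenylalanine ring-breathing mode at
1003 cm^-1^ carries no nitrogen and serves as the alignment reference.

Preprocessing is fixed in the order alignment check → baseline
correction → normalisation:

* `check_alignment()` requires a local maximum within 3 cm^-1 of
  1003 cm^-1.
* `baseline_correct()` is an iterative modified-polyfit: fit a
  sixth-degree polynomial, clip intensities to the fit, repeat until the
  relative RMS change of the fitted baseline drops below 0.01 or 100
  iterations. The published description of this routine does not define
  the convergence functional; relative RMS change of the baseline was
  chosen because it is scale-free and monotone in practice. An exactly
  polynomial background is removed to numerical zero (a test), and a
  Gaussian peak riding on it is recovered to within 5% of its height.
* `normalize_spectrum()` divides by the sum of absolute intensities
  (idempotent, scale-invariant).

Classification uses random forests (500 trees by default, default
`mtry`, seeded): a two-class model (unlabelled = {0, 5} at%, labelled =
{10–100} at%), a six-level model over labelling levels, and a
leave-one-strain-out harness (`loso_evaluate()`) that trains on all
strains but one and predicts the held-out strain — the test of
cross-taxon generalisation. Metrics follow the screening conventions:
the false-positive rate divides by cells *predicted* labelled and the
false-negative rate by cells *predicted* unlabelled (a false-omission
rate); since the latter differs from the textbook miss rate, both are
reported, clearly named. Zero denominators yield flagged `NA`s, never
errors.

## What the simulators emulate (and what they do not)

`simulate_gradient_experiment()` generates fraction × OTU count tables
with known truth. Each OTU's template mass along density is a Gaussian
centred at the unlabelled banding density (1.773 g/ml for RNA, the
middle of the 1.760–1.786 g/ml concentration range) plus
`full_label_shift × label_fraction` (0.015 g/ml at full labelling), with
sd 0.008 g/ml, a uniform background component (default 10% of each
OTU's mass) reflecting template smeared across the gradient, integrated
over 20 equal-width density bins (equal-volume fractions of a linear
gradient). Reads are drawn multinomially per fraction — sequencing
depth is set per library, as in a real amplicon run — with an optional
per-OTU Gamma multiplier (dispersion 0.1) so counts are marginally
negative-binomial and the downstream model is well specified.
Communities are log-normal (σ = 1.5) over 300 OTUs at 3000 reads per
fraction by default, matching the scale of a typical fraction library
(~3000 post-filter reads); exact per-fraction depths of any given study
are not claimed. In DNA mode the unlabelled banding centre follows the
classic linear G+C–density relation (1.660 + 0.00098 × GC%), compressed
into the heavy part of the secondary-gradient recovery range, and
labelled DNA is re-centred into the light 1.665–1.695 g/ml window; the
G+C effect is invoked qualitatively in the SIP literature without a
secondary-gradient formula, so this mapping is a modelling choice.

The qPCR profile is the per-fraction share of expected total template
mass (summing to 1), mirroring how gradient fractions are validated by
rRNA-copy quantification.

`simulate_spectra()` draws per-cell spectra as sums of Gaussian peaks on
a 2 cm^-1^ grid over 400–1914 cm^-1^ (instrument resolution is
unstated in typical acquisitions; 2 cm^-1^ matches the grating scale),
with peak centres shifted in proportion to at% ^15^N (full-label shifts
of −6 to −10 cm^-1^, consistent with reported ^15^N shifts; the 1003
cm^-1^ reference never shifts), a polynomial fluorescence baseline and
Gaussian noise. "Cyanobacteria-like" strains carry only the 1247, 1340
and 1480 cm^-1^ indicative peaks. `simulate_isotope_timecourse()` draws
replicate δ^15^N values from reported mean ± SEM summaries
(per-replicate sd reconstructed as SEM × √3 for triplicate designs).

None of the generators simulate centrifugation physics, diffusion,
rotor geometry, chimeras, sequencing error, pigment autofluorescence
bleaching, or taxon-specific spectral idiosyncrasies beyond the peak
patterns above. Passing tests therefore demonstrate that the inference
machinery is calibrated and powerful *under the stated statistical
model of SIP data* — not that any particular real dataset would yield
the same calls.

## Numerical choices and degenerate inputs

* Newton iteration on log-mean group fits is damped (step clipped to
  ±2) and started from the Poisson MLE; groups with zero total counts
  get the pseudo-mean and, on the labelled side, p = 1.
* BH correction is computed within each gradient separately, matching
  the per-gradient modelling design.
* All-zero gradients, single-fraction classes, non-monotone densities,
  overlapping windows, all-zero spectra and empty peak tables raise
  errors naming the offending object.
* All stochastic components (community draw, read sampling, spectra,
  forests) are seeded; fixed seeds give bit-identical outputs, and
  pipeline outputs embed the seed and a hash of the analysis
  configuration.

## Study sizes used in the packaged checks

The test suite and the acceptance script run the simulations at the
scale the statistics require rather than the largest size the model
could support: 100 null gradients (300 OTUs × 20 fractions) for the
false-call rate, 50 seeds per abundance level for spike recovery
(one fully labelled OTU at ~0.5% and ~0.01% relative abundance), and
Raman forests of 300 trees over three 8-peak strains (plus one
peak-deficient strain) with 8 cells per labelling level. These sizes
give binomial standard errors of a few percent on the reported rates,
which is the resolution at which the qualitative claims (calibrated
nulls, ~0.5% practical detection threshold, chance-level vs near-zero
OOB error) are meaningful.

## Known limitations

* The dispersion estimator is a transparent stand-in, not a reimplementation
  of any specific empirical-Bayes scheme; absolute p-values will differ from
  other differential-abundance software even where calls agree.
* The hump diagnostic formalises a visual judgement; profiles that are
  bimodal inside the labelled window pass, as a human reviewer would
  likely also accept them.
* The Raman harness is evaluated entirely on synthetic spectra; real
  strain-dependent performance differences (matrix effects, pigments,
  spectral baselines) are out of its reach, and per-strain metrics on
  real data should be expected to be worse than the synthetic ones.
* DNA-SIP support models the G+C effect linearly; heavy-tailed G+C
  distributions or intercalator stoichiometry effects are not modelled.
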