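---
title: "Methods: dominance analysis of engram-synapse proteomes"
author: "engramprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance analysis of engram-synapse proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engramprot)
```

This vignette documents the models, parameter choices and numerical
decisions behind `engramprot`, and what the synthetic-data tests do and do
not establish about real data.

## The experimental design being modelled

Each mouse contributes two sorted synaptosome fractions from the same
dorsal hippocampus: an eGRASP+ fraction enriched for labelled engram-cell
synapses and an eGRASP− fraction of unlabelled synapses. Mice belong to one
of two conditions — aversive contextual fear conditioning (CFC) or neutral
context exploration (CE) — and protein abundances arrive as normalised log2
values. All inference is within-mouse first: the unit of information for a
protein is the vector of paired log2 differences (eGRASP+ minus eGRASP−)
across mice of one condition. This removes mouse-level abundance offsets by
construction and is why `paired_differences()` pairs strictly by
`mouse_id`, never by column position.

## Paired differential expression

The upstream pipeline this package stands in for fits a peptide-level
robust regression per protein. `engramprot` deliberately replaces that
with a protein-level **paired t test** on the difference vectors: the
dominance analysis downstream consumes only (effect size, q-value) pairs,
and a paired t statistic preserves exactly that interface while keeping
the package self-contained. This is a declared simplification, not a
reimplementation of the peptide-level model.

Filters mirror the quantification rules of the emulated workflow:

* a protein must be quantified in at least 50% of samples of each label
  group (`min_group_fraction = 0.5`);
* at least two complete pairs must remain; incomplete pairs are dropped
  per protein (complete-pair analysis, no imputation).

The **effect size** is the mean paired log2 difference standardised to
replicate variability. The emulated description — log2 fold change scaled
to the mean abundance variance across biological replicates — is ambiguous
about the denominator, so both readings are implemented:
`effect_denominator = "paired_sd"` (default) divides by the sample SD of
the within-mouse differences; `"group_sd"` divides by the root mean of
the two group variances. The default was chosen because the paired SD is
the variance actually entering the paired test. The denominator is floored
at `sd_floor = 1e-6` so that zero-variance proteins yield a finite,
flagged (`degenerate_variance`) effect size rather than an error or an
infinity.

q-values are Benjamini–Hochberg adjusted within condition, with the
significance threshold fixed at q < 0.01 throughout, matching the
emulated analysis. The BH step is `stats::p.adjust`; the test suite checks
it against an independent step-up oracle.

## Huber regression and dominance classification

The comparative model regresses CE effect sizes (y) on CFC effect sizes
(x) for proteins quantified in both conditions, using the Huber loss so
that strongly regulated proteins (the scientifically interesting outliers)
do not leverage the fitted line:

* tuning constant `k = 1.345` — the standard value giving 95% efficiency
  under Gaussian errors; the emulated analysis does not state one;
* residual scale re-estimated every IRLS iteration by the normalised MAD
  (constant 1.4826), again because nothing more specific is stated;
* convergence when the largest coefficient change falls below 1e-8, with
  a 200-iteration cap; non-convergence is flagged and the last iterate
  returned rather than discarded, since downstream classification only
  needs the line;
* an exactly (or near-) interpolating fit drives the MAD to zero; the
  iteration stops there with unit weights, which is the correct limit;
* as `k → ∞` the fit reduces to ordinary least squares — the test suite
  verifies agreement with the closed form to 1e-6.

With ŷ(x) the prediction at a protein's CFC effect size, the dominance
score is `effect_CFC − effect_CE` and the classification is:
CFC-dominant when `effect_CFC > ŷ`, the score is positive and
`q_CFC < 0.01`; CE-dominant when `effect_CE > ŷ`, the score is negative
and `q_CE < 0.01`; otherwise none. Two genuinely open readings existed:

1. *"higher observed effect sizes in CFC relative to the predicted CE
   values"* can compare the observed **CFC** value with ŷ (default,
   `rule = "observed_vs_predicted"`) or can mean a negative **CE
   residual** (`rule = "ce_residual"`). Both are implemented; neither is
   claimed as authorial intent. They differ only for proteins whose CFC
   and CE effects both sit on the same side of the line.
2. Bootstrap prediction intervals could gate the classification or be
   descriptive. The stated rule names only effect sizes, their difference
   and q-values, so the intervals are **descriptive only** here; they are
   attached to the dominance table when supplied but never consulted.

Prediction intervals use a **percentile bootstrap** (default 5000 pair
resamples, refit per resample, 2.5/97.5 percentiles of fitted values at
each original x). Percentile rather than BCa because only "bootstrap
resampling" is specified and the percentile interval is the simplest
member of that family; resamples with constant x cannot be refitted and
are skipped and counted. The suite verifies 92–98% empirical coverage on
simulated linear data (200 replicates of n = 500 with 400 resamples
each — the resample count trades Monte-Carlo smoothness for runtime and
does not shift coverage).

Only synaptically annotated dominant proteins enter the compartment
analyses, mirroring the emulated workflow; `dominant_proteins()` applies
that restriction.

## Compartment statistics

Locations collapse by a fixed rule: any presynaptic and any postsynaptic
term → *Both*; only presynaptic → *Presynapse*; only postsynaptic →
*Postsynapse*; generic synaptic terms → *Synapse*. Terms are recognised by
the substrings `presyn`/`postsyn`, which is how the source vocabulary
encodes sidedness; unrecognised terms are logged and treated as generic.

* **Chi-square**: Pearson statistic without continuity correction on the
  dominance × location table, with a warning when any expected count
  drops below 5 (routine at ~33 dominant proteins over 4 locations — the
  statistic is still the agreed summary, the warning keeps the
  approximation honest).
* **Kolmogorov–Smirnov**: the statistic (sup ECDF difference) is the
  contract and is computed exactly; the two-sided p uses the asymptotic
  Kolmogorov series, advisory at small n. The dominant-protein sample
  pools CFC- and CE-dominant scores and is compared against the control
  distribution of all quantified proteins.
* **Logistic regression**: outcome CFC-dominant = 1 vs CE-dominant = 0;
  predictors are indicators for Postsynapse and Presynapse with the
  pooled `{Both, Synapse}` reference — chosen because the emulated forest
  plot reports exactly pre- and postsynaptic odds ratios. Maximum
  likelihood by IRLS (tolerance 1e-10), Wald 95% CIs, McFadden pseudo-R²
  (the flavour is not stated upstream; McFadden is the common default for
  logistic fits), and a likelihood-ratio p against the intercept-only
  model. Complete or quasi-separation — likely with ~33 observations —
  is detected from degenerate fitted probabilities or exploding
  coefficients and triggers a Firth penalised-likelihood fit, flagged in
  the output. For a single binary predictor the fitted odds ratio equals
  the 2×2 cross-product ratio exactly; the suite asserts this identity.
* **Gene-set enrichment**: one-sided hypergeometric upper-tail p
  (equivalently a one-sided Fisher exact test) against a background of
  18,384 prioritisable genes by default, BH-corrected across trait sets.
  The rare-variant proportion comparison conditions on the combined
  margins of the two groups by default; the population is an explicit
  parameter because the upstream choice is not stated.
* **KDE**: Gaussian kernel with Silverman's rule-of-thumb bandwidth;
  constant input would collapse the bandwidth, so a small positive floor
  is substituted and flagged. Group medians accompany the densities.

## Quadrant gating of synaptosome intensities

Gating operates on linear background-corrected intensities. The baseline
threshold formula is not stated upstream, so two documented conventions
are provided and the one used is recorded per run: with a negative
control, mean + 2 SD of the control; without, an Otsu split of the
log-intensity histogram (log because the mixture components are
approximately log-normal, making the histogram bimodal on that scale).
Ties at a threshold count as positive (`>=`), stated explicitly for
reproducibility. Quadrants are Q1 low/low, Q2 low-A/high-B, Q3 high/high,
Q4 high-A/low-B.

The Q3 proportion is reported among marker-positive particles
(denominator excludes the baseline quadrant Q1) because the emulated
per-quadrant proportions describe marker-positive populations; the
all-particle denominator is available via `denominator = "all"` since the
upstream convention is not printed. The Wilson score interval provides
the 95% CI. Sorting QC is the mean of per-run sorted/unsorted percentage
ratios.

## Spine registration

Distances are Euclidean in continuous nm coordinates. Spot-to-filament
distance is the minimum over point-to-segment projections (clamped to
segment ends; zero-length segments skipped). Channel-specific pre-filters
and the registration cutoff use **strict** inequalities (< 500 nm eGRASP
and < 200 nm Grm5 to the filament; < 700 nm to a spine terminal) because
the emulated procedure says "below". Registration is one-to-one
spot-to-nearest-spine; exact ties break to the lexicographically lower
spine id, a documented deterministic choice. What counts as the "spine
terminal" (head centroid vs distal trace endpoint) is left to the caller's
input, as the package cannot recover it from coordinates alone.

The Grm5 colocalization odds ratio for engram-to-engram (YFP+CFP+) versus
nonengram-to-engram (YFP+CFP−) spines is the 2×2 cross-product ratio,
with zero cells Haldane–Anscombe corrected and flagged. Its CI comes from
a **cluster bootstrap** resampling dendrites with replacement within
animals (2000 replicates, percentile interval) — a declared stand-in for
a hierarchical mixed-effects logistic model that respects the
dendrite/animal clustering without fitting random effects. Replicates in
which one spine class disappears are dropped and counted. Intensity
summaries use the natural log (the upstream base is unstated) and report
medians with interquartile ranges per class.

## The synthetic-data generators

The generators define the study conditions under which the package's
guarantees are tested; they are first-class, validated code.

**Paired abundances.** log2 abundance = protein baseline
(N(11, 1.5²), matching the observed median abundance scale) + a per-mouse,
per-protein random effect (SD 0.3) + a planted label effect + residual
noise. Residual SD defaults to 0.25 log2 units, consistent with a median
abundance coefficient of variation just under 20%. Default planted
fractions are 1.5% enriched and 2.5% depleted at ±1 log2 unit, the order
of magnitude of the emulated discovery sets; eight mice per condition.
Enrichment status is drawn once per protein and shared between conditions,
because the emulated proteome shows a largely common signature across
experiences — this is what gives the CE~CFC regression a positive slope —
while condition specificity enters through `dominance_shift` (default
0.5 log2 units), added to CFC effects of postsynaptic proteins and CE
effects of presynaptic proteins. Compartment labels are drawn from a
five-way distribution with 26% synaptically annotated, matching the
annotated fraction of the emulated dataset.

**Particles.** A four-state mixture: a baseline double-negative fraction
(default 20%), and among marker-positive particles a colocalized fraction
(default 80%, the scale of the emulated Q3 proportions) split evenly with
single-marker states. Intensities are log-normal with well-separated
means (log 1000 vs log 100, SD 0.4); within colocalized particles the two
log intensities share a Gaussian copula whose Pearson parameter
`2 sin(π ρ_s / 6)` targets the configured Spearman correlation.

**Geometry.** Dendrites are ~10 µm random-walk polylines; spine terminals
sit 50–150 nm off the polyline. This is deliberately close: the polyline
stands in for the traced filament skeleton *including* spine branches, so
that true puncta fall inside the 200/500 nm spot-to-filament pre-filters,
as they must have in the source tracing for the filter chain to retain
them. Puncta jitter is 50 nm per axis by default (post-deconvolution
localisation error scale). Defaults plant 61.2% CFP+ among YFP+ spines
and Grm5 presence probabilities 0.397/0.344 (EE/NE), i.e. an odds ratio
of 1.26 — the magnitudes of the emulated dataset — across 47 dendrites
from 5 animals.

All generators run under a single seeded RNG stream per call and restore
the caller's RNG state, so identical configurations reproduce
byte-identical outputs and generator calls cannot perturb surrounding
code. (Per-entity sub-streams were considered and dropped: a single
stream is simpler and the package never regenerates entities partially.)

**What passing tests show — and do not.** Parameter-recovery tests
demonstrate that the estimators recover planted truths under Gaussian
noise, log-normal intensity mixtures and isotropic spot jitter. Real data
violate all three in ways the generators do not emulate: missing values
are not completely at random, intensity distributions have heavier tails
and instrument-specific artefacts, spine geometry is anisotropic, and
biological effects are not two-point mixtures. Green tests therefore
validate the *implementation* of the statistics, not the adequacy of
those statistics for any particular real dataset.

## Problem sizes used in the test suite

Simulation-based tests use sizes chosen to keep Monte-Carlo error well
below the tested margins: 50 replicates of 400-protein experiments for
dominance recovery, 200 outer replicates of n = 500 for bootstrap
coverage, 5000 particles and 1000 spines for the colocalization and
overlap recoveries, and 200+ random instances for each oracle-equivalence
property. The pipeline default of 1000 proteins and 5000 bootstrap
resamples reflects a realistic single-run analysis.

## Known limitations

* The paired t test is a protein-level simplification; proteins whose
  evidence lives at the peptide level are treated less efficiently than
  the peptide-level model would.
* Asymptotic p-values (K-S, chi-square, Wald) are rough at the ~33-protein
  scale of the dominant set; the statistics themselves are exact and the
  package warns where approximations thin out.
* The cluster bootstrap treats dendrites as exchangeable within animals;
  a genuine hierarchical logistic model would also pool information
  across animals.
* `collapse_location()` relies on substring conventions of the synaptic
  ontology's term names, not on ontology identifiers.
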