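---
title: "Quantifying organelle stress phenotypes with mamquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organelle stress phenotypes with mamquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamquant)
```

mamquant turns a family of classically hand-made cell-biology measurements
into scripted, seeded, testable procedures: pixel-overlap quantification of
ER–mitochondria contact sites (MAMs), mitochondrial length morphometry,
tandem-fluorophore autophagy and mitophagy readouts, reference-normalized
calcium traces, fractional ATP bioenergetics, flow-cytometry summaries, and
volcano-filter transcriptomics screening. This vignette explains the
measurement models, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical choices behind the
implementation.

## The overlap index

Contacts between the ER and mitochondria are narrower than the resolution
of conventional light microscopy, so in practice a "contact" is scored
where the two organelle signals overlap after binarization. The pipeline
is:

1. **Uniform preprocessing.** Every channel in a comparison is
   contrast-stretched between the same percentile bounds
   (`preprocess_channel()`, default 0–100) and optionally unsharp-masked.
   `preprocess_batch()` refuses per-image parameter sets: fold-change
   statistics are only meaningful when every image is adjusted
   identically.
2. **One threshold per batch.** The default rule computes a single Otsu
   threshold from the pooled pixel histogram of the control batch
   (`batch_otsu()`) and applies it to all images; a fixed numeric
   threshold can be substituted. A per-image threshold would absorb
   exactly the group differences being measured.
3. **Small-object removal.** 8-connected components smaller than 10 px
   are removed; a component of exactly 10 px survives (the rule is
   strictly-less). 8-connectivity is the common convention for
   fluorescence puncta; it is recorded in the mask provenance along with
   the threshold.
4. **Pixel intersection.** `overlap_pixels()` counts coordinates
   foreground in both masks; `triple_overlap()` adds a third channel (for
   example a protein stain expected to be enriched at contacts).
5. **Fold change.** `overlap_index()` divides each sample's overlap count
   by the mean count of the control group. The control-group mean index
   is therefore 1 by construction, and group results are reported as
   mean ± SEM.

The denominator is the control-group mean of overlap counts — not a
per-image normalization by channel area — because the statistic is defined
as a fold change of overlapping pixels across samples. Pearson's
coefficient (`pearson_colocalization()`) is computed on the raw adjusted
intensities over the cell ROI, never on binarized masks: the two statistics
answer different questions (covariation of intensities vs area of
co-occupancy) and are kept strictly separate.

Whether overlap is computed per cell or per field, and which stretch
bounds are used, are deliberately exposed parameters recorded in
provenance rather than hidden constants.

## Mitochondrial morphometry

Lengths are classically measured by hand-tracing each mitochondrion. The
automated surrogate is: skeletonize each 8-connected object (Zhang–Suen
thinning, `thin_mask()`) and take the longest end-to-end geodesic path
through the skeleton, times the pixel size. Two standard digital-geometry
corrections are applied (`measure_lengths()`):

- **Kulpa step weights.** Summing unit/√2 steps along a pixel path
  overestimates the Euclidean length of straight segments by up to ~8%
  depending on orientation. The classical corrected weights (0.948 for
  orthogonal, 1.340 for diagonal steps) remove this bias.
- **End-cap extension.** Thinning erodes stroke ends slightly. Each path
  end is extended by the object's geodesic reach beyond that endpoint
  minus the local half-width (from the Euclidean distance transform), so
  a perfectly recovered medial axis receives no extension. On synthetic
  capsules the corrected estimator is unbiased with per-object errors
  under ~8%; uncorrected errors reach 12–16% for short objects.

Branched skeletons use the longest end-to-end path, the closest analogue
of tracing "along the entire length". Objects under the 10-px minimum are
excluded, mirroring the colocalization filter.

Each length is classified by `classify_length()`: fragmented below 2.5 µm,
intermediate in the closed interval [2.5, 5] µm, filamentous above 5 µm.
The boundary values are assigned to the intermediate bin — the printed
interval "2.5–5" is taken literally as closed, with "< 2.5" and "> 5"
strict — and the binning is total and exclusive over all non-negative
lengths. Doubling the pixel size doubles every length, so category changes
under recalibration can only move in the direction the bins imply.

## Tandem-reporter flux readouts

Tandem fluorophores (e.g. mCherry-EGFP-LC3B) exploit the acid-quenching of
EGFP: vesicles that have fused with lysosomes appear red-only, neutral
vesicles appear in both channels. `detect_puncta()` segments the red
channel (the acid-stable fluorophore, present in all puncta) and records
both channels' mean intensities per punctum. `classify_puncta()` calls a
punctum red-only when its green mean does not exceed a robust background
threshold, median + k·MAD of the non-punctum green pixels (k = 3 by
default). No numeric criterion for green positivity exists in common
practice; a robust background rule with the multiplier recorded in the
output is the defensible automated version. The flux readout is
`red_puncta_percentage()` = 100 · red / total, so red and dual percentages
sum to exactly 100.

For mito-targeted tandem reporters the readout is intensity-based instead:
`red_only_intensity_percentage()` = 100 · ΣR/(ΣR+ΣG) over the ROI, which
is invariant to common rescaling of both channels. Both per-cell and
pooled aggregation are possible by choice of ROI; results should state
which was used. `copositive_puncta_count()` scores marker vesicles (LC3,
CD63) containing mitochondria; "containing" defaults to any pixel overlap,
with an optional fractional-footprint requirement, making explicit what a
manual "engulfing" judgement leaves implicit.

## Calcium traces

Organelle-targeted calcium indicators bleach and drift; a co-expressed
calcium-insensitive reference (ER-GFP, mitoRFP) is therefore imaged
alongside. `dff0()` normalizes ratio-first: R(t) = indicator/reference per
timepoint, then ΔF/F0 = (R(t) − R(0))/R(0). Any multiplicative factor
shared by both channels — bleaching, excitation drift — cancels exactly in
R, and ΔF/F0 at time zero is exactly 0. For a store-depletion (efflux)
response with first-order kinetics, 1 + ΔF/F0 = exp(−kt), so
`fit_decay_rate()` recovers k by log-linear regression. Group curves are
pointwise mean ± SEM (`summarize_traces()`); whether replication is across
cells or experiments is the caller's framing — the function simply pools
the traces it is given.

## ATP metabolic profiling

Inhibitor panels partition ATP production: 2-DG blocks glucose utilization
(glycolysis and glucose-fed TCA), oligomycin A blocks mitochondrial ATP
synthase. With condition means A:

- glucose dependence g = (A_ctrl − A_DG)/A_ctrl, FAO/AAO capacity = 1 − g;
- mitochondrial dependence m = (A_ctrl − A_OA)/A_ctrl, glycolytic
  capacity = 1 − m.

Each capacity is stored as the exact floating-point complement of its
dependence, so the pair identities hold to machine precision, and the
profile is invariant to rescaling all luminescence values. Fractions are
computed on condition means by default (ratios of ATP levels, not
replicate-wise ratios); a per-replicate mode pairs matched replicates. The
combined DG+OA condition is loaded and reported but enters no default
formula: no standard combination rule exists, and this ambiguity is
surfaced as an explicit option (`baseline = "dgoa"` subtracts the combined
condition's mean as a non-glycolytic, non-mitochondrial background) rather
than a hidden choice. Fractions outside [0, 1] — possible with noisy or
paradoxical plates — are returned unclipped with an `out_of_range` flag.

## Flow-cytometry summaries

`flow_summary()` reports per-sample arithmetic-mean fluorescence
intensities (MFI — "mean" is taken at face value; the choice is recorded
here rather than silently geometric), the TMRM/MitoTracker-Green ratio
(membrane potential per unit mitochondrial mass), and fold changes against
the control-group mean, whose fold change is 1 by construction.

## Expression screening

`volcano_filter()` applies the two-dimensional cutoff |log2FC| ≥ 2 and
p ≤ 0.01, both inclusive: the p-cutoff is conventionally printed as "≤",
and the fold-change boundary is made inclusive for symmetry (the choice is
recorded here; genes exactly at boundary are vanishingly rare in real
tables). The calls partition the table, and negating all fold changes
swaps up and down calls exactly. Whether the p-value column holds raw or
adjusted values is the caller's decision; the filter operates on whatever
is supplied. `map_mitochondrial()` flags calls by case-insensitive
membership in a user-supplied gene list (a MitoCarta-style inventory; the
list itself is not bundled — tests use synthetic lists). `ddct()`
implements 2^-ΔΔCt with replicate cell means and is invariant to
per-condition constant Ct offsets.

## The synthetic-data generators

Every generator is a pure function of its parameters and one explicit
seed (`withr::with_seed`; the global RNG state is untouched), and returns
its ground truth alongside the rendered data.

- **Cell images** (`sim_cell_image()`): ER as dilated persistent random
  walks, mitochondria as capsules (stadium shapes), protein puncta as
  discs. True contact is defined as `dilate(ER, d) ∧ dilate(mito, d)` with
  d = 1 px by default — a small tolerance reflecting that
  diffraction-limited overlap, not molecular apposition, is what the
  measurement sees. The true contact area is directly controllable:
  `target_contact_px` adds ER-crossing capsules until the contact mask
  reaches the target (proposals overshooting by more than 5% are
  rejected so grazing contacts can fill the remainder); non-contact
  mitochondria are placed away from the dilated ER so chance overlap does
  not contaminate the truth. Default geometry: 192×192 px at 0.07 µm/px
  (super-resolution scale), foreground 0.6, background 0.02 on the [0,1]
  scale.
- **Capsule images** (`sim_capsule_image()`): non-overlapping capsules
  with true length = Euclidean centreline length × pixel size; lengths
  default to uniform on 1–8 µm, spanning all three morphology bins.
  Capsules are the simplest shape whose length is analytically known;
  placement failure raises an error naming how many were placed.
- **Reporter images** (`sim_reporter_image()`): the red-only count is
  `round(n · f)` with ties rounded half away from zero, making noiseless
  recovery exact and testable.
- **Calcium traces** (`sim_calcium_traces()`): A·exp(−kt) efflux or
  saturating influx, constant reference, optional shared bleaching
  factor.
- **ATP plates** (`sim_atp_plate()`): condition means follow the
  fraction definitions; DGOA defaults to B(1−g)(1−m) clipped at zero (a
  modelling choice, flagged as such). Replicate noise is mean-preserving
  multiplicative lognormal at a stated CV, so cv = 0 reproduces the truth
  to machine precision and the analytic fractions recomputed from a
  noiseless plate equal the ground truth exactly.
- **Gene tables** (`sim_gene_table()`): spiked genes have |log2FC| at or
  beyond the effect size and p below the significance cutoff; null genes
  have log2FC ~ N(0, 0.25) and uniform p, so crossing both cutoffs by
  chance is practically impossible and truth-label recovery is exact.
- **Flow events** (`sim_flow_events()`): independent per-channel
  lognormals, the conventional model for dye-intensity distributions.

What the generators do **not** emulate: point-spread-function optics,
realistic camera noise models, 3D stacks, touching/overlapping organelles,
spatially varying background, or cell-to-cell biological heterogeneity.
Passing recovery tests therefore demonstrates that the measurement code is
correct and unbiased under controlled conditions — not that segmentation
choices are optimal for any particular microscope or cell type.

## Numerical choices and degenerate inputs

- Contrast stretch of a constant image returns zeros (the bounds
  coincide); percentile bounds are validated as 0 ≤ low < high ≤ 100.
- Thresholding uses ≥, so a threshold of 0 selects everything.
- Pearson's coefficient with zero variance, flux percentages with zero
  puncta or zero total intensity, and SEM of a singleton group are
  reported as `NA` with an explanatory warning rather than fabricated.
- A zero control-group mean overlap makes the fold change undefined and
  is an error, as is a non-positive reference in ΔF/F0 (the offending
  timepoint is named).
- `compare_groups()` uses Welch's unequal-variance t-test — the safer
  default when only "t-test" is specified — and reports the
  zero-variance-in-both-groups case explicitly as degenerate instead of
  erroring or fabricating a statistic.
- Component labeling is 8-connected throughout and deterministic
  (components numbered in raster order).
- Pipeline runs (`run_pipeline()`) derive all stage seeds from the single
  config seed and write no timestamps, so identical config + seed gives
  byte-identical outputs.

## Validation scale

The test-suite and acceptance-script problem sizes were chosen so that the
full validation runs in well under a minute on one CPU while still being
statistically meaningful: 100 random 64×64 masks for the pixel-level
oracles, 10 images per group at 192×192 px for overlap-index recovery
(group-mean index within 15% of a true 2× contact ratio at 10% foreground
noise), 30 noiseless capsules for morphometry (lengths within 10%,
categories exact ≥ 0.3 µm from a bin boundary), 200 plates at cv = 5% for
ATP fraction recovery (each fraction type within ±0.05 over the
replication; per-plate scatter at this noise level is ≈ 2.4% SD, so
per-plate extremes of ~0.07 are expected and are not a defect), and exact
checks everywhere a noiseless closed form exists.

## Known limitations

- Morphometry assumes resolvable, non-touching mitochondria; a fused
  network is measured as one object's longest path, not decomposed.
- The overlap index is resolution- and threshold-dependent; it is a
  relative statistic (fold change under uniform processing), not an
  absolute contact-area estimate.
- Green-positivity classification depends on the background-pixel pool;
  images dominated by foreground would need an explicit background ROI.
- The DGOA combination rule in the plate generator is a modelling
  convention; real combined-inhibition data may deviate from
  multiplicative independence.
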