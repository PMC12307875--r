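# mamquant

Quantification of ER–mitochondria contact sites (MAMs), mitochondrial
morphology, autophagy/mitophagy flux, calcium dynamics, ATP bioenergetics
and stress-transcriptomics readouts — the image- and plate-based
measurements used to characterize organelle stress phenotypes (for example,
how ER stress reshapes mitochondria in neuronal cell models). The package is
aimed at cell biologists who have multi-channel fluorescence micrographs,
plate-reader tables, flow-cytometry event tables or per-gene statistics and
want reproducible, scripted versions of the classic Fiji/MATLAB hand
measurements — plus seeded synthetic-data generators with known ground
truth, so every stage can be validated by parameter recovery without any
external data.

## What it computes

- **Overlap index** (MAM quantification): channels are contrast-stretched
  uniformly across a batch, binarized with one pooled Otsu threshold,
  puncta under 10 px removed, and the number of pixels foreground in both
  channels counted. Each sample's overlapping-pixel count is expressed as a
  fold change over the control-group mean:
  `OI_i = overlap_i / mean(overlap_control)`, so the control mean is 1 by
  construction. Two- and three-channel intersections and Pearson's
  colocalization coefficient on raw intensities are included.
- **Mitochondrial morphometry**: per-object length as the longest geodesic
  path through a Zhang–Suen skeleton (with Kulpa step-weight and end-cap
  corrections), classified as fragmented (< 2.5 µm), intermediate
  (2.5–5 µm) or filamentous (> 5 µm).
- **Tandem-reporter flux**: red-puncta percentage
  (`100 · red / total`) for mCherry-EGFP-LC3B-style reporters, red-only
  intensity percentage (`100 · ΣR / (ΣR + ΣG)`) for mito-targeted tandem
  reporters, and counts of marker puncta co-positive for mitochondria.
- **Calcium traces**: reference-normalized ΔF/F0,
  `R(t) = F_ind(t)/F_ref(t)`, `ΔF/F0 = (R(t) − R(0))/R(0)`, with pointwise
  group mean ± SEM and first-order rate fitting.
- **ATP metabolic profiling**: with condition means `A` under vehicle,
  2-deoxy-D-glucose (DG) and oligomycin A (OA),
  glucose dependence `= (A_ctrl − A_DG)/A_ctrl`, FAO/AAO capacity its
  complement, mitochondrial dependence `= (A_ctrl − A_OA)/A_ctrl`,
  glycolytic capacity its complement.
- **Flow summaries**: per-sample mean fluorescence intensities, the
  TMRM/MitoTracker-Green potential-to-mass ratio, fold changes vs control.
- **Expression screening**: volcano filtering (|log2FC| ≥ 2, p ≤ 0.01,
  both inclusive), mitochondrial-gene mapping against a user-supplied list,
  and 2^-ΔΔCt qPCR quantification.
- **Pipeline**: `run_pipeline()` chains simulate → colocalize → morphometry
  → ATP profiling deterministically from one seed and writes CSV/JSON
  outputs; `compare_groups()` provides the Welch t comparison used for
  figure-style group contrasts.

## Worked example

```r
library(mamquant)

# simulate a control/stress comparison with a known 2x contact-area ratio
imgs <- c(
  lapply(1:10, function(i) sim_cell_image(target_contact_px = 300,
    noise_sd = 0.06, sample_id = paste0("ctrl_", i), group = "control",
    seed = i)$image),
  lapply(1:10, function(i) sim_cell_image(target_contact_px = 600,
    noise_sd = 0.06, sample_id = paste0("tg_", i), group = "stress",
    seed = 100 + i)$image))

er   <- preprocess_batch(imgs, "er")
mito <- preprocess_batch(imgs, "mito")
ctrl <- vapply(imgs, function(x) x$group == "control", logical(1))
thr_er   <- batch_otsu(er[ctrl])     # one threshold for the whole batch
thr_mito <- batch_otsu(mito[ctrl])

meas <- do.call(rbind, lapply(seq_along(imgs), function(i)
  overlap_pixels(binarize_and_filter(er[[i]], thr_er),
                 binarize_and_filter(mito[[i]], thr_mito),
                 sample_id = imgs[[i]]$sample_id,
                 group = imgs[[i]]$group)))
overlap_index(meas, control_group = "control")$summary
#>     group  n mean_index  sem_index
#> 1 control 10   1.000000 0.03185491
#> 2  stress 10   2.157237 0.03927153
```

The stress group's mean overlap index (≈ 2.16) recovers the simulated
two-fold increase in true contact area; the control mean is exactly 1
because the index is defined as a fold change over the control mean.

```r
profile <- metabolic_profile(sim_atp_plate(0.4, 0.6, seed = 1)$plate)
profile
#> <metabolic_profile>
#>   glucose_dependence          37.5 %
#>   fao_aao_capacity            62.5 %
#>   mitochondrial_dependence    57.9 %
#>   glycolytic_capacity         42.1 %
```

With 5% replicate noise on three replicates the recovered dependencies sit
within a few points of the generating truth (40% / 60%); averaging over
plates removes the residual scatter (see `scripts/acceptance.R`).

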