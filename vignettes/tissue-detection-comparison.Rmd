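---
title: "Comparing classical and learned tissue detection and its downstream effect on slide-level grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing classical and learned tissue detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Patch-based AI pipelines for whole-slide images (WSIs) begin with tissue
detection: a binary segmentation at a heavily downsampled resolution that
decides which patches ever reach the downstream model. Two families of
tissue detectors dominate practice — a classical one (Otsu's global
threshold plus morphological cleanup) and a trainable one (an
encoder–decoder segmentation network). `tissuedetect` implements both,
the patch-tiling conventions that connect a mask to a downstream grader,
and the paired statistical machinery for asking whether the choice of
tissue detector changes slide-level ISUP grading — on synthetic pyramidal
slides with exact planted ground truth, so every failure mode is by
construction rather than by annotation.

## The synthetic slides

`generate_slide()` renders a slide at 1.0 µm/px and builds a pyramid at
{1, 2, 4, 8} µm/px by Lanczos-3 downsampling (a separable windowed-sinc
filter whose support scales with the downsampling factor; constants are
preserved exactly). Ground truth is rasterized at 8.0 µm/px by area
majority: a coarse pixel is tissue when more than half of its footprint is
covered by the analytic fragment shape.

Tissue fragments are unions of randomly rotated ellipses with a smooth
low-order radial deformation, laid out in separate horizontal bands the
way sectioned core-needle biopsies sit on a slide. Defaults — 1024 µm
square slides, two fragments of ~500 µm major axis — keep the tissue area
fraction near 0.2 and generation under two seconds per slide. The
rendering regimes mirror the failure modes the comparison cares about:

* **normal**: clearly stained pinkish tissue on a bright background, with
  smooth achromatic texture; trivially separable by a luminance threshold.
* **pale**: tissue whose color is constructed to have *exactly* the
  background's luminance, differing only in chroma (the pixel noise is
  achromatic, shared across channels). An inverted-luminance Otsu cut has
  structurally nothing to work with — the designed analogue of weakly
  stained, eosin-only tissue — while any color-aware detector still has a
  clean signal.
* **pen marks**: thick saturated strokes, drawn outside tissue and labelled
  background in truth, so including them costs measurable precision.
* **debris**: small dark specks (area well below the cleanup floor)
  outside tissue; a correctly parameterized area filter removes them.
* **lesion**: an optional graded (ISUP 1–5) ellipse planted inside the
  first fragment, occupying a configured fraction of it;
  `pale_fragments` renders individual fragments pale so a *lesion-bearing*
  fragment can be made invisible to thresholding while the rest of the
  slide stays detectable.

Every slide derives a private RNG stream from `(seed, slide_id)`, so
cohorts are reproducible slide-by-slide regardless of generation order.

What the generator does **not** emulate: real H&E texture, stain
variation and scanner-specific color response, blur/fold/coverslip
artifacts, and annotation noise. Passing the recovery criteria here shows
the pipeline machinery and its designed asymmetries are correct — not
that either detector would achieve these numbers on clinical scans.

## Classical arm: Otsu + morphology

`segment_threshold()` works only at 8.0 µm/px: channel transform →
Gaussian blur → 256-bin histogram → `otsu_threshold()` (exhaustive
between-class-variance maximization; ties break to the smallest level) →
binarize (tissue strictly above the cut) → closing → opening → removal of
objects below `min_object_area_px` → filling of holes below
`max_hole_area_px`. All stages are parameterized through
`threshold_params()`; the shipped `"uniform"` preset (inverted luminance,
blur 1, disc radius 2, area floor 120 px, hole cap 200 px) is the single
parameter set used for every slide in the comparison. A `"saturation"`
channel mode is provided because weakly stained tissue separates better in
saturation; no claim is made that either matches any particular production
implementation. A degenerate histogram (all mass in one bin — a featureless
slide) yields an empty mask with the failure flag set rather than an
exception, because the study design tallies detection failures instead of
crashing on them.

## Learned arm: a desk-scale encoder–decoder

The trainable segmenter is a depth-2 encoder–decoder with skip
connections (~15k parameters, channel widths 8/16/32), written directly in
R with hand-derived backpropagation; convolutions are evaluated as
nine-tap shifted matrix products so both passes run inside BLAS. This
deliberately replaces a large pretrained-backbone UNet++ — at this
problem scale the *training protocol* is the object of study, not the
backbone. The protocol follows the full-scale recipe:

* pixel-wise binary cross entropy with positive-class weight 5.0;
* decoupled-weight-decay Adam (AdamW), epsilon 1e-6, weight decay 0.01;
* per-epoch global-pixel-pool F1 on a validation split for checkpoint
  selection and early stopping;
* augmentation: flips, 90° rotations, mild color jitter (configurable
  strength; more color augmentation is what would help pale tissue most).

`train_config()` records the full-scale defaults (learning rate 1e-6,
512-px tiles); `desk_train_config()` is the configuration actually used
here: 128-px tiles, learning rate 2e-3 cosine-annealed over 40 epochs,
batch size 1. Two desk-scale design choices deserve a note:

* **Input featurization.** The network sees RGB plus 5× the three channel
  differences (six channels). With raw RGB only, a net this small learns a
  single luminance-like feature and trades pale-slide sensitivity against
  normal-slide boundary precision; exposing chroma directly lets it hold
  both. A large backbone would learn this internally.
* **Validation F1 is pooled over pixels** (not averaged per tile), the
  natural choice when tiles have wildly different tissue content; this is
  a guess where the full-scale recipe is silent.

Inference uses the overlap-discard convention: the 8 µm/px raster is
mirror-padded to a tile multiple, tiles are spaced `tile − 2·overlap`
apart, each interior tile contributes only its central band (borders of
the image keep their outer margin — no neighbor exists), and the assembled
mask covers every pixel exactly once. Exactness requires the stride to
divide the tile size, which the canonical geometries (512/128, 256/64,
128/32) satisfy. Probabilities are binarized at 0.5.

Model selection among candidate segmenters follows the study rule: best
sensitivity subject to precision ≥ 90%, ties to the higher precision.

## Tiling for the grading model

Grading tiles are 256 px at 1.0 µm/px, extracted from the closest finer
pyramid level by Lanczos resampling (bit-exact crop when the level
matches). A tile is kept when at least 10% of its footprint is tissue
according to the segmentation mask — evaluated on the 8 µm/px mask window
(32×32 per tile), which for aligned tiles equals the fraction on a
nearest-neighbor upsampled mask. Training grids abut; inference grids
overlap. The phrase "128 pixel overlap" is read as 128 px *shared between
neighboring tiles* (stride 128 for 256-px tiles, i.e. 64 px discarded per
edge): the alternative per-edge reading would give stride zero, which the
geometry refuses.

## The downstream surrogate

The real grading model cannot run here, so the downstream impact analysis
uses a deterministic coverage-based surrogate: with `covered` the fraction
of the planted lesion under the union of kept-tile footprints, the grade
is the reference ISUP when `covered ≥ 0.5`, one grade lower (floored at 1)
when `0.1 ≤ covered < 0.5`, and benign otherwise. The thresholds are
chosen so that a wholly missed fragment reproduces the
"malignant-read-as-benign" pattern and a partly missed one reproduces the
one-grade drop. Because the surrogate is a pure function of the mask,
any between-arm disagreement is attributable to tissue detection alone —
exactly the quantity under study — at the cost of not modelling grading
noise, which is why no claim is made that surrogate discordance *rates*
match the full-scale ones.

`run_comparison()` applies the protocol: segment each slide with both
arms; slides where either arm detects no tissue are excluded and tallied
in a paired failure table; included slides are tiled per arm, graded per
arm, and summarized by per-arm quadratic weighted kappa (QWK) with a
bootstrap CI plus a discordance summary.

## Statistics

* `clopper_pearson()`: exact two-sided binomial interval from beta
  quantiles. "Exact binomial tests" admits several readings; this one
  reproduces both published failure-rate intervals to the printed digit,
  which settles the interpretation.
* `mcnemar_exact()`: the doubled-tail exact binomial
  `min(1, 2·P(X ≤ min(b,c)))` as primary — with discordant counts as
  small as 2 the chi-square approximation has no business being primary —
  and the continuity-corrected chi-square as a secondary mode.
* `quadratic_weighted_kappa()`: `1 − Σ(W·O)/Σ(W·E)` with squared-distance
  weights over categories 0 (benign) through 5; two identical constant
  vectors give 1 by convention (zero expected disagreement).
* `bootstrap_ci()`: seeded percentile bootstrap (2.5/97.5) over the
  aggregation unit, 1000 replicates by default; replicates on which the
  statistic is undefined are redrawn and counted. The percentile method is
  the simplest standard choice for kappa CIs.
* `pixel_metrics()`: sensitivity and precision per slide; an empty
  prediction flags precision as undefined and the slide is excluded from
  precision aggregation (failures are accounted separately).
* `discordance()`: direction counts (A-correct-only / B-correct-only /
  neither) are defined over *malignant* discordant slides, matching how
  the shares 44/120 and 45/120 are defined; the 6×6 confusion matrix of
  (arm A × arm B) grades covers all discordant slides.

## The standard cohort and problem sizes

`standard_cohort_manifest()` builds 67 single-patient slides: 24 training,
and 43 curated slides split 30%/70% at patient level into 13 validation
and 30 evaluation slides. The regime cycle (1/2 normal, 1/4 pale, 1/8 pen,
1/8 debris; lesions on ~70% of slides across all grades) gives every split
cell each regime. These sizes keep a full run — generation, training,
both-arm evaluation, downstream comparison — inside a few CPU-minutes
while leaving the designed asymmetry unambiguous: thresholding fails on
every pale slide and the trained network on none, the synthetic analogue
of the published failure asymmetry.

## Numerical conventions and degenerate inputs

Otsu ties break to the smallest level; grid and padding offsets split
evenly with the extra pixel to bottom/right; mirror padding is
half-sample symmetric (defined for any pad width, including a 1×1 input);
tile footprints that leave the mask are clipped and fractions taken over
the clipped area; a cohort must be non-empty and kappa needs at least two
cases; empty training sets are errors while featureless slides are
failures, not errors.

## Known limitations

The generator's realism limits are listed above. The network is far below
production scale and its desk-scale hyperparameters are tuned to this
generator, not to histology. QWK bootstrap resampling is at slide level by
default (`aggregation_unit` records the choice; location/patient pooling
of multi-slide cases is supported by labelling, not enforced). AUC-based
screening summaries are intentionally absent: they require continuous
scores a coverage surrogate does not have.
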