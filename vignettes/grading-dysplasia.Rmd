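---
title: "Grading decreased-granules dysplasia in bone-marrow smears"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading decreased-granules dysplasia in bone-marrow smears}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(smeargrade)
```

## The problem and the pipeline

Myelodysplastic syndromes are diagnosed in part from cell morphology on
stained bone-marrow smears: a lineage is dysplastic when ≥ 10% of its
cells look abnormal. The abnormality this package focuses on is
*decreased granules* (DG) in neutrophils — a loss of the fine pink
azurophilic granulation — graded ordinally 0 (normal), 1 (intermediate),
2 (dysplasia), 3 (severe). The pipeline runs: field image → cell
detection and cropping → multi-label ordinal regression → test-time
rotation ensemble → category gating and rounding → screening metrics,
with an expert-revision loop around the labels. Each stage is a module
with a narrow contract, so a clinical deployment can swap in, say, a
trained neural detector while keeping everything downstream unchanged.

## The label schema

The regressor's head has one output per label of a fixed, ordered
34-label vocabulary: 24 ordinal dysplasia labels (maximum grade 3) across
erythroid (9), granulocytic (10) and megakaryocytic (5) lineages; three
normal-cell labels (NE, NN, NM); the myeloblast presence label (MB); and
six not-applicable cell types (RBC, IG, EOS, LYM, PC, PLT), all with
maximum grade 1. Standard cytomorphology tables list more named entities
than a 34-dimensional head can carry one-to-one, and they reuse
abbreviations across lineages (multinuclearity appears in both the
erythroid and megakaryocytic sections — here MNE / MNM), so the selection
above is a design decision: every dysplasia scale is kept, "normal X"
rows become explicit presence labels, and the rarest not-applicable
types are folded away. The schema is data (a CSV with
`abbreviation,name,category,max_grade`), so an alternative vocabulary
loads without code changes; grade-vector index *i* always means schema
label *i*, and the schema is persisted with every dataset and model
archive.

## The regressor

Architecture: feature backbone → hidden fully connected layer → dropout
(rate 0.5) → linear head → per-label `max_grade · sigmoid`. The sigmoid
scaling confines every score to its legitimate grade range; an
unconstrained linear or ReLU output can wander far outside [0, 3] and a
single such sample dominates a quartic loss, which is why bounded
outputs are part of the contract rather than an option.

The loss is the weighted mean quartic
`Σ w_ℓ (p_ℓ − t_ℓ)⁴ / Σ w_ℓ` with weight 10 on DG and 1 elsewhere.
Relative to squared error it concentrates the penalty on large grade
errors — doubling one deviation multiplies its contribution by exactly
16 — encoding the screening priority that a two-grade miss is far worse
than two one-grade misses. Dividing by `Σ w` keeps the loss scale
comparable when weights change.

Two backbone profiles satisfy the pluggable-extractor contract:

* **transfer** wraps a user-supplied pretrained feature-extractor
  function (`extractor(raster) -> numeric`); the hidden layer adapts its
  features, and the optimizer keeps the extractor-side and head-side
  groups at separate learning rates (reference defaults 1e-5 / 1e-4).
* **tiny** is a self-contained small network for desk-scale work: a
  fixed image stem — per-channel block-mean downsampling (12×12 RGB,
  24×24 high-pass), a Gaussian-blur high-pass channel (σ 1.5 px) that
  responds to granule texture, and 15 rotation-invariant summary
  statistics (cell / nucleus / cytoplasm area fractions, high-pass
  energy, granule-coloured pixel fractions at three colour-contrast
  thresholds, mean stain colours) — followed by the trainable hidden
  layer and head. The grid features are centred on the crop's border
  (background) colour so that only cell matter carries signal.

Numerical choices in training: leaky rectifier (slope 0.05) so hidden
units cannot die irrecoverably under aggressive learning rates; head
weights initialized near zero (sd 0.002) as usual for regression heads,
which also makes an untrained model's output insensitive to
interpolation-level input perturbations; Adam with bias correction; L2
added to every gradient (coefficient 1e-6); inverted dropout. Training
is wrapped in a seeded RNG scope, so a fixed seed reproduces the loss
history bit for bit.

The reference protocol (120 epochs, batch 10, rates 1e-5/1e-4) is tied
to fine-tuning a large pretrained backbone. The desk-scale tiny protocol
used throughout the tests and the acceptance script is 60 epochs, batch
10, both groups at 5e-3, hidden width 48: a 2-layer network needs larger
steps and converges in minutes on one CPU. Problem sizes in the shipped
studies — 300 cells for the held-out split, 150 cells for 3-fold
cross-validation — are the package's chosen desk scale: large enough
that binarized sensitivity/specificity estimates have single-digit
percentage noise, small enough to run routinely.

## Imbalance-aware augmentation

Every crop is pasted into the centre of a fixed square canvas (default
96 px) filled with the crop's mean border colour, which removes boundary
effects and makes later rotations safe. Each epoch, every occurrence is
randomly transformed — scale uniform on [0.8, 1.2], rotation uniform on
[0°, 360°), independent fair-coin horizontal/vertical flips, integer
translation within 10% of the canvas — as a single bilinear affine warp
about the canvas centre. Rare-label oversampling repeats item *i*
`round(C_max / C_label(i))` times per epoch, where the item's *primary
label* is its highest-graded label (ties broken by schema order;
all-zero items pool as "none"). With counts {100, 10} the totals
equalize exactly; the ratio of per-label epoch totals stays ≤ 2 whenever
every label has at least one item. Balancing by the primary label
(rather than by full multi-label membership) is a design decision: it is
well-defined for any label structure and matches the intent of
"approximately the same number of images with each label".

## Inference: rotation ensemble and gating

Grade scores depend on the cell's orientation, so inference scores all
16 rotations (22.5° apart) of the pasted canvas and keeps the per-label
maximum. Rotation uses bilinear interpolation about the canvas centre
with border-colour fill. The final DG grade is gated: if the label with
the highest grade-normalized score (`score / max_grade`, ties to the
earliest schema label) is not granulocytic the grade is 0; otherwise the
ensemble DG score is rounded half-away-from-zero and clipped to
{0, 1, 2, 3}. Rounding x.5 up favours sensitivity over missed dysplasia,
the right bias for screening. The continuous (pre-rounding) DG score is
retained — gated to 0 for non-granulocytes — because AUC and the DG1
re-binning need a continuous quantity. How a lineage category should be
derived from the 34 outputs is not fixed by any standard; the normalized
argmax is this package's rule.

## Stratified cross-validation

Folds come from greedy iterative multi-label stratification: repeatedly
take the label with the fewest remaining unassigned items and hand its
items one by one to the fold with the greatest remaining demand for that
label (ties → greatest total demand → seeded random draw); label-free
leftovers go to the fold with the greatest total demand. On instances
small enough to enumerate exhaustively, the greedy assignment attains
the optimal maximum per-label fold imbalance, and 11 single-label items
over 5 folds always split {2,2,2,2,3}. Stratification keys are binary
"has label at grade ≥ 1" indicators by default — grades of one label are
pooled, matching stratification "by type of dysplasia" — with a
per-(label, grade) option (`by_grade = TRUE`) for finer control. The
driver trains one model per fold on the complement and predicts the
held-out cells, so each item is predicted exactly once by a model that
never saw it.

## Evaluation

Binarized metrics follow the five screening formulas (sensitivity,
specificity, PPV, NPV, accuracy) on the 2×2 collapse of the ordinal
confusion matrix; ratios with zero denominators are reported as
*undefined* (NA), never coerced to 0. AUC is the rank-based Mann–Whitney
statistic with ties counted ½, computed from midranks (equivalent to
exhaustive pair counting and invariant under monotone score
transforms). The stricter "obvious dysplasia" analysis drops true
grade-1 cells and re-bins grade-1 *predictions* to 0 or 2 by comparing
the continuous DG score with 1.0 — the midpoint of grades 0 and 2 and
the natural boundary of the rounding interval; no probabilistic
interpretation of the scores is assumed. The discrepancy report lists
false negatives (true > predicted) and false positives (predicted >
true) with |difference| ≥ 2, the cells an audit should examine first.

## The doctor-in-the-loop workflow

Model-label disagreements are queued (severest first, with raw ensemble
scores attached) for expert review; each verdict is either `ai_wrong`
(label upheld) or `human_wrong` (label revised). Revisions overwrite the
grade, bump the item's revision index and append to an immutable
history, so any earlier labelling state is reconstructible
(`revert_revisions()`); re-applying the same records is a no-op.
Verdicts are always human input — the loop's point is adjudication, not
automation — and the module deliberately imposes no stopping rule, only
an iteration counter.

## The synthetic smear generator

The generator emulates what the grading task needs and no more. A cell
is a soft-edged cytoplasm disc (granulocytes 15–19 px radius), a lobed
purple nucleus (3–5 lobes normally; a single round nucleus encodes the
hyposegmentation/immature-cell confounder), and Poisson-scattered pink
granule dots whose expected count is `granule_density × cytoplasm
area`. The DG grade maps to density piecewise linearly: grade 0 at the
base density (0.2 granules/px²), grade 3 at 2% of it, grades 1–2 evenly
spaced, all jittered ±10% within grade so grades are distributions on a
continuum rather than constants. The background is pale grey with
low-frequency mottle (so a detector cannot threshold at white), rasters
are quantized to the 8-bit RGB grid PNG stores (so datasets round-trip
disk bit-exactly), and one master seed is split hierarchically into
per-cell seeds. Field images place whole crop rectangles at
non-overlapping positions and fail loudly if placement is impossible —
never silently dropping cells — so re-cropping a ground-truth box
reproduces the stand-alone crop pixel for pixel. A population
specification plants exact per-label grade counts (the default emulates
a realistic cohort's imbalance, e.g. 46/77/11 DG cells among 1797 with a
large immature-granulocyte pool).

What the generator does *not* emulate — true stain variability,
focus/illumination gradients, touching and overlapping cells,
megakaryocyte ploidy morphology, the full visual diversity of the 34
label classes — bounds what green tests mean: they certify the
pipeline's mechanics and its ability to recover a planted ordinal
signal under the stated augmentations, not clinical performance. The
granulocyte radius range is kept deliberately narrow so that the
planted density signal is decodable from a single cell; with a much
wider size distribution the granule *count* alone could not separate
adjacent grades, on synthetic or real cells alike.

## The baseline detector

The detector contract (field → tagged boxes) is filled by a classical
baseline: estimate the background colour as the per-channel median,
threshold the colour distance by Otsu (saturated at 0.2 so the threshold
falls between background and cell matter rather than between pale
cytoplasm and dark nuclei, and floored at 0.12 because Otsu assumes a
bimodal histogram and would otherwise split the background noise of an
empty field), close morphologically, label connected components, filter
by area, and tag a box *applicable* when ≥ 5% of its pixels are
nucleus-dark (luminance < 0.55). Enucleate red-cell blobs and debris
fail the nucleus test and are excluded from cropping. Matching in tests
uses the standard IoU ≥ 0.5 criterion.

## Known limitations

* The tiny profile's summary statistics are tuned to the generator's
  stain palette; real smears need the transfer profile with a genuine
  pretrained extractor.
* Scores near a rounding boundary make the integer grade sensitive to
  small score shifts; the continuous score should accompany any
  clinical-style report.
* The max-over-rotations ensemble is upward-biased by construction: a
  single high-scoring orientation sets the grade. This is intentional
  (sensitivity first) but inflates false positives near grade
  boundaries.
* Iterative stratification is greedy; its optimality is verified
  exhaustively only on small instances, and with heavily overlapping
  labels the per-label balance guarantee weakens.
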