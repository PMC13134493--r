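---
title: "Methods: crystal scoring with low-rank adapted vision transformers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crystal scoring with low-rank adapted vision transformers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropvision)
```

## The problem

High-throughput crystallization screens image every drop of every plate many
times over weeks. The outcome of interest — a protein crystal — is rare
(typically under 5% of drops), morphologically diverse, and easily confused
with amorphous precipitate, phase separation, or salt crystals. Manual
scoring is slow and notoriously inconsistent between experts. `dropvision`
implements a complete, desk-scale pipeline for the machine-scoring workflow
used in modern crystallization facilities: binary crystal/other
classification of drop micrographs by a vision transformer fine-tuned with
low-rank adapters, independent models for visible-light and UV-fluorescence
images with late fusion of their scores, imbalance-aware evaluation, and a
human-in-the-loop curation cycle that turns scoring disagreements into
versioned training sets.

## The classifier and its adapters

The backbone is a standard pre-norm vision transformer: patch embedding,
learned class token and position embeddings, `L` encoder blocks (multi-head
self-attention and a two-layer GELU MLP, each behind LayerNorm with a
residual connection), and a linear two-class head. Two geometries are
configured:

* `"base-accounting"` — the ViT-B/14 layout (518×518 input, 12 blocks,
  hidden 768, 12 heads, MLP 3072, 3 channels). Its only purpose is
  parameter arithmetic: `param_count()` over its arrays totals 86.6 million,
  and rank-25 adapters on all per-block dense layers count 4 147 200
  trainable entries — the "4 million instead of 86.6 million" economy that
  motivates adapter fine-tuning. It is never trained here.
* `"tiny-desk"` — 64×64 input, 4 blocks, hidden 64, 4 heads, MLP 256,
  grayscale. Small enough that a full fine-tuning runs in about a minute on
  one CPU core; all experiments in this package use it.

Low-rank adaptation freezes every base weight and attaches a pair of
factors `(A, B)` to each dense layer: the layer computes
`x W + b + s (x A') B'` with `A` of shape `r × fan_in`, `B` of shape
`fan_out × r`, and scaling `s`. Defaults are rank `r = 25` and `alpha = 20`;
because the wording "scaling factor" is ambiguous between the two
conventions in circulation, both are implemented: `s = alpha / r` (0.8, the
default) and `s = alpha` directly, and the choice is recorded in every
checkpoint. `B` starts at zero, so an adapted model is *exactly* the base
model until training moves it — asserted bit-for-bit in the tests. Adapters
live in ordered stages: a second injection freezes the first stage, which is
how successive fine-tunings are kept separate; `lora_merge()` folds all
stages into the host weights (`W + s A'B'`) when a permanent model is
wanted.

Because "all dense layers" is ambiguous at the margins, targeting is
explicit: the default adapts the per-block q/k/v (separate or fused — both
layouts are supported), attention-output and MLP layers, leaves the patch
embedding and head un-adapted, and trains the fresh two-class head fully.
Patch-embedding and head adapters are config switches, and
`count_trainable()` reports any variant so the accounting can be compared
across conventions: separate q/k/v give 4 147 200 adapter entries, fused
q/k/v 3 686 400 — either rounds to the same 4 million.

Two defaults here deviate deliberately from the most common choices, for a
reason specific to this package: the tiny-desk backbone is *randomly
initialized*, not pretrained, because shipping or downloading foundation
weights is out of scope. Fine-tuning conventions tuned for pretrained hosts
transfer poorly to that regime:

* **Head pooling** defaults to the mean of the patch tokens rather than the
  class token (`pool = "cls"` restores the classical contract). With a
  random backbone the class token only sees the image through untrained
  attention, which starves the head of gradient signal in short runs; mean
  pooling gives every patch a direct path.
* **A-factor initialization** defaults to a zero-mean Gaussian with standard
  deviation `1/sqrt(fan_in)` (`a_init = "gaussian"` restores the fixed
  0.02). The gradient of `B` is proportional to `x A'`; with a tiny `A` the
  adapters barely move in a 3-epoch budget. Identity at initialization is
  untouched either way, since it rests on `B = 0`.

## The training recipe

`fit()` implements the fine-tuning recipe: weighted cross-entropy with
inverse-frequency class weights normalized to mean one
(`w_c = N / (2 n_c)`), a learning rate that decays linearly to zero over
the run, seeded per-epoch shuffling, and flip-only augmentation —
horizontal and vertical flips with probability 0.5 each, and nothing else,
because crops can cut crystals out of frame and shape transformations
distort the straight edges that identify them. The optimizer is Adam
(the original training framework does not disclose its optimizer, so it is
config together with weight decay, gradient clipping and warmup, all off by
default). `train_config()` carries the two canonical regimes as presets:
`"foundation"` (batch 32, 2 epochs) and `"finetune"` (batch 16, 1 epoch),
both starting at learning rate 0.0005. Only trainable arrays are updated;
after any number of steps the frozen base weights are bit-identical to
their initial values, which the suite asserts.

Visible and UV models are always trained independently, one per modality,
so that facilities without UV imaging can run the visible model alone.

## Score fusion

Each experiment gets one crystal probability per modality; `fuse_scores()`
consolidates them by the arithmetic mean, the product, or the maximum
("argmax" — the score of whichever model is more confident about a
crystal). The maximum is the default because recall under it dominates
either single modality at every threshold — an exact property of the max
rule that the tests assert on generated tables, alongside symmetry and the
ordering `product ≤ mean ≤ max`. When one modality is missing the present
score is used unchanged and the result is flagged `single_modality`.

## Evaluation under extreme imbalance

With ~95% of drops in the "other" class, a constant "no crystal" predictor
scores ~95% accuracy while detecting nothing. The metrics of record are
therefore crystal recall and balanced accuracy (the mean of the two
per-class recalls); precision, accuracy and F1 are reported alongside, and
per-crystal-type recall (microcrystals, needles/clusters, single crystals)
diagnoses where a model fails. Degenerate ratios are reported as undefined
(`NA`), never as zero, except the F1 convention: zero when `TP = 0` but
errors exist, undefined only for the empty case.

## The synthetic-data generator

`generate_plate()` renders paired visible/UV drop images with a ground-truth
manifest. It emulates the six phenotypes of the user scoring vocabulary:
clear drops; amorphous precipitate (band-limited blob fields); phase
separation (circular droplets with smooth, defocused rims — liquid
interfaces, deliberately unlike crystal facets); microcrystals (fields of
1–2 px diamonds); needle clusters (thin rotated rectangles radiating from
cluster centres); and single crystals (random convex polygons). Visible
renderings include the drop boundary, interior vignetting and additive
Gaussian noise; UV renderings show fluorescence only from fluorescent
objects, with amorphous precipitate fluorescing at a configurable nuisance
intensity (default 0.5× a crystal) to reproduce the classic UV
false-positive mode.

Two modality-complementarity scenarios are generated on demand, because
they are the reason fusion helps:

* **UV-only detectable** — fluorescent crystals buried under a drop-wide
  precipitate veil (`occlusion_level` ≈ 0.9): visible contrast falls below
  the generator's stated detectability floor (foreground-background
  difference 0.08 on the unit intensity scale) while the UV
  signal-to-background ratio exceeds its stated ceiling (5).
* **Visible-only detectable** — salt-like, non-fluorescent crystals that
  image clearly under visible light and vanish under UV.

A stated fraction of crystal scenes is assigned to each scenario,
round-robin across crystal types so the assignment is deterministic:
manifests are identical across seeds while pixel content varies. Everything
is seeded; the same scene specification renders byte-identically, and both
modalities of a scene share one geometry.

What the generator does *not* emulate: real optics (focus gradients,
plate-rim reflections, illumination inhomogeneity beyond a radial
vignette), colour imaging, skin effects at drop edges, or the full
morphological continuum between microcrystalline and amorphous material.
Passing the desk experiment therefore demonstrates that the pipeline's
machinery — adapters, recipe, fusion, evaluation, loop — works end to end
on data with the right *structure*, not that the tiny model would score
real micrographs at any particular level.

## The desk experiment

The performance bar the suite enforces mirrors the multi-step transfer
process at a scale a CPU handles in minutes. Conditions: 400 paired
training experiments (800 images; crystal:other 1:3; 20% of crystal scenes
UV-only and 20% visible-only detectable) and 100 held-out pairs from the
same generator. Training proceeds in two stacked stages — a
foundation-style fit over all 800 images (2 epochs, `modality = "all"`)
followed by one per-modality fine-tuning epoch on fresh adapters with the
earlier stage frozen — 3 epochs in total per model. Desk-specific
optimization settings (learning rate 0.002 with 10% warmup, batch 2, tail
weight averaging over the final quarter of steps) compensate for the random
initialization; they are configuration, not part of the recipe presets. The
bar: fused crystal recall ≥ 0.95 and balanced accuracy ≥ 0.90 on the
held-out pairs in at least 4 of 5 seeded replicates, with argmax fusion
strictly beating the visible-only model on the UV-only-detectable subset.
The UV model's recall ceiling under these conditions is 0.80 (it cannot see
the visible-only crystals), the visible model's is also 0.80; only fusion
can reach 1.0, which is the point of the experiment.

## The curation loop

`detect_discrepancies()` compares model calls (`fused_p ≥ τ`, with τ = 0.5
shared by training, fusion and the loop — the threshold is deliberately one
constant everywhere) against user scores mapped to binary (the two
crystalline user scores → crystal, the other five → other). Disagreements
queue for curators, who apply one of four labels: `crystal`, `other`,
`uncertain`, `unusable`. Unanimous crystal/other verdicts resolve the item;
anything else excludes it from training but keeps it quarantined, because
images on which experts cannot agree are stored, never deleted (a majority
rule is available as config). `assemble_version()` builds the next training
set from the agreements plus the resolved items, excludes any experiment
present in the held-out manifest (recording the count — nothing is
silently dropped), and emits an accounting report in which every scored
experiment lands in exactly one bucket; the reconciliation
(`agreements + discrepancies = scored`;
`resolved buckets + unresolved = discrepancies`) is asserted on every run.
The report distinguishes four resolved outcomes: model false crystals,
crystals the user missed (model right), crystals the model missed (user
right), and user false crystals — the last bucket is needed for exact
conservation even though published summaries typically fold it away.

For the plate-map display, `colour_scale()` maps probabilities to display
intensity with low visibility below 40% — linear from 0 to 0.1 on
[0, 0.4], then `0.1 + 0.9 ((p − 0.4)/0.6)^0.7`. The published interface
describes only the qualitative shape; this concrete curve satisfies the
stated constraints (monotone, anchored at 0 and 1, ≤ 0.1 below 40%) and is
otherwise a free choice.

## Numerical and reproducibility choices

* Grayscale conversion uses fixed luma weights 0.299/0.587/0.114; resizing
  is bilinear with antialiasing on downscale (recorded in the config).
* Normalization constants default to the training-set global mean and
  standard deviation, are stored on the trained model, and travel with its
  checkpoint.
* All randomness — initialization, adapter seeds, shuffling, augmentation,
  scene geometry — is seeded; `fit()` is byte-deterministic under a fixed
  seed, and pipeline runs with identical configs produce identical metrics.
* Checkpoints serialize the full model next to a JSON header (geometry,
  stage configurations, scaling convention, seeds, preprocessing); the
  round-trip is bit-exact.
* Ties: equal fused probabilities under argmax record `winning_modality =
  "both"`; several dual-modality inspections of a plate resolve to the
  earliest inspection id; plates without any dual inspection fall back to a
  seeded random choice.
* Degenerate inputs: empty manifests flow through every operation as empty
  results; a single-class training manifest is an error (inverse-frequency
  weights would be undefined); probability 0 at the true label is clamped
  at 1e-12 inside the loss.

## Known limitations

The tiny-desk model is a vehicle for testing the machinery, not a
production classifier; no pretrained weights ship with the package (a
checkpoint loader is provided for models trained elsewhere). The generator's
morphology is schematic, and desk-scale results do not transfer to real
micrographs without local fine-tuning — which is precisely the workflow the
curation loop exists to support. Published benchmark figures obtained with
released model weights on facility datasets are out of this package's
scope and are not asserted anywhere in its tests.
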