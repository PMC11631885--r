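---
title: "Methods: quantifying and detecting narrowed intervertebral disc spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and detecting narrowed intervertebral disc spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivdquant)
```

## The problem

Intervertebral disc disease (IVDD) is the most common spinal disorder of
dogs, and narrowing of an intervertebral disc space (IVDS) on a lateral
radiograph is its most common radiographic sign. A disc space is only a few
pixels wide, and whether it is "narrow" is inherently relative: the same
absolute width can be normal in a Pekingese and narrowed in a German
Shepherd, and even within one image the diagnostic cue is a space that is
small *compared with its neighbours*. `ivdquant` implements a screening
pipeline that starts from a vertebral-body segmentation mask (produced by any
upstream segmentation method — this package does not segment), measures every
disc space in pixels, and labels narrowed sites.

## The quantification algorithm

1. **Resize** the label mask to 1024 rows x 512 columns with
   nearest-neighbour sampling. Nearest-neighbour is forced by the data type:
   labels are categorical and interpolation would invent new ones. The spine
   axis is the row axis, so one image row corresponds to one element of the
   final profile.
2. **Skeletonize** each vertebral body (label 1). 8-connected components
   smaller than `min_area_px` (default 50 px) are discarded as segmentation
   specks; survivors are thinned with the Zhang-Suen algorithm. The skeleton
   is a shape-independent proxy for the body's centre: for the wide, squat
   quadrilateral of a lateral-view vertebral body it is a short medial
   stroke through the centroid.
3. **Fit the centerline** `x(y) = c0 + c1 y + ... + c4 y^4` (column as a
   function of row) by least squares through the pooled skeleton points.
   Internally the fit uses the scaled ordinate `y/1023` and a QR
   decomposition — a raw 4th-power Vandermonde in row units is numerically
   hostile — and reports coefficients on the raw scale. At least five
   distinct skeleton rows are required; fewer is a degenerate-fit error.
4. **Sample the profile**: for each row `y`, the profile is 1 iff the mask
   at `(y, round(x(y)))` is vertebral body. Rounding is half away from
   zero; samples outside the 512-column frame read as background.
   Annotation labels 2/3 (normal/narrowed disc space, used only to build
   training targets) read as background here.
5. **Measure gaps**: a disc space is a maximal zero-run flanked on both
   sides by one-runs of at least `min_run_px` (default 5) — shorter
   one-runs are label noise, not vertebral bodies — and its width is the
   zero-run's pixel count. Leading and trailing zero-runs are background.
   Each gap also carries `width / mean(widths of this image)`, the
   scale-free narrowing score used for ROC analysis and thresholding.

Two interpretation choices deserve a note because the choice was genuinely
open. Width is a **row count**, not an arc length along the curve: the
profile has exactly one element per row, and "counting the pixels" between
bodies is a count of vector positions. For gently curved spines the two
differ by well under a pixel. And the profile is indexed by **row**, not by
arc length, which is what makes vector index = image row and lets training
targets be painted directly onto mask rows.

## The sequence labeller

A disc space is judged relative to its neighbours, so the classifier needs
to see several vertebrae at once. The model is a 1D convolutional network
over the length-1024 binary profile with a deliberately large receptive
field: a stem convolution (kernel 151) lifting the single input channel to
64 feature channels, five residual blocks (convolution kernel 151, 64
channels, stride 1 -> batch normalization -> ReLU, identity added), and a
width-1 convolution to 3 logits with a per-position softmax. Zero padding
of 75 per side preserves length, so each of the 1024 positions receives a
probability triple over {no disc space, normal, narrowed}. The receptive
field is `1 + 6 x 150 = 901` positions — most of the image — and the test
suite verifies it exactly by perturbation: flipping an input more than 450
positions away from an output leaves that output bit-identical.

The published architecture names the ingredients (kernel 151, 64 channels,
stride 1, five intermediate layers, batch normalization, residual
connections) but not their order. We use conv -> BN -> ReLU with the
identity added after the activation, and a channel-lifting stem so the
residual sum is well-typed. These are the standard arrangement; nothing
downstream depends on the variant.

### Loss

Training minimizes a combined cross-entropy + focal loss. Per position,
with one-hot truth `y` and predicted probabilities `p`,

    L_c        = -y_c log p_c
    L_combined = sum_c [ alpha_c (1 - p_c)^gamma L_c + L_c ]

with `alpha_c = 0.25` for every class and `gamma = 2`. Background rows
dominate the profile (roughly 85% of positions) and narrowed rows are a few
percent, so the focal factor's down-weighting of easy, confidently
classified positions is what keeps the narrowed class from being ignored.
Probabilities are clipped to `[1e-7, 1 - 1e-7]` before logarithms. The
batch loss is the mean over positions and items. `combined_loss()` is the
reference R implementation of the formula; the C++ training path is tested
against it.

### Training

Adam with an 80:20 train/validation split by image, per-epoch shuffling,
best-validation-loss checkpointing and early stopping (patience 10). The
defaults in `train_config()` keep the reference regime (learning rate 1e-5,
50 epochs, batch 16). That learning rate belongs to a GPU-scale setting
with hundreds of images and long training; it moves weights by ~1e-5 per
Adam step, so in the few hundred steps a single-CPU validation run can
afford, a freshly initialized network would barely change. The phantom
recovery experiment in the acceptance suite therefore passes its own
schedule — learning rate 3e-3, batch 4, 10 epochs — chosen
up front from step-count arithmetic against the CPU budget, not tuned
against the acceptance bands. The dataset configuration and the
sensitivity/specificity bands of that experiment are fixed.

The network is implemented in the package itself (RcppArmadillo, float32,
convolutions evaluated as shifted GEMMs so BLAS carries the arithmetic):
the environment provides no R deep-learning framework, and the model *is*
the method, not infrastructure.

### From positions to decisions

`detect_narrowed()` converts per-position labels to per-gap decisions:
majority vote among a gap's rows restricted to normal/narrowed votes
(background votes are ignored — the network occasionally hedges at gap
borders), an exact tie counts as narrowed because the tool is a screening
aid where a false positive costs a clinician a second look and a false
negative costs a missed lesion, and a gap with no disc-space votes at all
is `unassigned` (treated as not-narrowed by the agreement statistics).

## The synthetic phantom

No clinical images ship with the package, so validation rests on a phantom
generator with exact ground truth. `generate_spine_mask()` renders 6-16
vertebral bodies as rectangles-along-the-curve on the 1024 x 512 canvas: at
each row of a body, columns within half the body height of the centerline
are foreground, optionally with +/- `jitter_px` of independent edge noise.
Narrowing is multiplicative: a gap drawn as `w` becomes
`round(w * factor)` with `factor` in 0.3-0.7 by default — the relative
concept that matches the ratio-to-mean score. Defaults emulate the
published cohort where one is stated and a field-plausible value where not:
normal gaps 8-18 px after resize (printed per-dog quantified widths span
roughly 2-20 px), narrowed prevalence 0.25 (the clinical validation pool
carried 65/294 = 22% narrowed sites), bodies 60-90 rows long. Specks are
1-9 px blobs that exercise the component-area filter; they are placed with
a one-pixel halo so they never merge with a body.

What the phantom deliberately does *not* model: radiographic intensity,
end-plate curvature and sclerosis, superimposed ribs, rotation or
foreshortening, and segmentation errors larger than a speck. A green
phantom test therefore establishes that the geometry and the learning
machinery are correct — exact width recovery on noiseless phantoms, +/-1 px
on curved ones, recoverable narrowing labels — and not that clinical
performance (kappa 0.780 against clinicians) transfers to any particular
scanner or breed mix.

`generate_vector_dataset()` bypasses rendering and emits (profile, labels)
pairs directly; it is the training input, and it is exact by construction,
which is what lets the round-trip tests pin rendering + quantification
against it.

## Agreement statistics

- `cohen_kappa()` on a pooled 2x2 narrowed-vs-not table; pooling all gaps
  across validation images into a single table is the only reading
  consistent with a single printed Total row over 294 disc spaces.
- `confusion_metrics()`: sensitivity, specificity, PPV, NPV, accuracy in
  percent; a zero denominator flags that metric as undefined rather than
  failing the table. Printed comparisons round half away from zero
  (`round_half_up()`), matching clinical-table convention.
- `fleiss_kappa()` for three-rater agreement, standard formulation.
- `roc_youden()`: the ratio-to-mean score enters negated (smaller ratio =
  more narrowed); AUC by the rank/Mann-Whitney method with ties counted
  one half (verified against brute-force pair counting to 1e-12); the
  operating threshold maximizes Youden's J over observed cuts, ties
  resolving toward higher specificity; the AUC confidence interval is a
  seeded stratified percentile bootstrap (2000 resamples). The reference
  analysis names a 95% CI but not its construction; the bootstrap is this
  package's substitute, not a claim about the original computation.

## Numerical choices

- Half-away-from-zero rounding everywhere a printed figure is reproduced.
- Curve fit: QR on the `[0,1]`-scaled basis; coefficients are reported on
  raw row units, so `c4` is O(1e-11) for realistic curvature.
- Float32 network arithmetic with double accumulation of losses; BN epsilon
  1e-5, running-statistic momentum 0.1.
- Argmax ties break toward the lower class index (so an untrained network
  with a zeroed head answers "no disc space", the conservative default).
- Determinism: phantoms and statistics are bit-reproducible under a seed;
  training is bit-reproducible on one machine (same BLAS, single thread).

## Known limitations

- The phantom's realism gap (above) bounds what the acceptance experiment
  can claim; clinical re-validation would need real annotated masks.
- `fit_spine_curve` weights every skeleton point equally, so a long body
  contributes more points than a short one; with 6+ bodies this has no
  visible effect on the fit.
- The PNG codec reads only the subset it writes (8-bit indexed/greyscale,
  non-interlaced) — sufficient for masks, not a general image reader.
- Anatomical naming (T10-T11, L4-L5) is out of scope: gaps are ordinal
  within an image.
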