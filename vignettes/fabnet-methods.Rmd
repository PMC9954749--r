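---
title: "Feature-agglomeration networks for H&E patch classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-agglomeration networks for H&E patch classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabnet)
```

This vignette is the package's own account of its methods: the network
architecture and how its parameters are counted, the stain-normalization
model, the class-balanced patch budget, the patient-aware evaluation
protocol, what the synthetic H&E generator does and does not emulate, and
the numerical and design choices made where more than one reading was
defensible.

## The classification problem

Histopathology slides stained with hematoxylin and eosin (H&E) are
classified from RGB crops. Whole slides are too large for a CNN input, so
the standard pipeline crops fixed-size patches (224×224 here), classifies
each patch, and averages patch probabilities into an image-level decision.
Two levels of accuracy matter clinically: image-level (fraction of images
classified correctly) and patient-level (each patient's per-image accuracy,
averaged over patients, so a patient with many slides does not dominate).
Because multiple images come from the same patient, train/test partitions
are drawn over *patients*; splitting over images would leak patient-specific
texture into the test set.

## The network

The model is built from a repeated *conv block*. A block applies a 5×5 and
a 3×3 convolution to its input in parallel (stride 1, zero padding so the
spatial size is preserved, ReLU on each branch), concatenates the two
activation maps along the channel axis, and compresses the concatenation
with a 1×1 convolution to `reduce_width` channels, followed by batch
normalization and ReLU. The two kernel sizes give each block a fine and a
coarser receptive field at the same depth.

Blocks are fused in consecutive pairs: within pair *p* the first block
feeds the second, their outputs are concatenated and average-pooled (2×2,
stride 2), and the pooled map is both the input of pair *p*+1 and that
stage's *tap*. After the last pair, every tap is average-pooled down to the
final spatial grid (7×7 for a 224×224 input), all taps are concatenated
(the stage fusion), global-average pooled, and classified by a single dense
softmax layer. This is the "agglomeration" idea: shallow, high-resolution
features are re-injected at the classifier rather than surviving only
through the deep path.

The default network has ten blocks B1..B10 with parallel filter counts
(16, 32, 32, 64, 64, 128, 128, 256, 256, 512), i.e. each pair follows an
(f, 2f) progression, and five taps C1..C5. Three convolutions per block
give 30 convolution layers.

```{r}
spec <- default_fabnet_spec(head_classes = 2)
spec
```

### Design choices in the architecture

Several aspects of the published description admit more than one reading;
the package fixes them as follows and exposes each as a configuration knob
where sensible.

* **Filter counts of B5, B7, B9** are not individually specified; they are
  set to 64, 128, 256 so that every pair follows the same (f, 2f)
  progression that all the specified blocks follow.
* **1×1 reduction width**: the bottleneck "reduces the optimal channels"
  without a stated width. The default is `min(filters_parallel, 32)`. This
  keeps the binary model at 2,189,810 trainable parameters, inside the
  3,239 K reference budget, while leaving the stated parallel widths
  untouched. `default_fabnet_spec(reduce_cap = )` changes it.
* **Batch-norm placement**: one batch normalization after the 1×1
  convolution per block (not per parallel branch); ReLU after each parallel
  convolution and after the block's batch norm.
* **Stage bridges C1..C5** are parameter-free average-pool bridges from
  each pooled pair fusion down to the final grid. Learned 1×1 bridges would
  add parameters the budget does not account for; pooled bridges are the
  simplest structure consistent with the budget.
* **Feed direction** inside a pair is forward (B5→B6), consistent with
  B1→B2; the pooled output of the last pair is itself pooled once (to 7×7)
  before stage fusion.
* **Biases and initialization**: all convolutions carry biases; batch norm
  contributes a trainable scale and shift per channel. Weights use a
  uniform fan-in scheme, *U*(−√(6/fan_in), +√(6/fan_in)), with an explicit
  seed; two builds from the same spec and seed are bit-identical.

### Parameter accounting

`spec_parameter_count()` is a closed-form summation over the block table
(5×5 and 3×3 kernels and biases, the 1×1 kernel and bias, 2 batch-norm
scalars per reduced channel, plus the dense head), kept deliberately
independent of the built model; `count_trainable_parameters()` sums the
tensors actually allocated. The test suite requires the two to agree
exactly, which guards both the channel bookkeeping and the builder.

```{r}
count_conv_layers(spec)
spec_parameter_count(spec)
```

### The training engine

No deep-learning framework is used: the convolution and pooling kernels
(forward and backward) are compiled C++ (im2col + GEMM via
RcppArmadillo), and the layer graph, batch normalization, softmax
cross-entropy and the optimizers (Adam, SGD, RMSprop, Adamax, Nadam,
Adadelta) are implemented in R. The backward pass is verified against
central differences to ~1e-5 relative error. One numerical subtlety: at the
zero-bias initialization, pixels whose entire concatenated feature vector
is zero put the 1×1 pre-activation *exactly* on the ReLU kink, where a
two-sided numeric difference and any subgradient legitimately disagree; the
gradient test therefore perturbs parameters to a generic point first.

Training defaults follow the tuned protocol of the architecture's source:
100 epochs, learning rate 1e-3, batch size 16 (64 for class-folder-style
datasets), Adam, categorical cross-entropy, no data augmentation, no early
stopping. In our CPU-scale experiments, raising the learning rate to 3e-3
destabilized the batch-norm running statistics (training accuracy high,
inference accuracy at chance), so the 1e-3 default is also the practical
choice.

## Macenko stain normalization

In optical density, OD = −log10((I+1)/255), stain mixing is approximately
linear (Beer–Lambert): each pixel's OD 3-vector is a nonnegative
combination of a hematoxylin and an eosin unit vector. The estimator:

1. Keep pixels whose OD vector *magnitude* exceeds 0.15 (tissue);
2. take the two leading eigenvectors of the tissue OD covariance (the
   stain plane);
3. compute each pixel's angle in that plane and take the 1st/99th
   percentile extreme directions;
4. map the extremes back to OD space, clip tiny negatives, normalize, and
   order the columns so the vector with larger blue OD is hematoxylin.

Normalization then rescales each stain's concentration field so its 99th
percentile maps to the reference maximum (default (1.9, 1.0)) and
re-renders the image through a fixed reference basis, hematoxylin
(0.65, 0.70, 0.29) and eosin (0.07, 0.99, 0.11) normalized — the widely
used default pair. All thresholds (0.15 OD, 1 % angle percentile, 99 %
concentration percentile) are the canonical defaults for this estimator
and are exposed as arguments.

Numerical choices worth noting:

* **Tissue masking by OD magnitude**, not per-channel thresholding: an
  almost-pure eosin field has a red OD component near 0.07·c, which a
  per-channel rule would discard wholesale, turning a rank-deficient image
  into a spurious "no tissue" case instead of the correct degenerate-stain
  diagnosis.
* **Rank test**: the second eigenvalue must exceed 1e-5 (absolute) *and*
  1e-3 of the first. The absolute floor sits two orders of magnitude above
  the variance that 8-bit quantization noise induces in OD (~4e-7, measured
  on single-stain renders), so quantization cannot masquerade as a second
  stain.
* **Exact reconstruction**: images are re-rendered with the exact inverse
  of the OD transform (including its +1 guard). Reconstructing with the
  guard omitted brightens every dark pixel by one level per pass and ruins
  idempotence.
* **Idempotence at 8 bits**: after the exact-inverse fix, re-normalizing a
  normalized image moves at least 99.9 % of pixel-channels by ≤2 intensity
  levels. A handful of near-black pixels (overlapping nuclei whose rendered
  intensity clips to ~0) can move by 3–4 levels because their
  concentrations are unrecoverable from an 8-bit pixel; the tests assert
  the ±2 band at the 99.9th percentile with a hard cap of 5.

## Class-balanced patch budgeting

With class image counts *x₁..xₙ* and a constant β (default 32), class *i*
receives

  *Nᵢ = ⌈ mean(x) / xᵢ · β ⌉*

patches per image, so the per-class totals *Nᵢ·xᵢ* all land within one
ceiling step of the common target β·mean(x): abundant classes contribute
few patches per image and rare classes many. On the reference breast-cohort
census at 40× this gives, e.g., 10 patches per ductal-carcinoma image and
74 per tubular-adenoma image. The formula's divisor glyph is read as a
fraction bar — the only reading that balances classes, which is the rule's
stated purpose. Patches are placed at seeded uniformly random in-bounds
offsets (0-based, half-open windows); a fixed-stride grid is not used
because the source protocol describes arbitrary window placement. Whether
the original budget was drawn per image (as here) or pooled per class is
not decidable from its description; per-image placement preserves the
provenance multiset, which the tests check.

## Cohorts, splits and metrics

Two directory layouts are ingested: a breast-style tree
(`category/subclass/patient/magnification/image.png`) and a class-folder
tree (`class/image.png`). The native filename encoding of the public breast
dataset is deliberately not parsed — the documented layout plus a CSV
manifest is the ingestion contract, and users holding the real download can
produce the layout with a single rename pass. Class-folder datasets carry
no patient structure, so each image becomes its own pseudo-patient, making
image-level and patient-level metrics coincide there by construction.

The patient split shuffles patients under a seed and cuts at
`round_half_up(ratio · n)` (default 0.70); cross-validation deals patients
round-robin into k folds (default 5), sizes differing by at most one.
Patient leakage is impossible by construction and is additionally audited:
`fabnet(..., split = plan)` refuses to see test-side patients, and the
pipeline's evaluation records are checked against the plan.

The published definitions of the patient score and image-level accuracy are
printed with the ratio inverted (they would exceed 1); both are implemented
in the conventional orientation, correct/total, which is the only
orientation under which averaging patient scores is meaningful. Argmax ties
break to the lowest class index. Multiclass precision/recall/F1 are
computed one-vs-rest per class and macro-averaged (the averaging convention
is not specified in the source; macro is stated explicitly here). ROC
curves sweep thresholds over the unique scores and the AUC uses the
trapezoidal rule; the tests pin it to the Mann–Whitney rank identity.

## The synthetic H&E generator

Every stochastic component is seeded, and images render through the
Beer–Lambert law with a known stain matrix, so ground truth is exact: a
Poisson number of elliptical nuclei (expected `nucleus_density` per
100×100 px) carries hematoxylin; the background carries eosin at a constant
level (default 0.4 OD, high enough that background pixels clear the 0.15
tissue threshold); nuclei displace cytoplasm, so nucleus pixels are
eosin-free. Mild per-pixel concentration jitter (±10 %) keeps the OD cloud
two-dimensional without bending the pure-stain directions, which is what
makes stain-vector recovery testable to within 2°. Magnification is
emulated purely as a nucleus scale factor (0.5× at "40X" up to 2× at
"400X").

What the generator does *not* emulate: chromatin texture, stromal
structure, color variation between scanners beyond the stain matrix,
tissue folds, blur, or any tumor morphology. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline's mechanics (budgeting,
leakage prevention, optimization, aggregation, metrics) are correct and
that the network can learn a genuinely class-correlated signal (nuclear
density) — they say nothing about accuracy on real histopathology.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own desk-scale study conditions: the end-to-end
run uses two classes with nucleus densities 6 vs 50 per 100×100 px (a
contrast a count-threshold classifier already separates at >90 %, so the
training target is achievable by construction), 6 patients per class × 3
images each at 64×64 px, β = 32 with 32×32 patches, a 70:30 patient split,
and a reduced single-pair network (base 8 filters) trained 10 epochs with
Adam at 1e-3, batch 16. Unit tests use smaller variants (8–16 px inputs,
2–4 filters) for gradient checks and invariants. The full 10-block model is
built and parameter-counted at 224×224 but trained only in reduced form.

## Known limitations

* The training engine is single-threaded CPU code built for correctness
  and desk-scale experiments, not for training the full model on real
  datasets.
* Sparse-NMF-based ("structure-preserving") color normalization is not
  implemented; the Macenko estimator is applied to both dataset styles.
* Batch-norm inference uses running statistics with momentum 0.1; very
  high learning rates can leave them stale relative to the weights.
* 8-bit image depth bounds every color-space guarantee (see the
  idempotence discussion above).
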