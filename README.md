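# fabnet

Patch-based classification of H&E histopathology images with a
feature-agglomeration convolutional network, implemented end to end in R.

Automated grading of hematoxylin-and-eosin (H&E) slides — benign vs
malignant breast tissue, or the nine colorectal tissue types — is usually
done by cropping fixed-size patches from each image, classifying the
patches with a CNN, and averaging patch probabilities into image- and
patient-level decisions. This package implements that whole pipeline for
researchers who want a transparent, fully seeded, dependency-light
reference implementation they can run and test on a laptop:

* **The network.** A multi-branch "feature agglomeration" architecture:
  each block runs a 5×5 and a 3×3 convolution in parallel, concatenates
  them, and compresses with a 1×1 bottleneck (+ batch norm, ReLU). Blocks
  are fused in pairs with 2×2 average pooling, and every pooled stage is
  bridged forward and re-concatenated before a global-average-pooled
  softmax head, so shallow detail reaches the classifier directly. The
  default 10-block network has 30 convolution layers and 2,189,810
  trainable parameters (under the 3,239 K reference budget). Forward and
  backward passes are compiled C++ (im2col + GEMM); no deep-learning
  framework is required.
* **Macenko stain normalization.** Estimates each image's two-stain basis
  in optical-density space (PCA plane + robust angular extremes) and maps
  it onto a reference basis, removing scanner/lab color variation.
* **Class-balanced patch budgeting.** Class *i* with *xᵢ* images receives
  *Nᵢ = ⌈ mean(x)/xᵢ · β ⌉* patches per image (β = 32), so per-class patch
  totals are near-equal regardless of class imbalance.
* **Patient-aware evaluation.** Patient-level 70:30 splits and 5-fold CV
  that make leakage impossible by construction; accuracy at patch, image
  (correct/total) and patient level (mean per-patient score), one-vs-rest
  precision/recall/F1, confusion matrices, ROC/AUC.
* **A synthetic H&E generator.** Seeded Beer–Lambert rendering of
  elliptical nuclei (hematoxylin) over cytoplasm (eosin) with known stain
  matrices and concentration fields, so every stage — including training —
  is testable without downloading any dataset.

## Worked example

Inspect the full architecture, then run the complete pipeline (synthetic
cohort → budgeted patches → patient split → training → evaluation) at
desk scale:

```r
library(fabnet)

spec <- default_fabnet_spec(head_classes = 2)
spec
#> Feature-agglomeration network spec
#>   blocks:          10 (5 fused pairs)
#>   parallel filters: 16 32 32 64 64 128 128 256 256 512
#>   1x1 widths:       16 32 32 32 32 32 32 32 32 32
#>   input:            224x224x3
#>   head classes:     2
#>   conv layers:     30 | trainable params: 2,189,810

res <- run_pipeline(list(
  out = "demo_run", seed = 29,
  synth = list(patients_per_class = 6, images_per_patient = 3,
               image_size = 64),
  patch = list(beta = 32, size = 32),
  train = list(epochs = 10, batch_size = 16),
  stages = c("synth", "patch", "split", "train", "evaluate")))

res$fit
#> Fitted feature-agglomeration network
#>   classes: benign_like, malignant_like
#>   trainable parameters: 5,682
#>   10 epochs on 768 patches; final loss 0.1812, accuracy 0.938

str(res$metrics[c("patch_accuracy", "image_accuracy", "patient_accuracy")])
#> List of 3
#>  $ patch_accuracy  : num 0.924
#>  $ image_accuracy  : num 1
#>  $ patient_accuracy: num 1
```

The run trains a reduced single-pair network on 768 seeded 32×32 patches
from a two-class synthetic cohort (sparse vs dense nuclei), evaluates only
on held-out patients, and reaches 92 % patch accuracy and 100 % image- and
patient-level accuracy; `demo_run/` contains the cohort, patch manifest,
split, training history, per-patch predictions, metrics JSON and a run
record listing every artifact. Identical configs and seeds reproduce every
file bit for bit. `fabnet()` is the underlying fitting function (classed
object with `print`, `summary`, `coef`, `predict`, `plot` methods), and a
command-line wrapper with subcommands `synth`, `normalize`, `patch`,
`split`, `folds`, `train`, `evaluate`, `run` lives at
`inst/cli/fabnet.R`.

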