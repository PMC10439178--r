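---
title: "Auditing skin tone representation in educational documents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing skin tone representation in educational documents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinaudit)
```

## The problem

Dermatology textbooks and other medical teaching materials are known to
underrepresent dark skin tones (Fitzpatrick phototypes V and VI) in their
clinical imagery, which plausibly contributes to diagnostic disparities.
Counting skin images by tone has historically been done by hand, chapter by
chapter. `skinaudit` automates that audit: given a PDF (or a directory of
page images), it extracts every embedded figure, decides which figures show
human skin, isolates the skin pixels, classifies each skin image as
Fitzpatrick I--IV (light) versus V--VI (dark), and reports the per-document
balance, with every counted image traceable to its page and bounding box.

The pipeline has four analytic stages, each exposed as ordinary functions
so any stage can be run, evaluated or replaced in isolation.

## Stage 1: figure extraction

`extract_images()` parses the document and returns each embedded raster
image with 1-based page number and a bounding box in page points. Two
conventions are fixed here because PDF itself does not dictate them: the
bounding-box origin is the *top-left* of the page (matching how viewers
display coordinates), and duplicated embeds are kept as distinct records,
because each placement is a separate educational occurrence. Only embedded
raster images are extracted; vector drawings are out of scope for a
skin-image audit. Figures smaller than `min_dim` (default 100 px) in either
dimension are dropped as decorative.

The PDF reader and the paired writer used by the synthetic generator are
deliberately minimal: they handle 8-bit RGB/greyscale image objects stored
raw, Flate (zlib) or JPEG-compressed, which covers the documents the
package itself emits and straightforward image-bearing PDFs. Encrypted
files are rejected with an error naming the file; an exotic image encoding
skips that image with a warning rather than aborting an audit.

## Stage 2: is this a skin image?

Each figure is summarized by a 38-dimensional descriptor:

* a **global histogram of gradient orientations** (32 bins). Gradients are
  central differences of the scalar intensity, orientation is the
  two-quadrant arctangent `atan(Gy / Gx)` on (-pi/2, pi/2], and each
  interior pixel contributes its gradient magnitude to the nearest bin
  center. The histogram is L1-normalized so it measures *texture
  composition*, not image size or contrast.
* **CIELAB channel statistics**: mean and population standard deviation of
  L*, a*, b* (D65 white point, 2-degree observer) — six values capturing
  the global color signature that separates clinical photographs from
  charts, text and stained histology.

Three conventions deserve a note, since reasonable alternatives exist. The
intensity channel for gradients is BT.601 luma (0.299 R + 0.587 G +
0.114 B): unlike CIELAB L*, a constant shift of all channels shifts luma
by the same constant, so the descriptor is exactly invariant to additive
photometric offsets — a property the test suite asserts. Orientations are
*unsigned* (two-quadrant), matching the arctangent ratio formula; a bin
boundary tie goes to the lower-index bin. Standard deviations divide by N,
not N - 1, so a constant image has exactly zero spread regardless of size.

The classifier is either gradient-boosted trees (default), with depth,
rounds and learning rate picked by an internal 3-fold cross-validated
AUROC over a small grid, or a nu-SVM with an RBF kernel (nu = 0.01,
gamma = 0.05). SVM decision values are mapped to probabilities by a
logistic fit on the training scores, which keeps the fit deterministic.
`crossval_evaluate()` reports stratified k-fold AUROC and F1 with skin as
the positive class; stratification keeps each fold's class ratio within one
sample of the global ratio.

## Stage 3: which pixels are skin?

Segmentation is rule-based, not learned. A pixel is a skin *candidate* iff
it satisfies published color loci in both HSV and YCbCr
(`skin_rule_ranges()`): hue in [-20, 50] degrees, saturation in
[0.15, 0.70], value >= 0.25, Cb in [77, 127], Cr in [133, 173]. Hue is
treated circularly — the locus is really the arc from 340 degrees through
red to 50 degrees — because skin chroma sits near the hue origin and noisy
dark-skin pixels routinely cross it. Every interval is a configuration key.

`refine_mask()` then applies, in a fixed order: morphological opening
(disk radius 1) and closing (radius 3); removal of components below
`min_area` (default 0.5% of the image); region growing that re-admits
neighbors within Delta-E (CIE76) 12 of the surviving region's mean CIELAB
color; and a watershed split of the distance map so merged regions are
culled individually. The default opening radius is intentionally small:
rule candidates are speckled wherever per-pixel noise crosses a rule
boundary, and an aggressive opening can erase a porous but valid candidate
before region growing can consolidate it — we observed exactly this
failure on dark-skin fixtures with radius 3. Lesion pixels are *not*
excluded: the audit measures tone of skin imagery, and lesion-versus-skin
separation is explicitly out of scope.

Masks are scored in a pixel-fraction convention: true/false
positives/negatives as fractions of *all* pixels (they sum to 1, and
accuracy = tp + tn), plus the Jaccard index. Because per-image averaging
versus pixel pooling is a genuine ambiguity in how such numbers get
reported, `evaluate_segmentation_batch()` returns both.

## Stage 4: how dark is the skin?

Three classifiers share one contract (a probability that the image shows
FST V--VI, the positive class):

* **ITA thresholds**: the individual typology angle
  `ITA = atan((L* - 50) / b*) * 180 / pi` is averaged over the mask and
  looked up in a threshold table. The default table is the standard one
  (I: > 55, II: 41--55, III: 28--41, IV: 10--28, V: -30--10, VI: <= -30
  degrees), so the binary cut is V--VI iff ITA <= 10. A value exactly on a
  threshold belongs to the darker category by default; `ita_fst_table(tie
  = "lighter")` flips that, since the convention is not universal.
* **Ensembles** on a 38-dim masked-region descriptor (32-bin HOG over the
  mask's bounding box with non-mask pixels zeroed; mean/sd of L* and b*;
  mean/sd of per-pixel ITA). Five kinds are provided: random forest,
  balanced random forest (per-class balanced bootstrap, aimed at the
  scarce V--VI class), extremely randomized trees, AdaBoost (SAMME.R over
  stumps) and gradient boosting. The ITA summary uses two statistics
  (mean and sd); a mean-only 37-dim variant is available because the
  choice is genuinely open.
* An **18-layer residual CNN** with a 2-class head, consuming the masked
  image (non-skin pixels zeroed) resized to the network input. The
  network is implemented natively (im2col + BLAS); its backward pass is
  verified against finite differences in the test suite, and the
  1000-class topology has exactly 11,689,512 trainable parameters
  (11,177,538 with the 2-class head). Training is momentum SGD (0.9) on
  class-weighted cross-entropy with the learning rate decaying linearly
  to zero across epochs; the reference schedule is 20 epochs, lr 1e-3,
  batch 32. Pretrained backbone weights can be loaded from a file when
  available; otherwise the network trains from He initialization.

Tone metrics are frequency-weighted: per-class binary precision, recall
and F1 averaged with weights equal to the true class frequencies (reducing
to the plain binary metrics under balance), plus accuracy and the
threshold-free AUROC. Data splits are stratified 70/10/20
train/validation/test.

## The report

`audit_document()` chains the stages and aggregates a
`representation_report`: total, skin and non-skin image counts; dark,
light and excluded counts among skin images; and
`prop_dark = n_dark / (n_dark + n_light)`. Images whose segmentation mask
comes back empty cannot be tone-classified; they are excluded from the
proportion's denominator and counted separately, so the count identities
`n_images_total = n_skin + n_nonskin` and
`n_skin = n_dark + n_light + n_excluded` always hold. A document with no
skin images reports an undefined (null) proportion rather than zero.

## The synthetic generator, and what passing tests do and do not show

Nothing in the package requires proprietary textbooks or clinical images:
`gen_dataset()` and `gen_document()` produce fully labeled fixtures. Skin
images are color-jittered ellipses on non-skin backgrounds, optionally
with a clothing rectangle (non-skin foreground) and a darker lesion blob
*inside* the true mask, mirroring the segmentation policy. Light-class
colors are drawn from L* ~ U(60, 78), b* ~ U(12, 22) and dark-class colors
from L* ~ U(28, 45), b* ~ U(4, 14) (a* ~ U(6, 18) for both), rejection-
sampled so light colors have ITA > 10 and dark colors ITA <= -30 degrees.
The two classes are therefore separated by at least 40 degrees of ITA *by
construction*. Non-skin figures emulate charts, text blocks and
histology-stain textures. Documents embed the images three per page and
ship a truth manifest keyed by page, bounding box and pixel checksum.

This design makes the end-to-end recovery tests well-posed: on the
generator's conditions the detector should reach cross-validated AUROC
near 1, segmentation should recover masks with Jaccard well above 0.8,
and every tone classifier should exceed weighted F1 of 0.9 on held-out
images. Passing those tests validates the *machinery* — feature
definitions, mask algebra, training loops, count conservation — not
real-world performance. Real textbook images have correlated texture,
mixed lighting, color-balance drift between cameras, and skin tones that
straddle the binary boundary; none of these is modeled, and accuracy on
real materials must be established against expert labels.

## Problem sizes and numerical choices

The reproducibility script and the heavier tests use a 200-image dataset
(100 skin, 20% dark) for detection, segmentation and tone evaluation, and
fine-tune the CNN for 5 epochs at 64 x 64 input with batch 16 and lr 0.01
from random initialization. These sizes were chosen as the smallest at
which all stages are comfortably separable on the generator's conditions;
the network topology is independent of input size (global average
pooling), and the higher learning rate compensates for the short schedule
— the reference 20-epoch / 1e-3 / batch-32 / 224-px configuration remains
the default of `finetune_cnn()` and `build_cnn()`. All randomness is
seeded; training, evaluation and report generation are bit-reproducible
given a seed.

Other numerical details: sRGB to CIELAB uses exact closed-form conversion
(no lookup tables), and the test suite checks it against an independent
scalar implementation at 1e-9 and against `grDevices::convertColor` at
coarser tolerance; zero-gradient pixels contribute no HOG mass (their
orientation is undefined); `b* = 0` pixels take ITA of +/-90 by the sign
of L* - 50 (0 when L* = 50); empty masks raise errors rather than
returning NaN summaries.

## Known limitations

* Segmentation is intensity-based and keeps lesions; heavily lesional
  images can bias the mean ITA of their own mask.
* The binary endpoint (I--IV versus V--VI) deliberately trades granularity
  for label reliability; six-class output exists only inside the ITA path.
* The PDF reader does not rasterize vector art, decode predictor-filtered
  or indexed color streams, or parse .pptx/.docx.
* ITA-based tone estimation is sensitive to lighting and color balance;
  on real photographs the trained classifiers are expected to degrade
  more gracefully than the threshold rule, but neither is calibrated for
  uncontrolled imagery.
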