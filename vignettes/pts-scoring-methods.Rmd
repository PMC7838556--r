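---
title: "Peri-tumoral stroma scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-tumoral stroma scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptsscore)
```

This vignette is the package's own account of its science: the model behind
the PTS score, the assumptions each stage makes, the parameters that matter
and why their defaults are what they are, what the synthetic data does and
does not emulate, and the choices we made where the design was genuinely
open.

## The score

A whole-slide H&E image is segmented into seven tissue classes — colon
cancer epithelium (tumor), stroma, lymphocytes, mucus, adipose tissue,
smooth muscle and normal colon mucosa — plus a background label that never
counts as tissue. The tumor *region* is obtained by morphological closing of
the tumor mask: dilation followed by erosion with the same structuring
element (SE). Closing is extensive (never removes tumor) and idempotent, and
it bridges intra-tumoral gaps narrower than the SE, so stroma lying in
gland lumina, clefts and pockets *inside* the tumor ends up within the
region while distant stroma does not. The score is

$$\mathrm{PTS} = \frac{\#\{\text{stroma pixels inside the closed tumor region}\}}{\#\{\text{tumor pixels}\}},$$

dimensionless and possibly above 1 (a slide can hold more peri-tumoral
stroma than tumor). Stroma pixels that fall inside the region but outside
the raw tumor mask are counted — that is precisely what "within the tumor
region boundaries" means; the denominator is the raw tumor pixel count, not
the region area.

**SE choice.** The SE is the one genuinely free parameter. The default is a
disk of radius 64 px, about 32 µm at 0.5 µm/px: wide enough to bridge gaps
larger than a typical gland lumen, narrow enough not to annex stroma far
from the invasion front. Every `pts_result` records the SE used; nested
disks never decrease the PTS area (asserted in the tests), so the score is
monotone in this parameter and must always be reported alongside it. An
optional minimum-object-size filter can drop salt-noise tumor specks before
closing; it is off by default because it alters the denominator.

**Borders and resolution.** Label maps are padded with background by the SE
extent before closing, so image edges never truncate the region. Slides may
be scored at a downsampled resolution; because the score is a ratio, the
factor cancels as long as numerator and denominator share it.

## Stain and intensity normalization

Tiles are normalized before segmentation in a fixed order: Macenko stain
normalization first, per-channel histogram normalization second. (The
upstream protocol applies both "prior to thresholding" without fixing an
order; we fix Macenko → histogram because the histogram stretch
standardizes whatever dynamic range the stain remapping produces.)

The Macenko step works in optical density, $OD = -\log_{10}(I/255)$, with a
floor of $1/255$ so white pixels stay finite. Pixels with OD norm above
$\beta = 0.15$ are tissue; the top-2 singular plane of that cloud holds the
two stain directions, which are read at the 1st/99th percentile angles
(the Macenko reference values — the upstream description names the method
without parameters). We use inverse-ECDF percentiles so the estimate is
invariant under pixel duplication. Signs are flipped to the nonnegative
octant, and the column with the larger red-channel OD component is labeled
hematoxylin (H absorbs red most strongly); this ordering convention is what
makes recomposition reproducible. Concentrations are solved by exact
nonnegative least squares (closed form for two stains), rescaled so each
stain's 99th-percentile maximum matches the target's, and recomposed with
the target matrix. Blank tiles raise an "insufficient tissue" error rather
than returning garbage vectors.

Histogram normalization maps each channel's min to 0 and max to 255
affinely with round-half-even; a constant channel passes through unchanged,
because any other choice fabricates contrast. Round-half-even is used
everywhere intensities are quantized.

## The segmenter

The segmenter is a U-Net implemented in base R: `depth` encoder levels of
two 3×3 convolution + batch-norm + ReLU pairs with 2×2 max-pooling, a
bottleneck block, mirrored decoder levels with 2×2 stride-2 transposed
convolutions and skip concatenation, a 1×1 softmax head over the seven
classes, cross-entropy loss and Adam. All heavy arithmetic is BLAS matrix
multiplication via im2col, and the backward pass is verified against
numerical differentiation in development. The architecture defaults (depth
4, 16 base filters, input 512) follow the common U-Net recipe; only the
"U-Net" family itself is fixed by the upstream method, so all of these are
configuration.

Training patches of 224 px are brought to the network input size by
**reflect padding**: mirrored interior values without repeating the edge
pixel, split evenly with the extra pixel on the bottom/right. Larger images
are tiled into input-size windows at inference and stitched back. Datasets
are split 80/10/10 into train/validation/test, stratified by each tile's
majority class with exact global counts (largest-remainder rounding).

**Early stopping.** After every epoch the mean validation Dice similarity
coefficient (DSC) is computed, pooled over patches and classes present in
truth or prediction. Training stops when no epoch within the last
`patience = 10` improved the best value by at least `min_gain = 0.1%`, and
the weights returned are those of the *best* epoch, not the last. We read
"0.1%" as a relative improvement (×1.001); at DSC near 0.9 the absolute
reading differs by under 10%, and both agree on all scripted sequences
tested. The rule itself is exposed as `early_stopping_status()` and checked
against an independent reference implementation.

**Dice conventions.** Per class, DSC = 2|P∩T|/(|P|+|T|). When a class is
absent from both maps the value is defined as 1 (absence correctly
predicted) but such patches are excluded from that class's n — otherwise
trivially-empty patches would inflate per-class means; this also matches
the way per-class confidence intervals shrink with differing patch counts.
Reports use normal-approximation 95% intervals over patches; a bootstrap
alternative was considered and rejected as heavier without changing any
decision at the problem sizes used here.

A multi-level Otsu threshold (`tissue_threshold`, exhaustive
between-class-variance search, brightest stratum = glass) provides a
tissue/background pre-mask; it does not post-process class labels. This is
the narrower of the two readings of thresholding-based segmentation in the
upstream description, chosen because the U-Net already assigns classes.

## Synthetic data: what it emulates and what it does not

The generators exist so that every downstream stage has pixel-exact or
analytic ground truth.

* **Tiles** are single-class squares of a base color plus clipped Gaussian
  RGB noise (optionally drawn on a coarse grain and upscaled). Base colors
  are pairwise separated by a margin (default 30 intensity levels) and
  specs below the margin are rejected as unlearnable. This is the simplest
  model a small U-Net provably learns; it emulates the balanced-class patch
  archives used for tissue classifiers (224 px, roughly equal class
  counts). It does **not** emulate nuclear texture, scanner artifacts or
  stain heterogeneity, so a perfect DSC here demonstrates that the training
  loop, stopping rule and decoding work — not that the network would reach
  any particular accuracy on real slides.
* **Slides** are axis-aligned rectangle compositions — tumor rectangle,
  disjoint interior stroma holes, an exterior stroma band, filler tissue,
  background border — because rectangles make every area an exact integer
  (no anti-aliasing ambiguity). For any SE that fills all holes, the closed
  region is the full tumor rectangle, so the expected score is exactly
  (hole area)/(tumor area); the morphology pipeline must reproduce it to
  the pixel, and does.
* **Cohorts** draw the PTS score from a Beta distribution scaled to
  [0, 1.2] — nonnegative, right-skewed, allowing scores above 1 —
  parameterized by target mean/SD with defaults 0.380/0.285, the observed
  cohort values. LNM is Bernoulli with logit linear in the score; the
  default slope is log(29.654) (the reported per-unit odds ratio) and the
  intercept −1.69 places the marginal LNM rate near 66/164 at the mean
  score. Invasion flags (LI/PI/VI) are drawn conditionally on LNM with the
  observed two-group frequencies and masked to NA at the observed rates;
  the flags are conditionally independent given LNM, a modeling choice —
  no joint distribution is published. T stages follow the observed
  per-group frequencies. The derived AnyI flag is "yes" if any flag is yes,
  NA if none is yes but one is missing (absence cannot be asserted from
  incomplete data), else "no".

## Cohort statistics

The exclusion ledger applies rules sequentially — rectal cancer, inadequate
image, distant metastasis — attributing each record to the first matching
rule, so counts always sum to the number removed. Descriptive tables use
pooled-variance Student's t (the named test; not Welch) for age and score,
and Pearson chi-square without continuity correction for categoricals,
displaying NA rows but excluding them from tests (the upstream handling of
NA in tests is unstated; excluding is the conservative reading).

Univariate logistic fits use `glm(binomial)`; odds ratios carry Wald 95%
intervals — consistent with the very wide published intervals on 164
patients — and complete separation is flagged rather than reported as a
huge finite OR. For a binary predictor the fitted OR equals the
contingency cross-product ratio, which the tests verify to four significant
figures. ROC AUC uses the Mann–Whitney rank-sum identity with midranks, so
ties are handled exactly; the 95% interval uses the DeLong placement
variance, cross-checked against an independent implementation in the test
suite. T-stage subgroups split at {T0–T2} vs {T3–T4}; strata with fewer
than two events or two non-events are reported as NA rows, matching how
degenerate cells are published.

Two calibration properties tie generator and fitter together and are
re-measured by the acceptance script: over 200 cohorts of n = 2000 with
slope 3.0, the Wald interval covers the truth at a rate inside [0.90,
0.99], and the mean fitted slope is within ±0.15 of 3.0.

## Problem sizes, numerics and reproducibility

The shipped tests and the acceptance script run the segmenter at desk
scale: 32-px tiles, depth 3, 8 base filters, 210 tiles, batch 8, learning
rate 0.01, at most 20 epochs. These sizes are the package's chosen study
conditions for the separable-task benchmark; small batches of flat-color
tiles make batch-norm statistics noisy, which is why the benchmark uses
batch 8 rather than smaller, and a 10× larger learning rate than the 1e-3
default that suits richer data. Published-scale accuracy (test DSC ≈ 0.89
on 100 000 real patches) is explicitly out of reach of a CPU-scale run and
is not a test target; the synthetic benchmark instead requires validation
mean DSC ≥ 0.95, which the separable task must achieve if the training
machinery is correct.

Every stochastic stage is a pure function of (spec, seed): generators
save and restore the RNG state, the trainer seeds initialization and
shuffling from its config, and the pipeline derives per-stage seeds from a
single root seed so stages are independently reproducible. The end-to-end
manifest records MD5 checksums of every output; re-running with the same
config and seed reproduces them bit-for-bit, and the acceptance script
asserts exactly that.

Known numerical edge cases, and what the code does: white pixels (OD floor
at 1/255); blank tiles ("insufficient tissue" error); constant channels in
histogram normalization (pass-through); two-stain NNLS with both
unconstrained coefficients negative (projects to the better single-stain
axis); argmax ties in label decoding (first class wins); Dice on
empty-empty masks (defined 1, excluded from per-class n); maps with no
tumor pixels ("no tumor in slide" error rather than a 0/0 score).

## Limitations

The synthetic renderer draws flat-colored geometry; none of the texture,
stain variation or scanner artifacts of real slides exist here, so green
tests bound correctness of the algorithms, not clinical performance. The
stain model handles exactly two stains plus residual; slides with heavy
third-dye content are outside its assumptions. The morphology is binary
and global — per-focus sub-scores and geodesic refinements are out of
scope. The cohort generator's conditional-independence structure for
invasion flags is a convenience, not an estimate of the real joint
distribution.
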