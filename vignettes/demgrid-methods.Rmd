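---
title: "Methods: dementia classification on coronal slice grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dementia classification on coronal slice grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demgrid)
```

# The problem

Three-class dementia staging — cognitively normal (CN), mild cognitive
impairment (MCI), Alzheimer's disease (AD) — from T1-weighted structural MRI
is a canonical imbalanced-classification problem: AD scans dominate clinical
archives (about 43% here, against 34% MCI and 22.5% CN), and classifiers
trained naively on such data collapse onto the majority class while still
posting a respectable-looking raw accuracy. `demgrid` implements the full
analysis pipeline around that problem: a seeded synthetic cohort generator, a
five-stage preprocessing chain ending in a 2D "slice grid" representation,
patient-level leakage-free splitting, a suite of imbalance mitigations, small
capsule-network and CNN classifiers, and an evaluation framework whose
metrics remain informative under severe imbalance.

Everything is deterministic under explicit seeds, and every stage is
separately testable without access-controlled clinical data.

# The slice-grid representation

Each 3D volume is reduced to a single 512 x 512 8-bit image built from ten
coronal sections taken at fixed millimetre offsets from the
anterior-commissure analogue:

```{r}
grid_slice_offsets()
```

The offsets span 18 mm centred on the medial temporal lobe, the region where
hippocampal atrophy and ventricular enlargement are most informative for
dementia staging. Each section is resampled to 102 x 256 pixels with
Catmull-Rom bicubic interpolation, the five posterior sections are tiled as
the top row and the five anterior ones as the bottom row (a 510 x 512
mosaic), and a final bicubic resize produces exactly 512 x 512. Left-right
orientation is preserved in every tile; a convention test pins this down. The
510-to-512 bridge is the only resampling step that mixes neighbouring tiles,
by at most one pixel at the seams.

# Synthetic cohorts

The generator renders ellipsoidal head phantoms with T1-like intensity tiers
(white matter > grey matter > CSF), two hippocampal blobs and two
ventricular cavities. Diagnosis acts through two linear scale parameters:

```{r}
str(default_class_effects())
```

The direction of these effects (hippocampal shrinkage, ventricular
enlargement along the CN to AD axis) follows the neuropathology; the
magnitudes are a package design choice, picked once so that a small
classifier can beat chance on desk-scale cohorts, and exposed in the
configuration. Class proportions default to the 22.6/34.1/43.3 clinical mix;
per-class patient counts are apportioned by largest remainder so they always
sum to the requested cohort size. Ages are class-conditional normals (CN
72, MCI 74, AD 77, sd 6 years) and sex is Bernoulli(0.5) — these exist
so that the stratified splitter has non-degenerate strata, not as a
demographic model. The default lattice is 96 x 112 x 96 voxels at 2 mm
(1 mm is supported); unit tests mostly use a 64 x 80 x 64 lattice for speed.

What the phantoms deliberately do not emulate: cortical folding, partial
volume effects, scanner-specific contrast, registration-hostile anatomy
variation, and multi-site batch effects. Passing tests on phantoms therefore
demonstrate that the pipeline machinery is correct and that the stated
effect sizes are recoverable — not that any architecture would reach a given
accuracy on clinical data.

# Preprocessing stages and their numerical choices

**Quality control.** SNR is mean foreground over background standard
deviation, with foreground thresholded at 20% of the robust (2nd-98th
percentile) intensity range. A scan is rejected when SNR < 20 or the motion
score exceeds 0.3; otherwise the quality score is
`0.4 * min(snr, 40)/40 + 0.3 * (1 - motion) + 0.3 * uniformity`. Raw SNR is
unbounded and cannot enter a [0, 1]-weighted score directly; normalising by
40 — twice the rejection threshold — maps the threshold to 0.5, which is the
least surprising choice. The motion score is a spectral Nyquist-ghost
estimator: a replica shifted by half the field of view along the
phase-encode axis scales even and odd k-space lines by (1 ± a), so the
even/odd magnitude disparity (odd lines against the geometric mean of their
even neighbours, median over a mid-frequency band) estimates the replica
amplitude a directly. This is preferred over image-space correlation with a
shifted copy because correlation is insensitive to the ghost amplitude and
requires a background segmentation that the ghost itself corrupts.
Uniformity is `1 - IQR/median` of the low-pass-filtered foreground, clipped
to [0, 1].

**Brain extraction.** Fractional-intensity thresholding at
`robust_min + 0.3 * (robust_max - robust_min)`, largest 6-connected
component, 3 x 3 x 3 morphological closing, interior hole filling, and a
gradient-weighted soft mask (the binary mask box-smoothed once) so edges
taper instead of cutting. This reproduces the behaviour of standard brain
extraction at desk scale without external tools.

**Spatial normalisation.** A 12-parameter affine (translation, rotation,
scale, shear) is estimated by minimising one minus the correlation ratio of
template and resampled subject intensities (24 bins), initialised from the
intensity centres of mass and refined by Nelder-Mead with a coarse-to-fine
restart; the cost is evaluated on a subsampled template-foreground grid
(stride 2 by default) and the final volume is resampled by trilinear
interpolation onto the template lattice. Nonlinear warping is deliberately
out of scope; on phantom anatomy the affine family recovers known
translations to under half a voxel and isotropic scales to under 2%, which
the tests enforce. If optimisation fails to improve on its initialisation
the initial transform is returned with a warning rather than an error.

**Intensity normalisation.** Three-class k-means on the brain-masked voxels
(the highest-mean class is white matter; an error is raised if it holds
fewer than 100 voxels), z-scoring by the WM mean and standard deviation,
optional histogram matching to a reference quantile function, clipping at
the 99.5th percentile and linear rescaling to [0, 255]. The reference
histogram is accumulated from the training-split scans of the current run —
a population reference is not distributable — so validation and test scans
are matched to a distribution estimated without them.

# Splitting and leakage

Patients (never scans) are assigned 70/20/10 to train/validation/test,
stratified by diagnosis, age band (<70, 70-80 inclusive, >80) and sex, under
seed 42 by default. Within each stratum patients are sorted by id before the
seeded shuffle, making the split invariant to input order; counts are
apportioned by largest remainder. Strata with fewer than three patients are
merged into the largest stratum of the same diagnosis — pooling age and sex
but never diagnosis — since apportioning three ways inside a two-patient
stratum is meaningless. All scans follow their patient, which makes
longitudinal separation automatic. `verify_no_leakage()` re-checks the
invariant mechanically and the trainer refuses to run when handed a failing
report. Note that with very small cohorts a stratum-wise 70/20/10 split can
leave the test set empty; the pipeline aborts with a clear message rather
than silently evaluating on nothing.

# Imbalance mitigation

The plan arithmetic is exact and tested against the canonical worked
example (training counts 2203/3325/4222): inverse-frequency weights
1.92/1.27/1.00, SMOTE synthesis 2019/897/0 up to the majority count,
undersampling removals 0/1122/2019 down to the minority count.

Synthesis uses Borderline-SMOTE-1: a minority point is DANGER when, among
its m = 10 nearest neighbours over all classes, at least m/2 but not all
belong to other classes; synthetic points interpolate between a DANGER seed
and one of its k = 5 nearest minority neighbours (falling back to the whole
minority class if no DANGER points exist). m and k are the literature
defaults. The feature space is configurable and defaults to downsampled
flattened grids, since no canonical image feature space is prescribed for
this step. Real rows are never modified; synthetic rows are flagged; the
operation is only ever applied to training data.

Three losses are provided with exact zero-points and reductions
(focal loss with gamma = 0 and unit alpha is cross-entropy): weighted
cross-entropy, focal loss (gamma = 2, alpha = 0.45/0.34/0.22 with the
largest weight on the rarest class, CN), and the capsule margin loss
(m+ = 0.9, m- = 0.1, lambda = 0.5). The combined strategy resamples first
(Borderline-SMOTE) and then trains under the focal loss; the cost-sensitive
weights are kept separate from alpha rather than multiplied into it, since
stacking two inverse-frequency corrections would over-correct.

# Models

The capsule head follows the standard routing-by-agreement construction: a
9 x 9/256 convolutional stem, 32 channels of 8-dimensional primary capsules
from a 6 x 6 stride-2 convolution, three 16-dimensional class capsules, and
r = 3 routing iterations. Routing logits start at zero — initialising the
couplings themselves at zero would be non-normalisable, so "couplings
initialised to zero" is read as zero logits, i.e. uniform couplings. The
squash nonlinearity is adopted from the original capsule formulation, since
routing is undefined without a length-bounding nonlinearity. Digit-capsule
transform weights are shared across spatial positions within each primary
channel: at a 512-pixel input, per-capsule weights would need billions of
parameters, and the shared variant is what large-input capsule
implementations use. With the 512/1024-unit reconstruction decoder
(reconstructing a 64 x 64 downsampled view; reconstructing the full
512 x 512 image is not feasible in a dense decoder) the full-scale geometry
counts 7.14M parameters, within 15% of the published 8.2M figure for this
architecture family.

Training is minibatch Adam (learning rate 0.001, decay 0.9 every 100
epochs), global gradient-norm clipping at 0.5, batch size 16, and early
stopping with patience 50 on the validation loss, with best-epoch weights
restored. Backpropagation through the capsule head treats the routing
couplings as constants of the final iteration — gradients flow through the
coupled sum and the squash but not through the routing logits. At r = 1 this
is exact (the tests verify it against central differences); at r = 3 it is
the standard approximation, and desk-scale memorisation tests confirm it
trains.

The baseline CNN is a deliberately small one-convolution softmax classifier
standing in for full-scale pretrained backbones, whose training is out of
scope here. What it preserves is every bespoke element of the training
protocol: the losses, the schedule, the clipping, the early stopping, and
the leakage gate.

# Evaluation conventions

All table-style percentages are integers rounded half away from zero; 0/0
ratios (precision of a never-predicted class) are reported as 0. Balanced
accuracy is the mean of macro sensitivity and macro specificity — the
convention under which every single-class predictor on a three-class
problem scores exactly 50%, consistent with the degenerate rows this
package reproduces. The ordinal MSE codes CN = 0, MCI = 1, AD = 2 and
reports the mean squared coded difference x100; this coding is the only one
consistent with the reproduced table values (the all-AD predictor scores
124%, the all-MCI predictor 66%). ROC AUCs count ties as one half; the micro
AUC is computed on the flattened one-vs-rest pairs; AUC-PR is trapezoidal;
MCC is the generalised multiclass form.

The bias index has no canonical formula, so the package defines one with
the properties the reported values require: the total-variation distance
between predicted and true class distributions, normalised by
`sum(phat_c (1 - p_c))`, its attainable ceiling under the predicted mix.
This makes every single-class collapse score exactly 1.0 regardless of
which class it collapses to, and a distribution-matched predictor score 0;
the normalisation is configurable. No "imbalance index" is reported, since
no defining formula is available for it.

Model ranking min-max normalises each criterion to [0, 1] (constant columns
map to 0), sorts by performance score, and breaks ties by top-5 accuracy
then by smaller parameter count.

# Problem sizes and determinism

The test suite runs phantoms at 64 x 80 x 64 x 2 mm, trains on 32 x 32
downsampled grids, and uses cohorts of 24-300 patients; the end-to-end
recovery property (a small CNN beating chance by 15+ points of macro
sensitivity) uses 300 patients at the default effect sizes, and the
mitigation property compares CN sensitivity with and without the combined
strategy over three seeds. These sizes are the package's choices for a
desk-scale test bed. Every stochastic component draws from a seed derived
deterministically from a single master seed, so cohorts, splits, SMOTE
draws and training histories are all bit-reproducible; reruns of the
pipeline produce identical manifests and the tests assert it.

# Known limitations

Affine-only registration; phantom (not anatomical) test data; a one-layer
CNN baseline rather than the full pretrained model zoo; no DICOM handling,
no multi-site harmonisation, no nonlinear warping, no attention-map
interpretability. The capsule routing gradient is approximate beyond one
iteration. These bounds are deliberate: the package's claims are about the
pipeline's arithmetic, invariants and reproducibility, all of which are
enforced by the test suite.
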