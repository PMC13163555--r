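---
title: "Gradient-DDP texture descriptors for MS MRI: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-DDP texture descriptors for MS MRI: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multiple sclerosis (MS) produces focal demyelinating lesions that appear
hyperintense on T2-weighted and FLAIR MRI and hypointense on T1. Two
clinical questions drive this package: *is a subject affected* (binary
detection against lesion-free controls), and *how advanced is the disease*
(mild / moderate / severe grading by lesion load — the number and total
volume of lesions). Both are approached slice-wise: a compact texture
descriptor is computed per 2D slice, and a classical classifier operates on
those descriptors under a subject-exclusive cross-validation protocol.

## The descriptors

**Classical DDP.** The intensity-based Decimal Descriptor Pattern scans
every interior pixel and records the mean, maximum and minimum of its 3×3
neighbourhood (`ddp_neighborhood_stats()`; borders are excluded rather than
padded, so no intensities are fabricated). The concatenated statistics form
a raw vector *b*.

**Gradient-DDP.** The gradient-enhanced variant replaces intensity
statistics with local *variation* statistics. The slice gradient is the
standard numerical gradient (central differences inside, one-sided at the
boundary; exact on affine images), giving per-pixel magnitude
$G_{mag}=\sqrt{G_x^2+G_y^2}$ and orientation $G_{dir}=\mathrm{atan2}(G_y,
G_x)$. The slice is tiled into non-overlapping 3×3 blocks (trailing partial
blocks dropped, row-major order) and each block contributes three
statistics: mean of $G_{mag}$, population variance of $G_{mag}$, and the
*circular* mean of $G_{dir}$, $\mathrm{atan2}(\overline{\sin},
\overline{\cos})$ — an arithmetic mean of angles is discontinuous at
$\pm\pi$, the circular mean is not. Because gradients annihilate additive
intensity shifts, the full Gradient-DDP feature is invariant to global
intensity offsets, a property the intensity DDP lacks at the raw-statistics
stage (though min–max normalization later removes affine intensity maps for
it too).

**Shared encoding.** Either raw vector is min–max normalized to $[0,1]$
over the *whole* vector (the statistics' own minimum/maximum/mean anchor
the code book; a per-channel option exists but is not the default), mapped
to 11 discrete codes, and summarized as a 16-bin normalized histogram over
the code range $[0,10]$ — the feature the classifiers see. A configuration
flag instead bins the pre-quantization normalized values on $[0,1]$; with
11 discrete codes and 16 bins, five bins are structurally empty in the
default path, which is intentional fidelity to the published protocol
rather than an inefficiency we hide.

**The quantizer.** Codes are anchored at the vector statistics: the
minimum maps to 0, the maximum to 1, the mean to 6 (equality tested within
a relative tolerance of $10^{-12}(b_{max}-b_{min})$, since exact float
equality is measure-zero). The remaining values fall into interval rules
cut at quarter points. The published cut points for the upper half,
$(\mu+b_{max})/4$ and siblings, are kept verbatim in the default
`"literal"` mode even though they can stray below $\mu$ — the rules are
then not an ordered partition, so they are evaluated first-match
top-to-bottom with a fallback code of 10, making the mapping total. Two
consequences of taking the table literally deserve note: code 1 (the
maximum) breaks ordinal order by design, and the equality anchors must take
precedence over the interval rules — evaluated strictly in printed order,
the interval rule ending at $3(\mu+b_{min})/4$ swallows the mean itself
whenever $b_{min} > \mu/3$, contradicting the table's own
$b_i=\mu\rightarrow 6$ row. A `"monotone"` mode replaces the cut points
with $b_{min}+k(\mu-b_{min})/4$ and $\mu+k(b_{max}-\mu)/4$, $k=1,2,3$,
yielding a proper ordered partition; it is the defensible reading but not
the default, and the mode used is recorded in the feature provenance.

## The phantom

Real reference data (simulated brain databases, clinical FLAIR sets)
require downloads, so the package ships a self-contained 2D anatomy proxy:
a filled ellipse brain with a CSF ring, a gray-matter band and a
white-matter core, per-subject jitter on the outer axes, and elliptical
lesions placed by rejection sampling entirely inside white matter (100
attempts per lesion, then an error — which prevents silent infinite loops
on undersized masks). Tissue means per modality follow the qualitative
contrast contracts: lesions brighter than white matter on T2/FLAIR, darker
on T1, CSF suppressed below gray matter on FLAIR. Corruptions are a
smooth multiplicative second-order polynomial bias field spanning
$1\pm a$ (intensity non-uniformity, default $a=0.1$) and additive Gaussian
noise (default $\sigma=3$ on tissue means of order 100–200; a Rician
option reflects the true magnitude-MRI noise law, which is approximately
Gaussian at these signal levels).

Severity grades are lesion-load ranges: mild 1–3 lesions with 1–3 px
semi-axes, moderate 4–8 with 2–5 px, severe 9–15 with 4–8 px — separable
but overlapping, with expected total lesion area strictly increasing.
Lesions are re-sampled per slice (whether the source protocol fixed them
in 3D per subject is unstated; per-slice re-sampling is our choice and is
noted as such), while the anatomy is fixed per subject. Binary labels are
derived from the lesion mask itself, so label soundness (MS ⇔ non-empty
mask) holds by construction.

**Why binary-task MS subjects default to the moderate grade.** A mild
lesion (1–3 px semi-axes) perturbs only $k\approx1$–3 of the $\approx441$
blocks of a 64×64 slice. Its footprint on the 16-bin histogram is of order
$k/N$, while the histogram's own sampling variability per bin is of order
$1/\sqrt{N}$ — and the ratio $k/\sqrt{N}$ *shrinks* as resolution grows.
Global code histograms are therefore structurally insensitive to minimal
lesion loads; a binary population built from mild subjects is nearly
inseparable regardless of noise settings. The default binary dataset hence
gives MS subjects the representative moderate load
(`binary_severity = "moderate"`), keeping the detection task
well-separated; `"cycle"` rotates mild/moderate/severe for a deliberately
harder population, and the severity task always uses all three grades.

**Default problem sizes.** Slices are 64×64 with 30 slices per subject and
20 subjects per class in the reference experiments — small enough to run
the whole pipeline in seconds while leaving hundreds of blocks per slice,
which is the regime the descriptor needs.

## Evaluation protocol

Slices never cross splits: whole subjects are assigned to folds
(`subject_stratified_split()`), greedily and seeded, balancing per-class
subject counts to within one. Each of the K rounds uses fold *r* for test,
fold *r+1* (cyclically) as a dedicated validation set and the rest for
training. Nothing is selected on the validation fold — its metrics are
reported only, mirroring a protocol that declares a validation set without
describing any tuning on it; rotation keeps all three roles
subject-exclusive simultaneously.

Classifiers are the four classical references with fixed hyperparameters:
RBF SVM (C = 10, γ = "scale", i.e. $1/(d\,\mathrm{Var}(X))$), k-nearest
neighbours (k = 3, inverse-distance weights, Euclidean), LDA (SVD solver,
no shrinkage; structurally constant histogram bins are dropped before the
fit since the histogram's unit-sum constraint makes the design collinear),
and an L2-penalized logistic classifier (ridge at λ = 1/n, multinomial for
three classes). The source description of its "logistic regression"
actually reads as ordinary least squares; a penalized logistic model is
implemented because the model is used for classification throughout. All
fits are deterministic given the data.

Metrics: accuracy, macro-averaged precision/recall/F1 (zero-division cells
contribute 0 — the conservative choice for multiclass averaging), the
confusion matrix, and the Matthews correlation coefficient — binary closed
form on 2×2 tables, generalized correlation form otherwise, 0 by
convention on zero denominators. Per-modality MCC values are aggregated as
mean ± *population* standard deviation to three decimals; the population
form is the one consistent with the published triplet summaries the
package reproduces in its acceptance checks.

## What the phantom does and does not show

The phantom validates the machinery: descriptor correctness, leakage-free
splitting, severity monotonicity, and that the end-to-end pipeline
recovers a signal it provably contains (and loses it under label
permutation — the permutation null concentrates MCC near zero). It does
*not* establish clinical performance: the anatomy is a concentric-ellipse
cartoon without gyri, partial-volume effects, registration error, scanner
variability or 3D lesion continuity, and lesion contrast is a single mean
with noise rather than a heterogeneous texture. Accuracies on the phantom
are therefore properties of the simulation, not predictions for clinical
data; real volumes can be substituted through the NIfTI/PNG loaders
without touching the rest of the pipeline.

## Numerical conventions collected

* Gradient at zero-gradient pixels: direction 0 via atan2(0, 0).
* Min–max normalization of a constant vector: all zeros.
* Quantizer: equality tolerance $10^{-12}(b_{max}-b_{min})$; fallback code
  10; anchors precede interval rules.
* Histogram: right edge inclusive in the last bin; values clamped to the
  bin domain.
* kNN: a zero-distance neighbour restricts the vote to exact matches; class
  ties break toward the earlier factor level.
* Population (denominator N) variance and standard deviation throughout.
* Every stochastic step is seedable, and identical configurations
  reproduce datasets, splits and reports bitwise.
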