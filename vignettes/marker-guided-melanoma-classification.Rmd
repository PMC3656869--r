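---
title: "Marker-guided melanoma cell classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-guided melanoma cell classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melmark)
```

## The problem

Immunohistochemistry (IHC) on tissue-microarray (TMA) cores is the workhorse
of tissue-based biomarker studies. For melanoma, every readout of a candidate
marker (such as the proliferation antigen Ki67) requires knowing which nuclei
belong to melanoma cells and which belong to the surrounding stroma,
lymphocytes or keratinocytes. Annotating nuclei by hand does not scale.

melmark implements a *marker-guided* alternative: a melanocyte-specific IHC
stain (Melan-A, visualised with the brown DAB chromogen) labels melanoma
regions chemically. The labels a staining mask provides are used to train a
texture-based nucleus classifier — no human annotation enters the training
loop. Once trained, the classifier recognises melanoma nuclei from the
hematoxylin counterstain alone, so it can be applied to sections stained for
any other marker, and the DAB channel there is free to carry that marker's
signal.

## The optical model

Brightfield stains absorb light according to Beer-Lambert: with blank-slide
intensity $I_0$ and per-pixel stain concentrations $c_s$, the transmitted
intensity in colour channel $k$ is

$$ I_k = I_0 \cdot 10^{-\sum_s c_s M_{sk}}, $$

where $M_{sk}$ is the unit optical-density (OD) colour vector of stain $s$.
Concentrations therefore mix *linearly in OD space*, and a $3\times3$ linear
solve per pixel ("colour deconvolution") separates hematoxylin from DAB.
The package ships calibrated vectors for hematoxylin
$(0.575, 0.681, 0.453)$ and DAB $(0.269, 0.570, 0.776)$; both are unit norm
to within $5\times10^{-4}$ and are re-normalised on construction. The third
(residual) row is their normalised cross product, so the matrix is always
invertible for non-parallel stains.

Two numerical choices matter here:

* **OD transform.** We use $\mathrm{OD} = -\log_{10}(\max(I, \varepsilon)/I_0)$
  with $\varepsilon$ = 1 gray level. The floor guards $\log(0)$ at saturated
  pixels. We deliberately floor rather than add $\varepsilon$ to $I$: an
  additive guard biases OD by $\approx 0.43/I$, which already reaches
  0.02 OD at $I = 21$ and would dominate the error budget of 8-bit images;
  the floor is exactly zero-bias above $\varepsilon$.
* **Negative concentrations.** Pixels outside the colour cone of the two
  stains solve to slightly negative concentrations (quantization noise).
  They are clipped to zero after solving and the clipped fraction is
  reported as a QC metric.

With 8-bit quantization the worst-case per-channel OD error is
$0.5/(I\ln 10)$, amplified by at most $\approx 3.7$ through the matrix
inverse. The synthetic generator therefore keeps per-channel OD below
$\approx 0.7$ ($I \gtrsim 50$), representative of a well-stained,
non-saturated section; within that regime deconvolution recovers the true
densities to better than 0.02 OD, which the test suite verifies on fifty
seeded scenes.

## The synthetic scene generator

No public image set accompanies the method, so the generator is a
first-class module: it produces scenes with *known* nucleus positions,
class labels, marker masks and per-cell biomarker positivity, which is what
makes every downstream stage testable.

A scene consists of:

* elliptical nuclei placed by dart-throwing with a minimum centre distance
  of `spacing` times the sum of the two radii — 1.2 for the non-touching
  presets, 0.8 for the touching preset used to exercise declumping;
* melanoma nuclei confined to a few contiguous circular clusters, which also
  carry DAB density (the marker mask ground truth); other nuclei outside;
* intra-nuclear chromatin texture: band-pass filtered white noise whose blob
  radius equals the class grain radius (1.5 px for melanoma, 4 px for other
  nuclei in the `separable` preset — one knob that maps directly onto the
  granularity spectrum);
* a faint, spatially textured cytoplasmic hematoxylin blush over the whole
  core (real cores are tissue-filled), at 3% of the nuclear amplitude;
* optional small, isolated DAB speckles outside clusters that emulate
  melanin pigment — a functional confounder for the mask's pigment guard,
  not an optical model of melanin;
* for biomarker (Ki67-style) scenes, DAB placed as nuclear/perinuclear
  staining on an exact-count random subset
  ($\mathrm{round}(f \cdot n)$ drawn without replacement) of melanoma
  nuclei, so small-scene tests are deterministic in expectation structure.

Default amplitudes are hematoxylin 0.85 OD peak and DAB 0.4 OD — mid-range
staining chosen for the quantization argument above. Nucleus radii are
normal with mean 6 px and SD 1 px, clamped to a 4.2 px minimum: at the
emulated resolution a smaller object is not a credible nucleus, and the
generator should not plant truth below the segmenter's documented size gate
(40 px²). Everything is driven by one integer seed; identical parameters
and seed give bit-identical scenes.

What the generator does *not* emulate — scanner noise, JPEG compression,
chromatic aberration, stain co-localisation in single pixels beyond the
linear model, out-of-focus tissue, true melanin optics — bounds what
passing tests mean: they establish the pipeline's correctness and internal
consistency, not its performance on any real cohort.

## Mask generation

The marker (Melan-A) mask thresholds the DAB density (Otsu over nonzero
densities by default), closes with a disk of radius 2, removes components
below `min_cluster_area` (400 px² by default — the *pigment guard*: single
pigmented melanocytes and speckles are far smaller than melanoma cell
nests), grows the survivors outward over a secondary threshold at half the
primary, and fills small holes. Growing only ever extends components that
passed the guard. The adaptive (Otsu) threshold is recomputed from the data,
so masking is *not* exactly idempotent under re-application to its own
masked output; with a fixed threshold it is, and the test suite pins that
version of the property.

The tissue mask uses a fixed low threshold (0.02 OD) on the hematoxylin
density: any measurable counterstain is tissue, while blank glass
deconvolves to essentially zero. Object-level thresholds (Otsu, robust
background) would discard faint cytoplasm and under-segment tissue.

## Nucleus segmentation

The hematoxylin channel is sharpened (Gaussian smooth, $\sigma = 1$, then
unsharp masking) for object detection only. Foreground is taken above a
robust background threshold — trimmed mean plus $k$ SD. The function default
is the textbook 5%/5% trim with $k = 2$; the *pipeline* default trims the
top 25% and uses $k = 3.5$. The wider trim is what makes the threshold
independent of how much of the frame the nuclei occupy: with a 5% trim,
object pixels leak into the "background" SD, the threshold scales with
nucleus density, and nuclei segment systematically larger in sparse cores
than dense ones — which shifts intensity features between cohorts. The
higher $k$ suppresses correlated background-noise patches that would
otherwise clear the object-size gate.

Declumping is shape-based: local maxima of the Gaussian-smoothed
($\sigma = 0.5$) distance transform seed a watershed with prominence
tolerance 0.35. These two values were calibrated jointly on the generator's
presets — the calibration target being exact recovery of non-touching
nuclei (no oversplitting of elongated ellipses) simultaneously with
$\ge 90\%$ recovery of nuclei whose centres sit at $0.8\times$ the sum of
radii. Objects outside 40–2,000 px² are dropped, labels are renumbered in
top-left-first order, and the whole procedure is deterministic.

Class assignment is a pure overlap rule: a nucleus is melanoma when at
least half of its pixels (inclusive) fall in the marker mask. These
mask-derived labels are the only labels the classifier ever trains on.

## The 73-feature catalogue

Each nucleus is measured on the *raw* deconvolved hematoxylin density over
its own pixels (texture families use the bounding box with out-of-object
pixels zeroed): 12 morphology, 9 intensity, 13 Haralick, 12 Gabor
(3 frequencies $\times$ 4 orientations), 16 granularity (radii 1–16) and
11 radial/edge features — 73 in total, the catalogue size the method was
designed around. Measuring on the raw rather than the sharpened channel is
deliberate: the $\sigma = 1$ detection smoothing erases precisely the
fine-grain chromatin signal (the class AUC of the radius-1–2 granularity
features drops from $\approx 0.93$ to $\approx 0.77$ on the separable
preset when measured after smoothing).

Granularity is the headline family: the spectrum
$g_i = 100\,(\Sigma O_{r_{i-1}} - \Sigma O_{r_i})/\Sigma\,\mathrm{patch}$
of mass removed between successive openings by reconstruction. Fine
chromatin loses its mass at radii 1–2; coarse texture survives longer;
$\sum_i g_i \le 100$ with equality once the radii exceed the largest
structure. The structuring element is the standard octagonal (alternating
4-/8-neighbourhood) approximation of a Euclidean disk; reconstruction is
geodesic dilation to stability. Haralick statistics use a symmetric GLCM
after per-object linear quantization to 8 levels (a small-object-safe
choice), averaged over the four unit offsets; a constant patch returns the
degenerate convention (contrast 0, ASM 1, correlation 0) with a QC flag.
Gabor kernels are DC-free so flat patches respond exactly zero. Degenerate
statistics are never NaN — they take documented conventional values and
set the per-nucleus `qc_degenerate` flag, keeping downstream selection and
classification total.

## Dataset assembly, feature selection, classification

Per-image feature tables are pooled, balanced to equal class counts by
seeded downsampling (a target-count mode reproduces near-equal balanced
sets when exact bookkeeping of an external design is wanted), and split
66.5%/33.5% stratified by class; the train/test totals match
$\mathrm{round}(0.665\,n)$ with per-stratum residual distribution. Min-max
standardization to $[0,1]$ is fitted on training rows only and applied
unchanged to every other set, so no test information leaks; zero-variance
columns map to zero and are flagged.

Feature selection ranks features by Welch two-sample $t$-test $p$-values on
a small class-stratified subsample (5% by default — testing on a subsample
avoids the foregone significance that trivial mean differences reach at
full $n$), with ties broken by $|t|$ then name for total determinism.
Backward elimination then removes features from the least significant end,
refitting a radial SVM at each step and recording internal and external
accuracies down to one feature; a least-squares cubic in feature count,
fitted to the external accuracy curve, picks the integer count maximising
the fitted polynomial (fewer than four points falls back to the empirical
argmax, flagged). Univariate ROC analysis of the selected set uses the
rank (Mann-Whitney) AUC, oriented so AUC $\ge 0.5$.

Three learners are provided: radial-kernel SVM ($C = 1$,
$\gamma = 1/p$), random forest (100 trees, seeded) and Gaussian naive
Bayes. The SVM's melanoma probability comes from a logistic (Platt-style)
calibration of its decision values fitted on the training margins. We do
not use LIBSVM's built-in probability machinery because its internal
cross-validation shuffle is not seedable from R, and the package promises
bit-reproducible training; the logistic-on-margin calibration gives the
same sigmoidal probability model deterministically. Class predictions
threshold the melanoma probability at 0.5 (inclusive). Evaluation reports
TP rate, FP rate, precision, recall, F-measure, accuracy and rank AUC with
melanoma as the positive class (a weighted-average mode mirrors
suite-style reporting), and every metric is recomputable from the stored
confusion matrix.

## Biomarker quantification

To score a nuclear proliferation marker on a new image the pipeline runs:
deconvolution, segmentation, feature extraction, melanoma classification
with the stored model (its feature subset and standardization travel with
it), nucleus-to-cell expansion, and per-cell DAB positivity. Expansion is
geodesic propagation up to 8 px, stopped where the local DAB gradient
magnitude exceeds the 75th percentile of in-ring gradients (the blocked
band is dilated by one pixel so discretization cannot leave leaks) or
where a competing cell is met; cells partition their territory and every
nucleus pixel keeps its label.

Positivity defaults to the *nuclear* mean DAB: for a nuclear antigen the
whole-cell mean dilutes the signal by the expansion area and couples the
call to expansion geometry. The whole-cell mean remains available
(`positivity_source = "cell"`) for cytoplasmic markers, and both means are
reported per cell. The default decision rule is adaptive: Otsu over the
per-cell means, accepted only when the split is decisively bimodal (gap at
least half the upper group mean — a scale-free criterion, so the ratio is
invariant to image-wide DAB rescaling); an indecisive split falls back to
an all-positive/all-negative call against a 0.1 OD floor, which handles
the all-negative and all-positive cores where Otsu would otherwise
manufacture a split. Only model-predicted melanoma cells enter the
positive ratio; an image with no melanoma cells returns an explicit
undefined-ratio flag.

## Reproducibility and problem sizes

A single pipeline seed fans out to per-stage seeds through a fixed
derivation, so balancing, splitting, ranking and forest training are
independent but jointly reproducible; rerunning a pipeline on the same
inputs gives byte-identical models. The test suite and the acceptance
script exercise the package at sizes chosen to be statistically meaningful
while staying desk-sized: fifty 128 px scenes for deconvolution closure,
a 50-nucleus core for segmentation recovery, ten 660 px cores totalling
2,000 nuclei per class (two cores held out) for the marker-guided learning
check, one hundred seeded repeats for selection recovery, and fifty
biomarker scenes spanning positive fractions 0–1 for ratio agreement.

## Known limitations

* Synthetic nuclei are smooth ellipses; real chromatin texture, nucleoli,
  overlapping 3-D tissue and cutting artefacts are absent, so real-data
  performance claims cannot be made from these tests.
* The melanin confounder is morphological (small isolated DAB-like blobs);
  true pigment has its own absorption spectrum that two-stain deconvolution
  cannot separate.
* The stain matrix is fixed calibration input; automatic stain-vector
  estimation is out of scope.
* Adaptive masking thresholds are not idempotent under re-masking (see
  above); pipelines that need strict idempotence should fix thresholds.
* The cell-expansion stop rule anchors on DAB gradients; on markers with
  no membrane/cytoplasmic contrast it reduces to a distance-limited
  Voronoi partition.
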