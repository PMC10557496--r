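---
title: "Quantified lesion grading of diabetic retinopathy: methods and design"
author: "DRgrader"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantified lesion grading of diabetic retinopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DRgrader)
```

## The problem and the model

Diabetic retinopathy (DR) is graded clinically into five levels — 0 No DR,
1 Mild, 2 Moderate, 3 Severe, 4 Proliferate — largely from the kinds and
amounts of visible retinal lesions: hemorrhages (HE), hard exudates (EX),
soft "cotton-wool" exudates (SE), microaneurysms (AN) and new vessels
elsewhere (NV).  Deep detectors can localize these lesions well, but a bare
severity score from a black-box classifier is hard for a clinician to act
on.  DRgrader implements the *explainable* half of that program: it starts
where a detector (or a human annotator) stops — typed lesion polygons in
pixel coordinates — and produces a severity grade together with the exact
threshold rule that produced it, rendered as a sentence a clinician can
check against the image.

The quantification is deliberately simple.  Each lesion instance is a
polygon; its area is the absolute shoelace value

$$S_i^t = \frac{1}{2}\,\Bigl|\sum_j \bigl(x_j\,y_{j+1} - y_j\,x_{j+1}\bigr)\Bigr|,$$

with the last vertex wrapping to the first.  Because source photographs
come at different resolutions, absolute areas are never compared; every
type's total area is normalized by the retinal area into a ratio
$T^t = \sum_i S_i^t / S$.  The retina itself is modeled as a perfect disk
whose radius is half the width of the image *after* cropping to the retina,
so $S = R^2\pi$.  This circle model is what makes vertically clipped
photographs (a common camera artifact that cuts off the top or bottom of
the fundus) commensurable with full ones: the left–right extent of the disk
survives the clipping and still determines $R$.

Nine features feed the grader: four ratios (`R_HE`, `R_EX`, `R_SE`,
`R_NV`) and five counts (`N_HE`, `N_EX`, `N_SE`, `N_AN`, `N_NV`).
Aneurysms are counted but carry no ratio — individually they are so small
that their summed area is noise.

## The rule set and its semantics

The shipped rule set (`builtinRuleSet()`, stored as versioned JSON under
`inst/extdata/`) contains nine conjunctive threshold rules over `R_SE`,
`R_HE`, `N_SE` and `N_NV`, one per leaf of the originating decision tree,
each carrying a confidence: the percentage of training images in that leaf
belonging to the leaf's majority class.  Confidences are reported verbatim
at inference time, never recomputed.

Boundary semantics are literal: `<=` is closed, `>` strict.  One rule
carries both `R_HE >= 0.052` and `R_HE > 0.171`; the first bound is
redundant but kept, because the rule is encoded exactly as stated.  The
package's audit (`auditRuleSet()`) proves by interval arithmetic over the
threshold-induced cell partition — an exact computation, since every rule is
constant on each cell — that the nine rules are pairwise mutually exclusive
and that exactly two regions of the feature domain are uncovered:

```{r audit}
auditRuleSet(builtinRuleSet())
```

The two gaps are artifacts of bracketed count ranges (`N_SE` in 1..15,
`N_NV` in 1..3) that mirror the support of the original training data.
Clinically, *more* lesions cannot mean *less* severity, so the default
fallback policy `widen_ranges` re-evaluates the rules with each bracketed
range opened to a one-sided bound (`N_SE >= 1`, `N_NV >= 1`) and flags the
result.  Two alternatives are selectable: `error` (refuse), and
`nearest_rule`, which picks the rule with the smallest total predicate
violation measured in raw feature units.  Note the unit mixing in the
latter: a count violation of 1 weighs like a ratio violation of 1 (i.e.,
100 % of the retina), so nearest_rule tends to repair ratio predicates
first.  That is intentional — count brackets encode training support, not
clinical dose–response — but it is a convention, not an estimate.

Explanations render each predicate as prose ("the ratio of soft exudate
lesions is less than or equal 18%"), join clauses with "and", and close
with the severity:

```{r explain}
res <- gradeFeatures(featureVector(R_SE = 0.10, R_HE = 0.10, N_HE = 3,
                                   N_SE = 2))
explanation(res)
```

## Re-deriving rules: the CART learner

`cartTrain()` is a from-scratch CART: binary axis-aligned splits chosen by
exhaustive scan over the midpoints of consecutive distinct feature values,
maximizing the weighted Gini decrease $\Delta = G(p) - (n_L G_L + n_R
G_R)/n$ with $G = 1 - \sum_k p_k^2$.  Design choices, all pre-pruning, no
surprises:

* exact search, no quantile subsampling — the tables here are thousands of
  rows, not millions;
* ties break deterministically toward the lowest feature index, then the
  lowest threshold, so a table plus a `cartConfig()` always yields the same
  serialized tree (the config's `seed` is recorded for provenance only; the
  search draws no random numbers);
* count features are numeric during splitting; at rule-extraction time a
  count path bounded on both sides becomes an integer range (`N_SE` in
  [1, 15]) and an upper bound below one becomes an equality (`N_SE = 0`),
  mirroring the printed rule style;
* stopping: `maxDepth` 12, `minSamplesLeaf` 1, `minImpurityDecrease` 1e-7.
  No cost-complexity pruning, surrogate splits, or missing-value handling.

`extractRules()` walks every root-to-leaf path, merges same-feature bounds,
and emits a rule per leaf with confidence $100\,\max_k n_k / \sum_k n_k$
computed on the *training* leaf counts (whether the original confidences
were training-set or cross-validated leaf fractions is not stated anywhere
we could check; training-set fractions are the documented choice here).
The suite verifies round-trip equivalence — `classify(extractRules(tree))`
equals direct tree traversal on 10^4 random probes — and checks the split
search against a brute-force enumerator on small tables and against rpart
on separable data.

## What the synthetic generator emulates — and what it does not

Real EyePACS/APTOS-style images and clinician polygons are not available to
this package, so every stage is exercised on synthetic data with the
statistical structure the grading model assumes.

`sampleFeatures()` draws vectors uniformly inside the union of a
severity's rule regions (regions equally likely), with every continuous
feature kept at least `margin` (default 0.01, in ratio units) away from
every rule threshold and integer features inside their brackets.  Support
caps not stated by the rules are fixed once: `R_SE` up to 0.45 and `R_HE`
up to 0.40 (burdens beyond roughly 40 % of the retina are outside clinical
reality and could not be packed into a disk anyway), unreferenced ratios
small (`R_EX` up to 0.08, `R_NV` up to 0.03).  Counts and ratios are
coupled — a zero count forces a zero ratio and vice versa, and counts are
drawn large enough that no single lesion exceeds 8 % of the retina.
Features the rules never reference are sampled severity-independently, so
that class information flows only through the rule features; where a rule
leaves `R_SE` free (the hemorrhage-defined moderate and severe regions),
45 % of draws carry no soft exudate at all.  That default matters: soft
exudate absence must remain a mixed stratum across classes, as it is in
real data, or a learner will split on "any soft exudate at all" before the
printed 0.18 boundary.  Uniform-in-region sampling is a declared stand-in
for unknown real class-conditional distributions, not an estimate of them.

`renderFundus()` turns a vector into an image plus ground-truth
annotation: a bright disk (with a mild radial shade and a few dark
vessel-like curves) on black, optionally clipped top or bottom, and one
simple star-convex polygon of 8–16 vertices per lesion instance.  Polygons
are packed without overlap into annular-wedge cells of the disk
(first-fit-decreasing by area per ring) and each polygon is *scaled about
its centroid to its exact requested area*, so re-quantifying the returned
annotation reproduces the requested ratios to float precision — the 2 %
round-trip tolerance in the tests is slack for degenerate cases, not a
typical error.  Count-only instances (aneurysms, or a positive count with
zero ratio) render as deliberately tiny polygons (≤ 25 px²).  Budgets that
cannot be packed raise an error; `generateDataset()` resamples such rare
extreme draws (same severity, image-local seed) before committing a row, so
images, annotations, CSV and labels always stay mutually consistent.

What the renderer does **not** emulate: photographic texture, illumination
gradients and camera artifacts beyond vertical clipping, anatomically
plausible lesion placement (lesions land where the packing puts them), the
optic disc and macula, and annotation noise — polygons are exact.  Green
tests on this data therefore demonstrate the correctness of the
*computational chain* (quantify → grade → explain → re-learn), not
detector robustness on real photographs.

## Preprocessing chain

The classical preparation steps are thin, documented wrappers over EBImage:
crop to the retina (ITU-R 601 luma, binarize at 10/255 by default, tightest
foreground bounding box; idempotent to ±1 px), bilinear resize to
1024 × 1024 (the working resolution of the grading pipeline), contrast
enhancement by CLAHE (clip limit 2, 8 × 8 tiles) applied on luminance with
chrominance preserved via the luminance gain, green-channel extraction, and
seed-reproducible augmentation (horizontal flip, rotation with black
corner fill, contrast scale about mid-gray, brightness offset, all clipped
to [0, 255]).  Zero-variance images pass through contrast enhancement
unchanged — there is no contrast to enhance, and rescaling a constant tile
would be an artifact.  No particular enhancement method is canonical for
this step; CLAHE is the standard deterministic choice for fundus imagery.

## Problem sizes and determinism

The shipped verification runs use: 5,000 vectors (1,000 per class, margin
0.01) for tree recovery with a 1,250-vector held-out set; 10^4–10^5 random
probes for rule/tree equivalence and the coverage audit; and 50 rendered
1024 × 1024 images (10 per class) for the end-to-end closure.  All
randomness flows through explicit integer seeds (`withSeed` scopes restore
the caller's RNG state), and dataset regeneration under a fixed config is
byte-identical.

## Known limitations

* Confidences are leaf fractions, not calibrated probabilities; no
  per-patient or two-eye aggregation is attempted.
* Overlapping same-type polygons double-count their intersection in the
  ratio, because the total is a naive sum over instances; merging
  overlapping annotations is annotation policy, not computation.
* Self-intersecting polygons are accepted with a warning and evaluated by
  the shoelace formula as written (signed loop sum).
* Ratios above 1 (polygon outside the circle model) warn rather than fail.
* The vessel curves in synthetic images are cosmetic; NV placement does not
  affect features.
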