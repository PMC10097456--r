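---
title: "Verifying radiomic feature patterns: models, properties and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying radiomic feature patterns: models, properties and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radformal)
```

## The method in one paragraph

radformal classifies soft-tissue sarcoma exams into "no metastases / no
recurrence" (group A) and "metastases / local recurrence" (group B) by
*verifying* a formal disease property on each exam instead of training a
statistical classifier. Five radiomic features are computed per MRI slice —
kurtosis and skewness of the masked intensity distribution, and elongation,
sphericity and mesh surface of the 2D lesion shape. Each feature value is
discretized into three equal-width levels (low / basal / up), every slice
becomes five actions `b{level}of3{feature}`, and the concatenated actions of
an exam form a sequential CCS process `a1.a2.….nil`. A modal mu-calculus
property describing the disease pattern is then model-checked on the chain:
a true verdict predicts group B. Because the semantic object is a labelled
transition system, the same machinery yields witnesses, failure notes and a
slice-level localization of where in the exam the pattern holds.

## Feature computation

**First-order features.** For the masked intensities, with $m_k$ the $k$-th
central sample moment (population $1/n$ denominators),

$$\mathrm{skewness} = m_3 / m_2^{3/2}, \qquad
  \mathrm{kurtosis} = m_4 / m_2^{2}.$$

Kurtosis is deliberately *non-excess* (a normal distribution maps to 3),
matching the convention of the major radiomics extraction libraries. Both
statistics are invariant under positive affine intensity maps, so they are
unaffected by the linear part of normalization; only the outlier clipping
below can alter them.

**Preprocessing.** `preprocess_config()` defaults to the standard settings
for fluid-sensitive MRI radiomics:

* `normalize = TRUE` — the whole slice is z-scored (mean 0, sd 1);
* `remove_outliers_sigma = 3` — normalized values beyond ±3 are *clipped*
  to ±3. Clipping (rather than excluding outlier voxels) is deterministic,
  keeps the voxel count stable, and is the interpretation we adopt for the
  "remove outliers at 3σ" convention; the alternative — dropping voxels —
  would make the first-order sample depend on the background distribution
  in an unstable way.
* `resample_spacing = c(0.6, 0.6)` mm — in-plane resampling with an
  interpolating natural cubic spline applied separably along rows and
  columns (an order-3 spline resampler; we make no attempt to reproduce any
  specific library's B-spline kernel bit-for-bit). The mask is resampled by
  nearest neighbour and re-binarized. The third resampling component is
  zero by construction: processing is strictly 2D (`force_2d`).
* `bin_count = 50` — fixed bin count for gray-level *texture* matrices.
  None of the five selected features uses gray-level binning, so the
  setting is inert here; it is kept in the configuration because run
  manifests should record the full extraction context.

**2D shape features.** The lesion contour is traced by marching squares on
the binary mask in physical coordinates: the mask is zero-padded, each 2×2
pixel neighbourhood contributes a contour segment through the midpoints of
its crossed edges, and saddle configurations are resolved as two separate
corner cuts. `mesh_surface` is the enclosed area; for a single pixel the
contour is the diamond through the four edge midpoints, so the area is
exactly $d_1 d_2 / 2$.

The *perimeter* needs one numerical decision. The raw marching-squares
polygon systematically overstates the length of smooth boundaries: a digital
straight line at angle $\theta$ is traced with length factor
$\cos\theta + (\sqrt2-1)\sin\theta$, whose average over orientations is
$8/\bigl(\pi(1+\sqrt2)\bigr) \approx 1.055$. An uncorrected perimeter would
therefore cap the sphericity of a perfect disk near $0.948$ at *any*
resolution. We multiply the raw contour length by Kulpa's classical
correction constant $\pi(1+\sqrt2)/8 \approx 0.948$, the standard
digital-geometry fix, making the estimator consistent: disk sphericity then
converges to 1 as resolution grows, and for arbitrary connected masks
sphericity stays below ≈1.03 (the marching-squares polygon is at best
octagonal, and the isoperimetric inequality bounds the raw quotient by 1).
The area is left uncorrected — it is already accurate to well under 1% for
lesions ≥10 pixels across.

With the corrected perimeter $P$ and area $A$,

$$\mathrm{sphericity} = \frac{2\sqrt{\pi A}}{P}, \qquad
  \mathrm{elongation} = \sqrt{\lambda_\text{minor} / \lambda_\text{major}},$$

the $\lambda$ being eigenvalues of the covariance of foreground pixel-centre
coordinates. A single-pixel mask has no principal axes; we define its
elongation as 1 (an isotropic point), avoiding 0/0. Disconnected masks are
treated as a union: areas and contour lengths add, and the covariance runs
over all foreground pixels — segmentations that include satellite edema
regions remain well defined.

## Discretization

`fit_bins()` computes, per feature, equal-width 3-bin edges over the
*cohort-wide* range (all slices of all patients). The alternative — fitting
per exam — would make "level 3 sphericity" mean something different in every
patient, which is incoherent when a single shared property is verified
across the cohort; cohort-wide bins are the only choice that makes the
action alphabet comparable. Conventions, all tested:

* a value equal to an interior edge goes to the *upper* bin; the maximum is
  level 3;
* values outside the fitted range (new exams scored with a stored scheme)
  are clamped into the extreme bins — a stored scheme must classify unseen
  data;
* a constant feature column is degenerate and maps everything to the basal
  level 2.

Each slice then emits five actions in the fixed order sphericity, kurtosis,
skewness, elongation, meshsurface; slices are concatenated in ascending
index order. The order matters: the property's two-step obligations (for
example "high sphericity immediately followed by low kurtosis") read
consecutive actions, so the within-slice order is part of the model's
semantics, not cosmetics.

## Models and the property language

Exams use only the sequential fragment of CCS — action prefix and `nil` —
so every model is a finite chain: $k$ actions give states $0..k$, state $i$
steps to $i+1$, and the final state is deadlocked. The state $i$ is
attributed to the slice of the action it is about to consume (the final
state to the last slice); this map is what turns satisfying state sets into
slice localizations.

The property language has `tt`/`ff`, disjunction, diamonds `<a, b>φ`
(existential over the listed actions), complement diamonds `<- a, b>φ`
(existential over every *other* action, with `<->φ` the unrestricted case),
the universal box `[-]φ` over all actions (deadlocks satisfy it vacuously,
so `[-]ff` characterizes termination), and least fixpoints `min X = φ`.
Named properties (`F0`, `F1`, …) are acyclic macros expanded bottom-up, so
each is evaluated exactly once per chain. Only least fixpoints are
implemented — the bundled property uses nothing else — and `max` is
rejected with an explicit unsupported-operator error, as are conjunction
and negation, which the dialect does not contain.

Semantics are computed by Knaster–Tarski iteration from the empty set;
on a chain the fixpoint stabilizes in at most `n_states + 1` rounds, and the
iterates grow monotonically (both properties are asserted by tests against
a brute-force oracle that re-evaluates the whole formula from scratch).
On acyclic chains the pervasive shape `min X = φ ∨ <->X` is equivalent to
"φ holds at some suffix state", which gives an independent linear-scan
oracle used throughout the test suite.

**The bundled disease property** (`sts_property_set()`) has entry point
`F0 = F1 ∨ F10`. The `F1..F4` chain demands four occurrences of the
consecutive pair (`b3of3sphericity`, `b1of3kurtosis`); the first two may be
found anywhere (`<->X` recursion), the last two restrict the recursion to
steps over actions *other than* the pair's own actions. The `F10..F14`
chain describes repeated sphericity/kurtosis/mesh-or-elongation triples
ending in a basal meshsurface or elongation action followed by termination.
A structural consequence worth documenting: with the fixed within-slice
action order, the third step of each `F10..F13` triple requires a
meshsurface or elongation action *immediately after* a kurtosis action —
a position always occupied by a skewness action — so on well-formed
five-feature chains the `F10` branch is unsatisfiable and `F0` reduces to
`F1`. The checker stays fully general (the property is verified as
written, and a property test pins down the unsatisfiability); only the
synthetic generator exploits the fact, implanting the `F1` pattern.

**Verdict artifacts.** For a true verdict the checker reconstructs a
witness by walking the satisfied diamond obligations forward from the
initial state; on a chain this is a prefix of the exam's own action list.
For a false verdict the failure note names the sub-property that is deepest
in the macro chain while still satisfied somewhere, and the slice where its
satisfaction stops — a pragmatic notion of "how far the obligations got"
(the property language itself offers no canonical counterexample format for
eventually-style formulas). `localize()` reports, per property, the slices
owning at least one satisfying state.

## Classification metrics

Group B is the positive class. From the confusion matrix, sensitivity,
specificity, accuracy, PPV and NPV are computed with zero denominators
yielding `NA` (undefined) rather than errors. The clinical utility indices
are $\mathrm{CUI}^+ = \mathrm{Se} \times \mathrm{PPV}$ and
$\mathrm{CUI}^- = \mathrm{Sp} \times \mathrm{NPV}$, graded
excellent (≥0.81), good (≥0.64), satisfactory/fair (≥0.49), poor (<0.49),
very poor (≤0.36). As conventionally stated, the last two bands overlap on
$(0.36, 0.49)$; we resolve by band order — very poor iff ≤0.36, otherwise
poor — which keeps the grade monotone in the index (tested on a grid).
Display rounding is half-up to 2 decimals (3 for CUI); raw values are kept
alongside. Feature intercorrelation uses Spearman's rank correlation with
average ranks for ties, via `stats::cor`.

## The synthetic cohort generator

There is no bundled clinical dataset; the generator defines the study
conditions the package is evaluated under.

*Sequence mode* draws, per patient, a 5 × n\_slices level matrix uniform on
{1,2,3}, with n\_slices uniform on 5–20 (a plausible slice count for
extremity MRI; satisfier draws are floored at 4 slices, the minimum the
pattern needs). Defaults are 21 group-A and 26 group-B patients with
pattern-carrier probabilities 7/21 and 21/26 — the group sizes and
classification proportions of the published cohort. Carriers get the
pattern implanted as four *consecutive* (sphericity 3, kurtosis 1) slices:
consecutiveness guarantees the restricted recursion of the last two
obligations is respected, because the intervening actions are skewness /
elongation / meshsurface actions that the exclusion sets never name.
Non-carriers are redrawn (rejection sampling against the checker itself,
bounded at 1000 attempts) until their chain fails the property — the
property's negation has no tractable closed form, and rejection keeps the
conditional distribution honest. Ground-truth flags therefore agree with
the checker's verdict for every patient by construction, which is what lets
fixed carrier counts (`fixed_counts = TRUE`, giving exactly
`round(p*n)` carriers) reproduce a prescribed confusion matrix identically.

*Image mode* draws elliptical lesions — area uniform on 60–400 mm², axis
ratio on 0.4–1, random orientation — filled with gamma-distributed
intensities (shape 2–10, scale 20, location 100) on a Gaussian background
(sd 5) in a 64×64 frame at 0.8 mm spacing, resampled to 0.6 mm by the
standard preprocessing. The knobs drive the features monotonically (area →
mesh surface, axis ratio → elongation/sphericity, gamma shape → skewness/
kurtosis), which is what the end-to-end tests assert. Image mode does *not*
attempt the inverse problem of realizing a prescribed discretized pattern
through images, and it does not model MRI texture, scanner heterogeneity,
bias fields or partial-volume effects — so passing image-mode tests shows
the plumbing and the monotone physics are right, not that clinical
performance would transfer.

## Problem sizes and numerical tolerances

The test suite compares the checker with the brute-force oracle on 1000
random chains of up to 40 states with formulas of modal depth up to 4, plus
150 well-formed action chains against the suffix-scan oracle; the
acceptance script re-runs a 400-case agreement sample. The metric panel is
recomputed on the 47-patient fixed-count cohort and on a tenfold (470
patient) cohort with sampled carrier flags, whose observed sensitivity and
specificity are required to sit within three binomial standard errors of
their rates. Shape analytics use disks of radius 10–25 pixels at 0.6 mm
spacing (area within 5% of $\pi r^2$, sphericity and elongation within 5%
of 1) and the exact single-pixel half-cell identity. Monte-Carlo moments
use $10^5$ normal draws with tolerance 0.05 on kurtosis.

## Known limitations

* The perimeter correction is calibrated for smooth, isotropically oriented
  boundaries; for deliberately axis-aligned rectangles it *under*-states
  the true perimeter by up to ~5%, inflating their sphericity accordingly
  (still bounded below ~1.03).
* Discretization uses cohort-wide min/max, so a single extreme slice
  stretches every bin; robust quantile-based bounds would change the action
  alphabet and are out of scope.
* The checker is specialized to finite LTSs and least fixpoints; general
  CCS (choice, parallel composition) and greatest fixpoints are rejected,
  not silently misread.
* Sequence-mode synthesis draws levels independently across slices and
  features; real exams have strong between-slice autocorrelation, so
  rejection-sampling acceptance rates observed here say nothing about the
  prevalence of the pattern in clinical data.
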