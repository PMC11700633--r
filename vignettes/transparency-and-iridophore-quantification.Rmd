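---
title: "Calibrated transparency, iridophore coverage, and exact nonparametric inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated transparency, iridophore coverage, and exact nonparametric inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iridoquant)
```

## The measurement problem

Sexual dimorphism in mouthbrooding fish shows up as a difference in how
much light the floor of the lower jaw transmits: the male jaw is occupied
by reflective iridophores and is markedly less transparent. Turning that
observation into numbers requires two image-derived measures and a
statistics layer matched to very small group sizes (5–11 animals per
group). This vignette documents the models behind each step, the tunable
parameters, the numerical conventions, and what the synthetic validation
does and does not establish.

## Calibrated transparency

A transparency measurement uses two transmitted-light acquisitions on the
same optical setup: a blank **control** image $C$ of the dish, and a
**sample** image $S$ with the tissue in place. Per-pixel transparency in
percent is

$$T(x, y) = 100 \cdot \frac{S(x, y)}{C(x, y)} \cdot f,$$

where $f$ is a calibration factor correcting the slight difference in
overall light intensity between the two acquisitions. Two sample-free
*peripheral areas* $P_1, P_2$ appear in both images; for each area the
ratio of mean control to mean sample intensity is computed, and

$$f = \tfrac{1}{2}\left(\frac{\overline{C}_{P_1}}{\overline{S}_{P_1}} +
\frac{\overline{C}_{P_2}}{\overline{S}_{P_2}}\right).$$

If either image is rescaled by a global gain $c > 0$ (different lamp
output, different exposure), $f$ picks up the factor $1/c$ and the map is
unchanged — an exact algebraic cancellation the test suite verifies to
better than $10^{-6}$ relative. The cancellation holds only below sensor
saturation; clipped pixels break the linearity it relies on, as on any
real camera.

Two conventions here were genuinely open and deserve a note:

- **Mean of area ratios vs ratio of pooled means.** Averaging the two
  area-level ratios (the default, `method = "area_ratios"`) and dividing
  pooled mean intensities (`method = "ratio_of_means"`) coincide when both
  areas are equally bright and sized, and differ slightly otherwise. Both
  are provided; the default follows the "average ratio of the two areas"
  reading, which weights both areas equally regardless of their size.
- **Per-pixel first, aggregate second.** The map is computed per pixel and
  then aggregated over the measurement ROI (mean by default, median
  selectable). Computing a single ratio of region means instead would
  weight pixels by control brightness; the per-pixel route is the primary
  definition and the one validated against ground truth.

Degenerate inputs follow one rule: pixels with zero control intensity are
*undefined* (`NA`) and excluded from every aggregate. Substituting 0 or
100 there would bias group comparisons in opposite directions; exclusion
biases neither. Transparency above 100% (specular highlights, noise) is
retained by default — clipping is available (`clip = TRUE`) but silently
shrinks group differences, so it is off.

## Iridophore area fraction

Iridophores reflect incident light, so under reflected-light illumination
they are bright against a dark background. Segmentation is deliberately
minimal: within the measurement ROI, a pixel is iridophore iff its
intensity is **strictly greater** than a threshold, and the area fraction
is $100 \cdot n_{\mathrm{irido}} / n_{\mathrm{ROI}}$. The threshold is a
required analysis parameter expressed as a fraction of the dynamic range
(default 0.5 for synthetic scenes, i.e. 32767.5 counts at 16 bits); no
automatic threshold learning is attempted. Raising the threshold can never
increase the fraction — a monotonicity property the tests check — so
sensitivity analyses over the threshold are well behaved.

## The synthetic-scene generator

Real jaw photographs are not redistributable inputs for a test suite, so
validation runs on rendered scenes with planted ground truth. The forward
model is:

- a smooth illumination field $L$ (linear ramp by default, radial
  selectable; base 0.7 of dynamic range, relative amplitude 0.1) shared
  *exactly* by the control and sample exposures of one scene, with
  optional per-image global gains to exercise the calibration;
- a transmittance field equal to the group's `tissue_transmittance` inside
  the measurement region and 1 outside, so
  `sample = gain · L · transmittance`;
- iridophore disks in the reflected modality (reflectance 0.9 over
  background 0.1), placed inside the measurement rectangle and therefore
  never touching the peripheral areas;
- additive Gaussian noise, SD `noise_sd` of the dynamic range (default
  0.01), clipped to the sensor range.

Rendered intensities stay continuous (doubles on the counts scale);
quantization to integers happens only when a scene is written to TIFF.
This keeps the noise-free forward-model identity exact to floating point —
the pipeline recovers planted transmittance × 100 to $10^{-6}$ — while
file round-trips remain lossless for integer-valued images.

**Anti-aliasing and truth consistency.** Disk edges are anti-aliased with
a linear signed-distance ramp one pixel wide: coverage
$\mathrm{clamp}(r - d + \tfrac12,\, 0,\, 1)$ for a pixel centre at
distance $d$ from a disk of radius $r$. The planted truth mask is the
centre-in-disk rule $d < r$. These two choices are deliberately matched:
coverage exceeds ½ exactly when the centre is inside, so with the default
threshold midway between background and blob reflectance, noise-free
segmentation reproduces the truth mask pixel for pixel. An area-exact
coverage model would disagree with any pixel-level truth mask on boundary
pixels and make "exact recovery" unattainable by construction. At
`noise_sd = 0.01` only pixels in the one-pixel edge band can flip, which
keeps the measured fraction within ~0.1 percentage point of truth in the
default geometry (tolerance 1 point in the tests).

Default study conditions mirror the dimorphism design: groups of 5, female
transmittance 0.9 with no iridophores, male transmittance 0.3 with ~25%
coverage (14 disks of radius 4–5.5 px in a 58 × 58 px measurement region
of a 96 × 96 scene). Where the source protocol does not state a value —
camera noise, illumination geometry, ROI shapes — the generator uses the
conventions above as fixed, documented choices, not estimates.

What passing on synthetic scenes shows: the arithmetic, calibration,
conventions and inference are correct against known truth. What it does
not show: robustness to focus drift, uneven tissue thickness, specular
structures, or misplaced ROIs in real photographs; those failure modes are
not in the forward model.

## Exact nonparametric tests

Group sizes of 5–11 make asymptotic p-values questionable and make the
*attainable* significance levels a design property worth computing. Both
Wilcoxon tests therefore default to permutation-exact p-values:

- **Rank-sum.** The pooled data are mid-ranked (ties get average ranks);
  the null distribution of the rank-sum $W$ of the first group is the
  distribution over all $\binom{m+n}{n}$ assignments of those mid-ranks,
  which remains exact under ties. Rather than materializing assignments,
  the implementation counts subsets by sum with a dynamic program over
  doubled mid-ranks (always integers). Two-sided p doubles the smaller
  tail, capped at 1.
- **Signed-rank.** Zero differences are dropped before ranking
  (Wilcoxon's convention; a `"fail"` policy is available since the choice
  is not universal), tied magnitudes get mid-ranks, and the null
  enumerates all $2^n$ sign patterns the same way.
- **Auto mode.** Exact enumeration is used while the number of
  arrangements is at most $2 \times 10^6$; beyond that the tie-corrected
  normal approximation (optional continuity correction) takes over.

Two design facts fall out of exactness and are asserted in the acceptance
tests: a 5-vs-5 rank-sum comparison can reach at best $p = 2/252 \approx
0.0079$, so complete separation is enough for `**` (p < 0.01); seven
signed-rank pairs reach at best $2/128 = 0.015625$, so `*` is attainable
but `**` never is in that design.

- **Steel–Dwass.** For each of the $k(k-1)/2$ group pairs, the pair is
  ranked jointly, the rank-sum is standardized by its tie-corrected null
  mean and variance to $z$, and $q = |z|\sqrt{2}$ is referred to the
  studentized-range distribution with $k$ groups and infinite degrees of
  freedom. This is the standard large-sample reference for the procedure;
  no exact small-sample tables are used, and no continuity correction is
  applied (reference implementations differ here and the original
  software's behaviour is undocumented — at $k = 2$ the procedure then
  reduces exactly to the two-sided normal-approximation rank-sum test,
  which the tests verify to $10^{-9}$). Monte-Carlo calibration at group
  sizes (6, 10, 11) puts the family-wise type-I error near 0.04 at
  $\alpha = 0.05$ — slightly conservative, as expected for a rank
  procedure at these sizes.
- **Letters and markers.** Compact letter displays use insert-and-absorb:
  start from one column holding all groups, split every column containing
  a significantly different pair, absorb columns that become subsets. The
  invariant — two groups share a letter iff not significantly different —
  is property-tested against a brute-force checker on random significance
  patterns. Letters are ordered by group medians (highest median gets
  "a"), matching how group summaries are reported (medians, not means).
  Markers use strict cutoffs: `**` for p < 0.01, `*` for 0.01 ≤ p < 0.05,
  `N.S.` otherwise.

## Ancillary rules

- `gsi()` returns the gonad-somatic index as a percentage
  (100 · gonad / body weight); the percent scale is the common convention
  and the only scale ambiguity in the source measure.
- `filter_degs()` applies the differential-expression rule with strict
  inequalities — FDR < 0.05 **and** |log2FC| > 1 — and annotates direction
  by the sign of the fold change. Boundary rows (FDR = 0.05, log2FC = 1)
  are excluded on purpose.

## Problem sizes and reproducibility

The test suite and the acceptance script run at deliberately modest sizes
chosen as sufficient for their purpose: 96 × 96 px scenes (the identities
being checked are resolution-independent), exact-test oracle grids up to
$m, n \le 8$ and $n \le 12$ (full brute-force enumeration stays cheap
there while covering all tie structures), 2000 Monte-Carlo replicates for
family-wise error (standard error ≈ 0.005 at $\alpha = 0.05$), and 200
random patterns for the letter-display property. Every stochastic step is
seeded: scenes derive per-subject seeds from a master seed, so cohorts,
files and downstream statistics reproduce bit-identically.

## Known limitations

- ROI geometry is rectangles-by-default and polygon-by-file; freehand ROI
  drawing is out of scope.
- The generator does not model depth-dependent scattering, birefringence,
  vignetting beyond the smooth field, or spatially correlated noise.
- The Steel–Dwass reference is asymptotic; at $n \le 3$ per group its
  p-values are coarse (the seasonal March groups, n = 3, were excluded
  from testing in the motivating design for exactly this reason).
- The DEG filter is the final selection rule only; upstream expression
  quantification and normalization are explicitly out of scope.
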