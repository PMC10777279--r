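---
title: "Methods: simulating and analysing crowdsourced skin demarcations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing crowdsourced skin demarcations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crowdmark` analyses crowd-consensus demarcation studies of affected skin,
of the kind used to estimate cutaneous cGVHD surface-area involvement from
patient photographs. This vignette documents the model behind the
synthetic-data generator, the analysis procedures, the numerical choices,
and what a green test suite does and does not establish.

## Study structure

A study consists of stereo *photos*, each projected into several 2D
*views* ("0_0" is the original camera angle; the others are combinations
of ±15° rotations about two axes). Photos are split into a
**ground-truth-provided** set — whose expert demarcation may be shown to
raters as feedback and on which rater reliability is scored — and a
**ground-truth-withheld** set, the evaluation set whose expert answer is
never released. Raters belong to a **high-feedback** arm (expert answer
revealed on 1 of every 4 of their provided-set submissions) or a
**low-feedback** arm (1 of every 14). Analyses run on the withheld views
with affected skin; four crowd definitions are built per image: first 17
arrivals of each arm, first 32 of the low arm, and the low arm's top-5
raters by reliability.

## The synthetic generator

No patient photographs are public, so every analysis stage is exercised
against a generator that reproduces the *statistical structure* of the
study rather than its appearance.

**Geometry.** The skin region of a photo is a radially wobbled ellipse
covering roughly two thirds of the frame (always more than half, and
always connected). Affected regions are smooth random blobs inside the
skin; their radii are iteratively rescaled after clipping so the total
affected area lands within ±30% of the configured coverage target.
Views are small rigid transforms (rotation ≤ 10°, integer shift ≤ 2 px by
default) applied jointly to the skin and ground-truth masks — a 2D
stand-in for 3D reprojection that preserves what the analyses rely on:
several correlated views of the same skin. A view that would push more
than 5% of skin pixels out of frame is an error.

**Rater noise model.** The study's raters are humans tracing outlines on
a phone screen; the generator's skill model is necessarily invented, and
each parameter is config-exposed:

| parameter | units | default | role |
|---|---|---|---|
| `boundary_jitter_sigma` | px | lognormal, median 2 | node placement noise; coarse touch-screen tracing |
| `region_detection_prob` | — | ≈ 0.9 | chance a lesion is noticed at all |
| `false_positive_rate` | regions/image | 0.1 | spurious marked blobs |
| `node_budget` | nodes/polygon | 12–40 | outline fidelity limit of the interface |
| `shared_bias_sigma` | % of skin area | 3 | per-(view, region) border mis-reading common to all raters |

A demarcation is simulated by tracing each detected ground-truth region's
boundary, resampling it to the node budget, applying the shared bias as a
radial rescale about the region centroid, jittering every node, adding
Poisson false-positive blobs, rasterizing, and clipping to the skin mask.

**Why a shared bias term.** With independent zero-mean jitter alone, the
plurality consensus is a noise-averaging estimator, so its residual error
is proportional to the raters' dispersion divided by √r — i.e.
disagreement would *mechanically* predict consensus error, the opposite of
what crowd studies of this task observe. What voting cannot remove is the
component of error shared by raters: everyone reading an ambiguous border
the same (wrong) way, producing consensus masks with confident sharp edges
that still miss subtle surface change. The generator therefore draws one
border offset per (view, region), common to all raters. It is
parameterized in percentage points of skin area, not pixels, encoding the
assumption that interpretation difficulty depends on a lesion's
appearance, not its size; a pixel-scaled bias would covary with lesion
perimeter exactly like jitter does and would re-couple disagreement to
error through photo geometry. Its default SD (3 pp) makes the systematic
component dominate the √r-attenuated jitter residual for desk-scale
crowds, the regime the real study operates in.

**Feedback.** Exposure is logged (every 4th / 14th provided-set
submission per rater, in the rater's own chronological order) but by
default does not alter skill: reported learning effects in this task are
absent, and a time-constant model is the appropriate null. A
`skill_drift` knob linearly scales jitter over a rater's submission stream
to exercise the learning-curve machinery, and `jitter_multiplier` per arm
can emulate a between-arm skill gap.

**Determinism.** One master seed governs a run. Every demarcation's RNG
stream is derived by hashing (seed, rater id, image id) — and the shared
bias by hashing (image id, region, seed) — so any single demarcation can
be regenerated in isolation, independent of iteration order, and exports
are byte-identical across reruns.

## Consensus and metrics

Votes are counted per pixel; the consensus contains pixels marked by at
least half the crowd, *inclusive* at exactly 50% (relevant for even
crowds, e.g. 2 votes of 4). The threshold is config-exposed
(`consensus_threshold`) for sensitivity analyses; 0.5 is the
study-faithful value and numeric comparison uses a 10⁻⁹ tolerance so the
50% boundary is never lost to floating-point error.

Dice is `2|A∩B|/(|A|+|B|)`, with the empty-vs-empty case defined as 1
(agreement on absence) and empty-vs-non-empty as 0; the evaluation scope
only contains affected images, so this convention affects edge fixtures
only. Surface-area fractions are percentages of the *skin* mask, not the
frame, which keeps the error in the units clinicians use. SAE is the
absolute difference of those fractions — a pure area metric, blind to
location, which is exactly why both metrics are reported together.

### Rasterization

Demarcations are polygon node loops in continuous 0-based (row, col)
coordinates; a pixel belongs to a polygon when its centre (r+0.5, c+0.5)
is inside under the **nonzero-winding** rule. Winding (rather than
even-odd parity) is deliberate: a flat list of loops must both *union*
independently drawn overlapping outlines and *preserve holes* when masks
are round-tripped through polygon export. With oriented loops — boundary
tracing emits outer boundaries and hole boundaries with opposite
orientations — winding does both; no flat-loop even-odd rule can. For
simple non-overlapping loops the two rules agree, and an even-odd mode is
kept for cross-checks. Mask → polygons → mask round trips are exact
because traced vertices sit on the integer corner grid while pixel
centres sit at half-integers, so no crossing test ever ties.

## Reliability, selection, learning

Rater reliability is the mean of a chosen metric over the rater's
demarcations of ground-truth-provided images. Which metric ranked "best
performers" in the original study is unknown; the package defaults to
mean Dice (`ranking_metric = "mean_dice"`), with mean SAE as the
alternative, and asserts nothing about which the study used. Ranking is
computed once per rater globally and applied per image to the raters
available there — the per-image aspect is availability, not re-scoring.
Unscored raters are eligible but rank last (excluding them could make
images un-assemblable); ties break by earlier enrollment.

Learning curves track each rater's error over their first `horizon`
(default 100) affected withheld images in their own submission order,
averaged in windows of 20. Raters short of the horizon are excluded.

## Study-level analyses

Crowd summaries report medians, type-7 (linearly interpolated) quartiles
and means — stated because box-plot quantile conventions differ. The
Mann-Whitney comparison uses midranks; for combined n ≤ 12 the two-sided
p-value is exact by full enumeration of group labelings (ties handled
exactly; p = 2·min(P(U ≤ u), P(U ≥ u)) capped at 1), above that a normal
approximation with tie-corrected variance and no continuity correction.
The switch point balances fidelity and runtime; any realistic image count
uses the approximation.

For the variability-vs-error analysis, each photo contributes x = the
raters' surface-area-estimate SD and y = the consensus SAE reduced over
the photo's views. Two reductions the source material leaves open are
config-exposed with these defaults:

* `photo_reduction = "median"` over views for y (robust to single-view
  outliers; mean available).
* `sd_pooling = "per_view_mean"` for x: the within-view rater SD,
  averaged over views. The pooled alternative (one SD across all
  fractions of the photo) absorbs *between-view* systematic differences
  into x; since y is built from the same per-view deviations, pooling
  makes the two axes share sampling noise and manufactures correlation
  even for a homogeneous crowd. Within-view SD is the clean measure of
  inter-rater disagreement, so it is the default; `"pooled"` remains
  available for sensitivity analysis.

## What a green suite establishes — and what it does not

The acceptance tests verify: the metric definitions on worked examples;
the study's image-count arithmetic (3000 views, 711 withheld affected)
from the full-geometry config; exact agreement of consensus and metrics
with brute-force per-pixel oracles; that top-5 selection recovers planted
reliable raters and that the top-5 consensus does not trail the first-17
consensus; that a homogeneous crowd shows no variability-error
correlation; that time-constant skill yields flat learning curves; and
that exact Mann-Whitney p-values match enumeration. All of this is
computed on synthetic data. The generator does not model photographic
appearance, skin-tone diversity, rater recruitment or drop-out, the
app's gamification, or 3D surface geometry; the original study's
headline numbers (median Dice ≈ 0.7–0.8, SAE ≈ 9–11%, between-arm
p-values) depend on real human raters and are *not* reproduction targets
— only their qualitative orderings are asserted.

## Limitations

* Views are rigid 2D transforms; real reprojections change occlusion and
  foreshortening, so between-view variation is likely understated.
* The skill model is parametric and stationary; real raters mix
  strategies and attention levels within a session.
* Desk-scale defaults (64×64 px, a handful of photos) are chosen for
  test-time tractability; the full 3000-image geometry is generated for
  structural checks only, without demarcations.
* The qualification step by which the app admitted raters after training
  is unreported and not modelled.
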