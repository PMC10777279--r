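# crowdmark

Consensus analysis of crowdsourced skin demarcations.

Assessing cutaneous chronic graft-versus-host disease (cGVHD) relies on
estimating how much body surface area is affected, yet expert visual
assessment is both scarce and unreliable, and collecting expert
demarcations at the scale needed to train automated segmentation models is
expensive. One practical alternative is to let a crowd of untrained raters
outline the affected skin in photographs and fuse their submissions into a
consensus demarcation. `crowdmark` is an R package for designing and
analysing such studies: it simulates a full crowd study with
heterogeneous-skill raters, builds plurality-vote consensus masks for
several crowd definitions, scores them against expert ground truth, and
runs the reliability, variability and learning analyses such a study
needs. Its intended users are researchers in medical image analysis who
want a tested, reproducible harness for crowd-consensus methodology.

## The statistics at the core

For binary masks on a pixel grid (`TRUE` = affected):

* **Plurality-vote consensus.** Given demarcations *M₁ … Mᵣ* of one image,
  each pixel is labelled with the number of raters who marked it; the
  consensus mask is `{p : #votes(p) / r ≥ 0.5}` (pixels at exactly 50% are
  included).
* **Dice coefficient.** `Dice(A, B) = 2|A∩B| / (|A| + |B|)`; 0 = no
  overlap, 1 = identical.
* **Surface area error (SAE).** With skin mask *S*, prediction *P* and
  ground truth *G*: `SAE = | 100·|P|/|S| − 100·|G|/|S| |` percentage points
  of skin area. If the truth covers 10% of the skin and the crowd marks
  25%, the SAE is 15. SAE deliberately ignores *where* pixels are marked;
  it is paired with Dice for that reason.
* **Crowd definitions.** First-*r* arrivals from a feedback arm (r = 17 or
  32), or the per-image top-5 raters ranked by their mean score on the
  ground-truth-provided image set.
* **Study-level analyses.** Mann-Whitney U crowd comparisons (exact by
  enumeration for small samples, tie-corrected normal approximation
  otherwise); per-photo spread of the error across the 9 projected views
  of each stereo photo; and an OLS regression of per-photo consensus error
  on the per-photo SD of individual raters' area estimates, whose R²
  answers whether disagreement predicts consensus accuracy.

The simulator emulates the study design end to end: stereo "photos"
projected to multiple 2D views, a ground-truth-provided (training
feedback) versus ground-truth-withheld (evaluation) split, two feedback
arms with exposure rates 1/4 and 1/14, and raters who trace node-bounded
polygons with boundary jitter, imperfect region detection, spurious
regions, and a shared per-view border-ambiguity bias. See the methods
vignette (`vignettes/crowd-demarcation-methods.Rmd`) for the model and its
assumptions.

## Worked example

```r
library(crowdmark)

cfg <- study_config(
  height = 48, width = 48,
  gt_provided = list(affected_photos = 4, unaffected_photos = 1, n_views = 3),
  gt_withheld = list(affected_photos = 4, unaffected_photos = 1, n_views = 3),
  arms = list(
    high_feedback = list(n_raters = 12, feedback_rate = 1/4,
                         demarcations_per_image = 9, skill = skill_distribution()),
    low_feedback  = list(n_raters = 12, feedback_rate = 1/14,
                         demarcations_per_image = 9, skill = skill_distribution())
  ),
  crowds = list(
    high_r9  = crowd_spec("high_r9", "high_feedback", first_r = 9),
    low_r9   = crowd_spec("low_r9", "low_feedback", first_r = 9),
    low_top5 = crowd_spec("low_top5", "low_feedback", top_k = 5)
  )
)
ds <- simulate_study(cfg, seed = 42)
ds
#> <study_dataset> 30 images (10 photos), 24 raters, 540 demarcations

res <- run_study(ds)
res$summary[, c("crowd_name", "n_images", "median_dice", "median_sae", "mean_sae")]
#>   crowd_name n_images median_dice median_sae mean_sae
#> 1    high_r9       12       0.666       1.43     2.44
#> 2     low_r9       12       0.675       1.71     2.84
#> 3   low_top5       12       0.678       1.88     2.62
```

The summary rows are per-crowd medians/means of Dice and SAE over the 12
evaluation images (ground-truth-withheld views with affected skin): here
all three crowds of identically-distributed raters perform alike, as they
should. `res$comparisons` holds the pairwise Mann-Whitney tests (all
non-significant in this example, e.g. p = 0.95 for high_r9 vs low_top5 on
SAE), `res$photo_spread` the per-photo view ranges, and `res$regression`
the variability-vs-error fits (with only 4 affected evaluation photos the
R² of those fits is noise; the acceptance suite uses 40 photos).

A scaled-down study is simulated above; a config with the original
geometry — 120 training photos at 7 views plus 240 evaluation photos at 9
views, i.e. 3000 2D images of which 711 are withheld affected views — is
available as `study_config(preset = "study")`.

The same pipeline runs from the shell against directories of PNG masks and
CSV tables:

```sh
Rscript inst/cli/crowdmark.R simulate  --config cfg.json --out data/ --seed 42
Rscript inst/cli/crowdmark.R run-study --data data/ --out results/
Rscript inst/cli/crowdmark.R report    --results results/ --out figs/
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the defining
checks of the two agreement metrics — the worked surface-area-error
example (10% truth vs 25% prediction on a 1000-pixel skin) and the Dice
values for identical and for disjoint non-empty masks on simulated lesion
geometry — and writes them as JSON keyed by target id.
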