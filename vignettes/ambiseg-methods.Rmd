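---
title: "ambiseg: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ambiseg: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambiseg)
```

`ambiseg` covers the model-agnostic layers of a segmentation workflow for
ambiguous bioimages: consensus annotation, ensemble fusion, uncertainty
quantification, instance evaluation, and uncertainty-driven quality
assurance. This vignette documents the underlying models, the parameters a
user may want to touch, the numerical decisions baked into the code, and
what the synthetic test bed does and does not demonstrate.

## Conventions

Label masks are integer matrices with values `0..K-1`; class 0 is always
background. (File formats that store 1-based class labels should be shifted
on import; with 0-based labels the foreground predicate is simply
`label > 0`.) Probability maps are `H x W x K` arrays whose per-pixel class
probabilities sum to one within `1e-6`; readers renormalise deviations up to
`1e-3` and refuse anything larger, on the argument that small drift is
storage precision while large drift is a broken exporter. Pixels are indexed
row-major from the top-left.

## Consensus ground truth

`majority_vote()` assigns each pixel the class chosen by most raters, with
ties going to the lowest class index. Since background is class 0, the tie
rule is deliberately conservative: disputed pixels fall back to background
rather than to an arbitrary foreground class.

`staple_binary()` implements the classical two-class EM with a latent true
segmentation `Ti ∈ {0,1}` and per-rater sensitivity/specificity. The E-step
computes the posterior foreground weight per pixel from the current
parameters and a foreground prior; the M-step re-estimates each rater's
`(p_r, q_r)` from the posterior weights. Numerical choices:

* **Initialisation** `p_r = q_r = 0.99`. Starting near-perfect raters makes
  the first consensus close to a strict vote and is the standard, stable
  choice.
* **Convergence** when the largest absolute parameter change drops below
  `tol = 1e-7`, capped at `max_iter = 200`. `max_iter = 0` exposes the
  single E-step at the initial parameters, which the test suite uses to
  verify that the posterior is monotone in the prior.
* **Likelihood monotonicity.** The observed-data log-likelihood is recorded
  every iteration and asserted non-decreasing on every test run; a decrease
  would indicate an implementation error in either step.
* **Parameter clipping** to `[1e-7, 1 - 1e-7]` keeps the E-step finite when
  a rater agrees perfectly with the consensus.

### The foreground prior

The prior was a genuinely open design point. A per-pixel prior equal to the
mean of the rater foreground indicators ("rater-mean") looks natural but
re-uses the same votes that already enter the likelihood. On sparse images
(foreground a few percent of pixels, as in nuclei or soma stains) this
double counting has a failure mode the test suite reproduces: wherever two
or more raters false-positive on the same pixel, prior and likelihood
reinforce each other, the pixel enters the consensus, the sensitivity
estimates drop, misses become cheap, and the consensus inflates further.
The default is therefore `prior = "consensus"`: a scalar global prevalence
taken from the majority-vote consensus, which anchors the EM without
feeding the per-pixel votes back into it. `"rater-mean"` and explicit
scalar priors remain available. With the default, the suite checks that
five simulated raters with sensitivity 0.90 and specificity 0.95 on a
256 x 256 scene are recovered with mean absolute error at most 0.02 over
ten seeds.

### Multiclass masks

`staple_multiclass()` runs one binary STAPLE per foreground class (class
vs rest) and assigns each pixel the class with the highest posterior among
those reaching 0.5. When no class reaches 0.5 the pixel is a *background
decision* — the "rest" side won every one-vs-rest round — which makes the
K = 2 case reduce exactly to `staple_binary()`. A pixel is **undecided**
only when the best posterior is exactly tied between foreground classes
(this occurs in practice with few raters and symmetric disagreement).
Undecided pixels are resolved by copying the label of the rater with the
highest score; when no scores are supplied, each rater's macro Dice against
the pre-tie-break consensus is used. No automatic correction of
biologically implausible consensus regions is attempted; the undecided
count is surfaced in reports so such regions can be reviewed manually.

## Ensemble fusion and tiled inference

The fused prediction is the uniform mixture over all `M x T` member maps;
the label map is the per-pixel argmax with ties to the lowest class index
(again background-favouring, and deterministic). The four test-time views
are the self-inverse dihedral elements {identity, hflip, vflip, rot180}:
a four-element set of rotations and flips that remains valid for
non-square tiles, and whose involution property makes the
apply/invert geometry trivially exact.

Large images are processed as overlapping tiles (default `512 x 512`,
overlap 0.5) stitched with a separable Gaussian importance weight,
`sigma = dim/8` per axis. Border predictions are less reliable, so tiles
contribute most near their centres. The sampled weight map is normalised by
its maximum, which makes the invariant "peak weight = 1" hold for even tile
sizes too (where no pixel sits exactly at the continuous centre); weights
are floored at `1e-8` so accumulated weights never vanish. Images smaller
than a tile are symmetric-reflection padded; the final row/column of tiles
is shifted inward so windows never leave the image. Whether the Gaussian
weighting is applied before or after view inversion is immaterial for
self-inverse views; it is applied per tile before inversion.

## Uncertainty decomposition

For each class `k` the per-pixel predictive variance over the `M x T`
members is computed as

```
epistemic_k = mean(p - p^2)         aleatoric_k = mean((p - p_bar_k)^2)
```

where `p_bar_k` is the fused mixture probability (not a per-view mean — the
reference of the deviation term is the quantity the pipeline actually
reports). Their sum telescopes to `p_bar (1 - p_bar)` and is therefore
bounded by 0.25 for any admissible ensemble; the aggregate over classes is
scaled by `zeta / K` with default `zeta = 4`, which puts the binary
per-pixel ceiling at exactly 1. Both ceilings are verified by a grid search
over member configurations plus the analytic worst cases (half the members
fully confident in each class; all members at 0.5), in the test suite and
in `scripts/acceptance.R`. The naming of the two terms follows the
moment-based decomposition used with deep ensembles for segmentation; note
that for `K > 2` the aggregation is a pragmatic average rather than the
full general formulation.

The image-level score `U` averages the aggregated map over the predicted
foreground, pixels with `label > 0`. An all-background prediction would
leave `U` undefined; the implementation falls back to the global mean and
attaches a `no_foreground` flag, and the QA step always includes flagged
records in the review list. Silence seemed the only wrong option here.

## Instances and evaluation

Instance derivation replaces learned flow-field post-processing with a
fully specified procedure: per-class connected components (default
8-connectivity), optionally subdivided by flooding the Euclidean distance
transform with basin-separation radius `min_distance = 5` px to split
touching objects. Instances never span classes; ids are assigned in
raster-scan order of each component's first pixel, so outputs are
deterministic and relabelling-stable. The pixel bookkeeping between the
semantic and instance representations is reported
(`instance_consistency_report()`), mirroring the practice of surfacing
removed-pixel counts when instance post-processing drops foreground.
Minimum-size filtering is strict (`size < min_size` removed, equality
kept), idempotent, and is applied to both reference and prediction at
evaluation time — the biological viability argument applies to both sides;
a flag is not provided because the choice is made once per analysis via the
`min_size` parameter.

Dice uses the standard `2TP / (2TP + FP + FN)` per class with unweighted
macro averaging; the default averages over foreground classes only, with
`include_background = TRUE` for challenge-style reporting. A class empty in
both masks scores 1 (perfect agreement on absence), and analogously
`AP = 1` when `TP = FP = FN = 0`.

Instance matching at threshold `eta` accepts candidate pairs with
`IoU >= eta` (the non-strict convention; observable only on exact ties) and
matches them one-to-one greedily in descending IoU with deterministic id
tie-breaks. Greedy matching is not guaranteed optimal in general, so the
test suite compares it against an exhaustive optimal matcher on 200 random
scenes with up to six instances per map; they agree on all of them, and
`AP_eta` is asserted non-increasing in `eta`. `mAP` averages `AP_eta` over
the ten thresholds 0.50–0.95 (computed as exact hundredths to avoid
floating-point grid drift); multiclass maps are matched per class and
macro-averaged.

`expert_range_classification()` compares a model score to the `[min, max]`
of the per-image expert scores; boundary equality counts as in-range, so
"human-level" is a closed interval.

## Quality assurance

Predictions are ranked by decreasing `U` (rank 1 = most uncertain), ties
broken by image id for reproducibility. The review threshold `U_min` is the
minimum `U` among hold-out predictions whose quality score falls below
`tau`; if no prediction fails, the conservative fallback `U_min = max(U)`
is used and flagged rather than disabling review silently. Raising `tau`
can only grow the failure set, so `U_min` is non-increasing in `tau` — an
invariant the tests assert. Pearson correlation between `U` and the quality
score, with the usual t-based two-tailed p-value, quantifies how well `U`
anticipates quality.

## The synthetic test bed

The generator produces what the methods need to be falsifiable, not
photorealism:

* **Scenes**: non-overlapping random ellipses (background intensity 0.1,
  foreground 0.6 by default, Gaussian pixel noise sd 0.05) with exact
  semantic and instance ground truth. Default canvas 128 x 128 with 5–10
  objects of semi-axis 4–9 px — sparse bright blobs at a realistic
  foreground fraction for nuclear or somatic stains. Object packing is
  attempted 200 times per object and fails loudly rather than looping.
* **Raters**: independent per-pixel flips with configurable sensitivity and
  specificity, plus optional morphological boundary jitter. This gives the
  STAPLE tests a known-parameter oracle; empirical flip rates are checked
  against their binomial expectations.
* **Ensembles**: member logits are a sharpened one-hot of the truth plus a
  smooth field shared across models within a view (view-to-view variation,
  driving the deviation-from-mixture term) and an independent smooth field
  per member (model disagreement, driving the spread term). Both scales at
  zero produce identical one-hot members and exactly zero uncertainty.
* **Mock predictor**: a logistic intensity thresholder calibrated to the
  nominal scene statistics, with small member/view perturbations. On
  nominal scenes it is confident; on content near its decision intensity
  its probabilities approach 0.5. This emulates the *mechanism* by which a
  trained ensemble reacts to out-of-distribution inputs without training
  anything.
* **OOD tiers**: "in" = nominal scenes; "partial" = nominal scenes plus an
  elongated tube and speckles at ambiguous intensities (stand-ins for blood
  vessels and fluorescent particles); "full" = structure-free textured
  fields with entirely different statistics.

Every generator output is a pure function of its configuration and seed.

What passing tests show — and what they do not: the synthetic rater model
has spatially independent errors, whereas real experts disagree mostly
along boundaries and structures; the mock predictor is a pixel-wise
intensity model, whereas real ensembles have spatially correlated errors
and calibration quirks. The suite therefore demonstrates correctness of
the estimators, fusion algebra, metrics, and QA logic under controlled
conditions, not the field performance of any particular trained ensemble.

## Problem sizes in the test suite

The suite favours the smallest sizes at which each property is
identifiable: hand-checkable examples on 2 x 2 to 8 x 8 grids, property
checks on 16–96 px scenes, STAPLE parameter recovery at 64/128/256 px
(error shrinking with size), ten degradation levels at 96 px for the
uncertainty-quality correlation, and a 16-scene, 20-seed tiered benchmark
at 64 px for out-of-distribution ranking.

## Known limitations

* STAPLE here assumes spatially homogeneous rater performance and, in the
  multiclass case, a one-vs-rest decomposition rather than full K x K
  confusion matrices.
* The watershed splitter is a geometric stand-in for learned object
  separation; heavily overlapping or concave objects can be over- or
  under-split, and `min_distance` needs domain tuning.
* The uncertainty aggregation for `K > 2` is a scaled average across
  classes; its ceiling of 1 is specific to `K = 2` with `zeta = 4`.
* No training, calibration, or Monte-Carlo dropout facilities are included;
  probability maps come from an external predictor contract or from files.
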