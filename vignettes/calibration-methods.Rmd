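---
title: "Calibrating classifier thresholds and extracting biodiversity insight from acoustic detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating classifier thresholds and extracting biodiversity insight from acoustic detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamcal)
```

## The problem

A pretrained vocalization classifier applied to passive acoustic recordings
emits *detections*: short audio windows tagged with a species and a
confidence score in (0, 1]. Pipelines conventionally discard everything below
an export floor (0.80 here). What remains is still a mixture of correct
calls and confusions, and the mixing proportion differs enormously between
species and between deployments — the same species can be nearly perfect in
one country's recordings and useless in another's. Before any ecological
statement can be made, each species in each dataset needs its own
reliability assessment.

Recall is left alone deliberately: estimating what the classifier *missed*
would require exhaustively annotating raw audio, which is intractable at
corpus scale. Everything downstream therefore conditions on detections, and
the quantity under control is precision.

## Precision estimation and threshold choice

For one (species, dataset) pair, an expert labels a uniform random sample of
`n_per_species` detections (default 50) drawn from all detections at or
above the export floor, marking each true or false positive. For a
candidate threshold $\theta$ the precision estimate restricts the labeled
sample to scores $\ge \theta$:

$$\hat p(\theta) = \frac{T_p(\theta)}{T_p(\theta) + F_p(\theta)}$$

The calibrated threshold is the **lowest** grid value
$\theta \in \{0.80, 0.81, \dots, 0.99\}$ with $\hat p(\theta) \ge 0.90$;
if no grid point qualifies the pair is *unreliable* and all its detections
are discarded. Choices worth making explicit:

* **Grid step 0.01.** The grid endpoints are conventional; the step matches
  the two-decimal score convention of classifier output. 20 grid points.
* **One labeled sample, reused across thresholds.** The labeling budget (50
  per species, roughly 20–30 minutes of expert time) admits no re-labeling
  per threshold. High thresholds therefore rest on few surviving labels, so
  estimates with fewer than `min_labeled` (default 5) survivors are
  *undefined* and ineligible — without this guard a threshold could be
  chosen on one or two labels. Setting `min_labeled = 1` restores the
  guard-free reading.
* **Inclusive comparisons.** "Reaches 90%" is $\ge 0.90$, and a detection
  scoring exactly the threshold is kept, consistent with precision being
  computed on $score \ge \theta$. Both are configurable.
* **Wilson 95% intervals**, not Wald: calibrated species often sit at
  $\hat p = 1$, where the Wald interval collapses to a point. The Wilson
  interval is computed in-package and cross-checked in the tests against
  `prop.test(correct = FALSE)`.
* **Plateaus** resolve to the lowest qualifying threshold; no preference for
  later, higher-precision grid points.

Downstream use additionally requires more than 20 detections surviving the
chosen threshold (strict inequality), and species with 50 or fewer raw
detections are dropped before sampling — both counted per dataset.
Calibration is never transferred between datasets: a species present in two
datasets is calibrated twice and may well be reliable in only one.

## The synthetic detection stream

The generator exists so that every stage can be tested against known truth.
Per (recorder, species) it draws two independent inhomogeneous Poisson
streams — true positives at `tp_rate_per_hour`, false positives at
`fp_rate_per_hour` — with a shared hourly intensity modulation:

* a **diel kernel**, a von Mises mixture on the 24 h circle evaluated at
  hour midpoints and normalized to mean 1 (so daily totals are preserved);
* a **residency window** in day-of-year, wrapping the year end for winter
  residents;
* a **migration band**: present only where the recorder latitude is within
  `band_halfwidth` of a center that starts at `start_latitude` on the
  simulation start date (the anchor is a package choice; the band tuple
  itself carries no date) and moves north at `speed_deg_per_week`;
* a **habitat multiplier** per recorder habitat.

Each event receives a Beta-distributed score (rounded to the canonical
6-decimal CSV precision) and is emitted only if the score reaches the export
floor — emission-truncation, not a refitted above-floor distribution,
because that is what export floors do to real classifier output. Every
emitted detection carries a ground-truth label.

Applying the modulation to *both* streams is a modeling simplification
(real false positives do not follow the bird's diel rhythm), adopted because
it buys the central analytic property: among detections scoring
$\ge \theta$ the expected precision is

$$p(\theta) = \frac{r\,S_{tp}(\theta)}{r\,S_{tp}(\theta) + S_{fp}(\theta)},$$

with $r$ the tp:fp rate ratio and $S$ the Beta survival functions —
independent of recorder layout, season and habitat. `precision_oracle()`
exposes this closed form and `analytic_optimum()` the implied optimal
threshold; the calibration tests are comparisons against them.

Determinism: one master seed; each (recorder, species) stream is sub-seeded
by a stable hash of (seed, recorder, species), so output is byte-identical
under a fixed seed and invariant to iteration order. Event times are drawn
uniformly within hour cells; there is no song-bout autocorrelation, no
acoustic-distance model, no score drift over time, and no inter-species
correlation. Passing tests therefore demonstrate that the *estimators* are
correct under the assumed sampling model, not that real deployments satisfy
that model.

## Scenario presets

Five fixed scenarios cover the phenomena the summaries are meant to
recover. `diel_triptych` places dawn / midday / dusk singers (von Mises
concentration 4) on one Amazonian recorder; `migration_north` moves a
2.5°-halfwidth presence band at 1.2°/week up a 54–75° N transect (the
transect extends beyond the band's travel so edge truncation does not bias
the front); `seasonal_taiwan` runs two full years with a summer breeder
(days 91–240), a wrapping winter visitor (days 274–90) and a year-round
resident; `habitat_gradient` uses multipliers 2.0 / 1.0 / 0.5 across
old-growth, secondary forest and pasture (360 recorder-days).

`precision_ladder` is the calibration stress case: ten species whose true
precision at the floor spans 0.05–0.995. The sub-90% rungs give both
streams the *same* Beta score distribution, making $p(\theta)$ exactly
constant at $r/(1+r)$ — flat curves that can never drift over the target.
Two species cross 0.90 at interior thresholds (0.85 and 0.89); their
false-positive scores use high-concentration Betas (Beta(369, 81),
Beta(250, 40), score SD ≈ 0.02) so the crossing is steep. This is a design
requirement, not a convenience: with diffuse Beta tails the precision curve
rises only ~0.02 per grid step, the optimum is statistically ill-defined at
any realistic label budget, and no estimator could recover it exactly — a
Monte-Carlo of the recovery procedure during design confirmed that the
chosen parameterization makes exact recovery at 500 labels and
within-one-step recovery at 50 labels well-posed. Rates are scaled so each
species emits ≈ 6000 detections over the 35-day run, giving label samples a
large pool to draw from.

## Insight summaries

All summaries consume the *trusted* set (post allowlist, raw-count and
threshold filters, in that default order) enriched with recorder metadata;
local time is `timestamp_utc` plus a per-recorder offset carried as data —
no timezone database, because diel analysis wants local solar time wherever
the recorder sits.

* **Diel profiles** count detections per local hour; effort correction
  (dividing by recorded hours per hour-of-day) is optional since detection
  patterns are routinely shown unnormalized. `circular_mean_hour()`
  summarizes the peak.
* **Habitat rates**: daily rate = detections / recorded hours per
  (recorder, day); recorder-days with effort but no detections enter as
  zeros, which is what makes the habitat means comparable. The 90th
  percentile of pooled daily rates is stored as the display cap so rate
  plots are reproducible from the summary alone.
* **Migration fronts**: median and quartiles of detection latitude per
  weekly bin; the least-squares slope of the medians is a convenience
  diagnostic of front speed.
* **Occurrence matrices**: species × weekly bins spanning the detection
  range, counts or presence; row order from average-linkage hierarchical
  clustering of presence rows under Jaccard distance. Rows are pre-sorted
  alphabetically before clustering, making the leaf order deterministic and
  invariant to input row order; two all-empty rows are defined to have
  distance 0. Weekly bins, Jaccard and average linkage are conventional
  defaults for presence data — the summaries expose all three as
  parameters.

Conservation invariants hold throughout: diel counts, count-mode row sums
and per-bin migration counts each total the species' trusted detections.

## Numerical and interface choices

Scores are written with six decimals and offsets with three, so canonical
CSV tables round-trip exactly; grid thresholds are canonical two-decimal
doubles, so `score >= threshold` at the boundary is exact. Detections with
invalid fields are rejected with row-level reasons, never repaired, and
accepted + rejected always equals input rows. Missing ids are derived
deterministically from (file, offset, species) so labels re-join stably.
Species names match exactly after whitespace/case normalization — fuzzy
matching risks silent misjoins. Pipeline runs write a manifest of input
hashes and parameters and no wall-clock values anywhere, so an unchanged
config reproduces a byte-identical run directory.

The test suite and the acceptance script use the preset problem sizes: ten
independent ladder pools of ≈ 59,000 detections with 100 label-resampling
replicates per budget, ≈ 17,000 detections for the diel check, ≈ 15,000 for
the migration check — large enough that the stated tolerances (3 binomial
SDs; ±1 h diel; 15% slope; 20% rate ratio) are comfortably binding on
estimator correctness rather than on Monte-Carlo noise.

## Limitations

Precision-only validation cannot say what fraction of true vocal activity
was detected; all rates are *detected-vocalization* rates, comparable across
strata only under equal detectability. Calibrated thresholds are valid for
the dataset they were calibrated on, and the simulator's independence
assumptions (Poisson arrivals, shared modulation of false positives, no
bouts) mean real-data performance must still be characterized by real
expert labels — which is precisely the workflow the package automates.
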