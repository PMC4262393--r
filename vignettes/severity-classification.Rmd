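---
title: "Tier-based severity classification of inherited diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tier-based severity classification of inherited diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevclass)
```

## The problem

Expanded carrier screening (ECS) panels test for hundreds of recessive
diseases at once, and professional guidelines make disease severity a key
criterion for panel inclusion. Polling clinicians disease-by-disease does
not scale: every newly mapped disease would need a fresh survey. sevclass
implements the alternative: survey the importance of *disease
characteristics* once (shortened life span, intellectual disability,
sensory impairment, ...), group those characteristics into importance
tiers, and then classify any disease into Profound, Severe, Moderate or
Mild from nothing but the list of characteristics of its untreated
course.

The package ships the reference survey on which this approach was
piloted: 192 health-care professionals (genetic counselors and
physicians) rated 15 characteristics on a 1--10 importance scale and
rated the severity of 15 diseases, five each, on the ordinal
Mild < Moderate < Severe < Profound scale. Those ratings, tier
assignments, disease profiles and screening-status flags are packaged as
plain-CSV fixtures (`load_default_characteristics()`,
`load_reference_diseases()`, `reference_profiles()`).

## Tier derivation: 1-D Ward clustering

Mean importance ratings are clustered with Ward's minimum-variance
agglomerative method, written out in full rather than delegated, because
the merge history and its costs are part of the method's audit trail.
At each step the pair of clusters merged is the one minimising the exact
increase in total within-cluster sum of squares,

$$\Delta ESS(A, B) \;=\; \frac{|A|\,|B|}{|A|+|B|}\,
  (\bar{x}_A - \bar{x}_B)^2 ,$$

which for 1-D data needs only cluster sizes and means. The merge costs
telescope: their sum equals the total sum of squared deviations from the
grand mean, an identity the test suite asserts numerically. Cutting the
tree at $k$ undoes the last $k-1$ merges; clusters are labelled in
descending order of cluster mean, so Tier 1 (or the Profound group) is
always the top cluster.

Numerical choices:

* **Tie-breaking.** Among equal-cost candidate merges (cost difference
  below $10^{-12}$) the pair whose lowest member index in input order is
  smallest wins, then the smaller second index. Runs are therefore
  bit-reproducible regardless of floating-point coincidences.
* **k is explicit.** The package never selects $k$; the reference
  analysis uses $k=4$ for characteristics and $k=3$ for diseases.
  `merge_cost_profile()` reports the cost of the next merge at each $k$
  as a diagnostic only.
* **Means only.** Clustering operates on per-item mean ratings, matching
  the reference analysis; medians are reported but not clustered.
* **All 15 items are clustered,** the two modifiers included: the
  reference analysis clustered all 15, with availability of treatment
  co-clustering at the top of Tier 2 and variable expressivity at the
  bottom of Tier 3. Modifiers are excluded later, at classification
  time, never from the clustering itself. `derive_tiers(...,
  include_modifiers = FALSE)` exposes the 13-core-item variant, which
  yields the same core memberships on the packaged means; both choices
  are therefore defensible and the inclusive one is the default.

`ward_linkage()` is verified against an independent Lance--Williams
implementation (`stats::hclust(method = "ward.D2")`): on random small
vectors with distinct values the partitions agree exactly at every $k$.

## The decision algorithm

Classification uses only the core characteristics, bucketed by tier,
after two filters:

1. **Penetrance.** A characteristic counts only if at least 25% of
   affected individuals show it (`penetrance_threshold = 0.25`,
   inclusive by default because the criterion is "at least"; a strict
   comparison is a config switch). Unspecified penetrance passes -- the
   packaged profiles list presence only and must classify.
2. **Eliminated items.** The two modifiers and the single Tier 4
   characteristic (reduced fertility) are inert: availability of
   treatment is not a property of the untreated course, variable
   expressivity is captured by the penetrance question, and reduced
   fertility was a clear outlier in importance. A modifier in an input
   profile is ignored with a notice, never an error.

The rules then fire in strict precedence over the effective tier counts
$n_1, n_2, n_3$:

| rule | condition | class |
|------|-----------|-------|
| R1 | $n_1 \ge 2$ | Profound |
| R2 | $n_1 = 1$ | Severe |
| R3 | $n_1 = 0,\; n_2 \ge 1,\; n_2 + n_3 \ge 4$ | Severe |
| R4 | otherwise, $n_2 + n_3 \ge 1$ | Moderate |
| R5 | otherwise | Mild |

Every classification carries a rule trace (each rule evaluated, with the
counts it saw), supporting transparent consent conversations about *why*
a disease sits in its bin.

Readings the criteria leave open, and the choices made:

* **"More than one Tier 1 characteristic"** means at least two distinct
  Tier 1 ids. The two infant/child life-span items count separately if
  both are listed; the validator warns on such input because reference
  profiles list at most one life-span item.
* **R3's "a Tier 2 characteristic and at least three other Tier 2 or 3
  characteristics"** is read as $n_2 \ge 1$ and $n_2 + n_3 \ge 4$. This
  total-count reading reproduces both contrast cases in the reference
  panel: Usher syndrome type 1F (1 Tier 2 + 3 Tier 3 = 4, Severe) and
  alpha-1 antitrypsin deficiency (2 Tier 2 + 1 Tier 3 = 3, Moderate).
  The stricter alternative -- the three *others* must be Tier 3 -- is
  available as `classifier_config(r3_others_tier3 = TRUE)` and leaves
  all 15 reference classifications unchanged.
* A disease whose only listed characteristic is neonatal-lethal shortened
  life span classifies as Severe (R2), not Profound -- the alpha-thalassemia
  (Hb Barts) situation. The criteria arguably understate such diseases;
  the package follows the criteria and leaves the tension to
  documentation.

Two properties are enforced by construction and property-tested over
randomly generated profiles: adding a characteristic at passing
penetrance never lowers the class, and raising the penetrance threshold
never raises it.

## Survey aggregation conventions

* Mean is the arithmetic mean over all contributing respondents;
  item-wise inclusion (no listwise deletion of respondents who skipped
  items).
* Even-count medians use the midpoint of the two central values -- the
  packaged medians are consistent with that convention.
* Percentages (e.g. the penetrance-option distribution) are rounded
  half-up to one decimal. Computed percentages are reported even where
  the source tabulation disagrees with its own counts: 75 of 192
  respondents is 39.1%, and that is what `penetrance_distribution()`
  returns.
* Severity labels encode as Mild = 1 ... Profound = 4, fixed and not
  configurable.

## The synthetic survey generator

`simulate_ratings()` draws each respondent's rating from a normal
distribution centred on the item's target mean with standard deviation
`spread`, rounds to the nearest integer and clamps to the scale bounds.
Each item has its own substream derived from the master seed and a
stable hash of the item id, so adding an item never perturbs the other
items' draws; identical seeds give byte-identical output.

Clamping (censoring) was chosen over rejection-based truncation
deliberately: its discrete law has a closed form (used as the oracle in
the tests), the `spread = 0` limit degenerates exactly to
`round(target)`, and its mean bias is strictly smaller than the
truncated alternative's near the scale ceiling. The bias is accepted and
documented rather than re-centred away. From the closed form: at
`spread = 1.5` the worst packaged target (9.53, near the ceiling of 10)
is pulled down by 0.38 rating points, while every target at or below 8.1
moves by less than 0.07; over targets in $[2, 9]$ the bias stays below
0.22 at `spread` 1.5 and below 0.40 at `spread` 2. Because the bias is
monotone and compressive near the top, the *ordering* of item means --
all that Ward clustering of 1-D data consumes -- is essentially
preserved, which is why tier recovery survives it.

What the generator emulates: per-respondent integer ratings with
realistic dispersion around the reference means, on both the 1--10 and
1--4 scales. What it does not: respondent covariates (profession,
specialty), the uneven survey-set sizes (52/46/94), item-item
correlation within a respondent, and any systematic rater severity or
leniency. Passing recovery tests therefore show the pipeline is
consistent and well-calibrated under independent, symmetric noise -- not
that real surveys of this size must recover the tiers.

`recovery_experiment()` quantifies end-to-end recoverability: simulate a
survey targeting the packaged characteristic means, aggregate, re-derive
tiers, and ask whether the full 15-item co-cluster assignment matches
the packaged one exactly. With `spread = 0` recovery is 1 by
construction; at the reference survey's size (192 respondents) with
`spread = 1.5` -- roughly the dispersion implied by the packaged
min/max ranges -- recovery is routinely above 0.95, as recomputed by
`scripts/acceptance.R` on every run. With 5 respondents at `spread = 4`
it collapses, the expected sample-size monotonicity.

The sizes used by the shipped checks -- 200 random vectors for the Ward
oracle comparison, 1000 random profiles for the monotonicity properties,
100 simulated surveys for recovery -- keep the whole suite under a
minute while leaving Monte Carlo error far below the effects asserted.

## Evaluation

`concordance()` compares algorithmic classes with survey-derived groups
as a 4x4 confusion matrix plus simple agreement; on the packaged panel
the classifier reproduces all 15 survey groups and never predicts Mild
(no surveyed disease averaged below 1.8 of 4). Chance-corrected
agreement is deliberately not the default -- with 15 diseases and three
occupied classes a kappa would suggest more precision than the pilot
supports. `bootstrap_tier_stability()` resamples whole respondents (the
survey's sampling unit) with replacement and reports per-characteristic
tier frequencies; respondents are canonically sorted first so the result
depends only on data and seed.

## Known limitations

* The tiers and rules derive from one 192-respondent pilot of
  screening-adjacent professionals; patients and disease experts may
  rate differently, and the package deliberately provides the bootstrap
  and recovery machinery to re-derive everything from replication data.
* Penetrance enters only as a hard threshold; no weighting by how many
  affected individuals show a characteristic.
* The classifier is ordinal-out only -- no severity score, and no
  modelling of treatment availability, which the criteria exclude from
  untreated-course severity by design.
* The 1-D Ward implementation is quadratic per merge and intended for
  the tens-of-items regime of characteristic and disease panels, not for
  thousands of items.
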