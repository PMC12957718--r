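---
title: "Methods: detecting and modelling winter communal roosting from GPS tracking"
author: "roostkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and modelling winter communal roosting from GPS tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(roostkit)
```

# The problem

Red kites (*Milvus milvus*) on their wintering grounds facultatively gather
in nocturnal communal roosts. Given multi-year GPS tracking of individually
tagged birds — duty-cycled fixes between 07:00 and 21:00 local time —
roostkit reconstructs each bird's nightly roosting history, decides when it
attended a communal roost, models how attendance depends on age, sex and
breeding status, separates within-individual behavioural change from
selective mortality, and tests whether birds roost assortatively with their
breeding mates and kin. Every stage can be exercised end to end on a
synthetic tracked population whose generative parameters are known, so the
pipeline's statistical machinery is validated against recoverable truth.

# From fixes to attendance

## Night locations

A fix belongs to night *d* when it falls after civil dusk (solar elevation
−6°) of local date *d* or before civil dawn of date *d + 1*; the duty cycle
brackets this at 07:00–21:00 CET. Twilight times come from the standard
NOAA solar-position approximation (accurate to a minute or two, ample for
hourly fixes); in the test-suite they are cross-checked against an
independent Meeus-style ephemeris. Each bird-night is reduced to the
component-wise median of its qualifying planar fixes, which is robust to
the occasional pre-roost or early-morning movement fix.

Coordinates are processed in planar metres. Because no projection library
is available to the package, interchange WGS84 coordinates pass through a
small local equirectangular projection (ellipsoidal meridional and normal
radii at a declared origin). The map is affine and exactly invertible;
distance distortion over a study-area-sized extent (tens of km) is below
0.15%, i.e. sub-metre at the 300 m scale that matters here, and is verified
against geodesic distances in the tests.

## The communal-roost rule

A focal bird is at a communal roost in a five-night interval when at least
two *other* tagged birds had night locations within 300 m of one of its
night locations during that interval. Distances are between nightly
medians, and the ball is closed (a pair at exactly 300 m counts). Two
matching rules are implemented:

* `cross_night` (default): another bird counts if any of its night
  locations in the interval is within the radius of any focal night
  location. Pooling nights reduces false negatives when only a small
  fraction of the roost is tagged, which is the rationale for the
  five-night window.
* `same_night`: the two birds must be within the radius on the same night.

Both are exposed because the cumulative-versus-simultaneous reading of the
window is genuinely ambiguous; the default follows the false-negative
argument. `sensitivity_sweep()` evaluates the rule over grids of radius,
window and neighbour threshold; attendance is provably monotone in each.

## Interval calendar and weights

Winters run 1 November – 31 January (92 nights) and intervals are
consecutive non-overlapping five-night blocks anchored at 1 November: 18
full blocks plus one two-night block, hence 19 intervals per winter and
114 over six winters, independent of the data. Block anchoring (rather
than a sliding window) is what makes the interval count a calendar fact.

Birds far from the study area cannot be seen with the (locally
concentrated) tagged flock, so absence there is weak evidence of
non-attendance. Each bird-interval gets weight
`1 − mean(distance to study-area polygon) / max over units`: units fully
inside weigh 1, the farthest unit weighs 0. The global maximum is used as
the scaling constant because "scaled between 0 and 1" admits no other
self-contained reading. Distances are Euclidean in the projected plane,
zero inside the polygon (hand-rolled ray casting + point-segment
distances, again for lack of an installed geometry package).

# The attendance model

Attendance (0/1) per bird × five-night interval is modelled with a
weighted binomial logit mixed model. Juvenile-tagged cohort:

$$\mathrm{logit}\,P(y_{bwt}=1) = \beta_0 + \beta_1\,\mathrm{age}
+ \beta_2\,\mathrm{age}^2 + \beta_3\,\mathrm{male} + \beta_4\,\mathrm{breeding}
+ u_b + v_{bw} + s_{bw}\,t + w_w$$

with bird intercepts $u_b$, correlated bird-within-winter intercepts and
interval-sequence slopes $(v_{bw}, s_{bw})$ (temporal autocorrelation), and
winter intercepts $w_w$. Adult-tagged birds have unknown age and all breed,
so their model keeps sex only. Weights multiply each unit's log-likelihood
contribution (binomial prior weights). Age is standardised with fixed
constants (centre 3.5, scale 1.5 — the mid-range of the observable 1–7
winter ages), so generative and fitted coefficients live on the same scale;
the interval index is standardised over the 1–19 winter sequence.

Estimation is marginal maximum likelihood via the Laplace approximation
(glmmTMB). The engine is a contract, not an emulation of any particular
software: the requirement, enforced by simulation tests, is that fixed
effects generated from known truth are covered by their 95% intervals at
the nominal rate (20 seeded replicates at 150 birds × 4 winters; chosen as
the smallest size at which all effects are comfortably identified while 20
refits stay affordable). A Bayesian sampler satisfying the same recovery
property would be interchangeable. Coefficients beyond ±15 on the logit
scale raise a separation flag; non-convergence is flagged, never silent.

Diagnostics follow standard practice for binary mixed models:

* **Binned residuals** — units sorted by fitted probability, equal-count
  bins, mean residual against a ±2 SE band. With conditional (shrunken)
  fitted values a few benign excursions are expected even under correct
  specification; the informative use is comparative, and the tests verify
  that omitting a true quadratic term produces systematically larger
  excursions than the well-specified fit.
* **Event-rate classification accuracy** — fitted probabilities are
  thresholded at the observed event rate and the weighted proportion of
  correct classifications reported.
* **Adjusted repeatability** — on the latent scale,
  $R = \sigma^2_{bird} / (\sigma^2_{bird} + \sigma^2_{winter} + \pi^2/3)$.
  The denominator includes the winter variance but not the fixed-effect
  variance (adjusted repeatability) nor the slope variance: predictions are
  evaluated at the average interval, where the slope contributes nothing.
  Confidence intervals come from a seeded parametric bootstrap (simulate a
  new response from the fit with fresh random effects, refit, recompute).
* **Model comparison** — penalised marginal log-likelihood (−AIC/2, random
  effects integrated out). The marginal scale matters: conditional
  likelihoods let random effects absorb an omitted fixed term, which would
  make the comparison blind to exactly the misspecification it should
  detect. The reported SE of a difference is a heuristic from pointwise
  conditional contributions, analogous to the pointwise SE of
  cross-validated predictive density.

`cramers_v()` quantifies the age–breeding confounding that motivates
fitting a separate non-breeder model.

# Plasticity versus selective mortality

A population-level age decline can reflect individuals changing with age
(plasticity) or differential death of frequent roosters (selective
disappearance). On the subset of birds with confirmed mortality — whose
longevity, the age at death in winters, is known — four weighted binomial
models are fitted: age only (no bird intercept); age + bird intercept;
longevity + bird intercept; age + longevity + bird intercept. All include
sex, breeding status, Julian date (days from 1 November, standardised; a
fixed-covariate stand-in for temporal autocorrelation suited to the
reduced sample) and a winter intercept; age enters quadratically. These
fits use REML: longevity is a between-bird covariate and only a few dozen
birds have confirmed deaths, and ML variance components make its Wald SE
anticonservative at that cluster count (about 12% false detections at the
nominal 5% in simulation, restored to near-nominal by REML).

The interpretation rule reads the fullest model: an age term excluding
zero while longevity covers zero ⇒ plasticity; the converse ⇒ selective
mortality; both ⇒ both mechanisms. Age is standardised within the
mortality subset (not with the global constants) so the quadratic stays
near-orthogonal to the linear term in this age-truncated sample; VIFs of
the fixed design are reported and flagged at ≥ 2. Note that longevity and
observed age are intrinsically correlated in any mortality cohort
(observation is truncated at death), so VIFs around 2 are a property of
the design, not an error.

The two generative scenarios used to validate discrimination
(`simulate_mortality_cohort()`) are: *plasticity* — the quadratic age
effect of the default truth, longevity unrelated to roosting; *selective
mortality* — no within-bird change, attendance log-odds declining 1.5 per
SD of longevity (a strong but plausible selective signal chosen once at a
size detectable in a 43-bird cohort). Under both, death truncates
observation, so a population-level age decline appears either way; only
the model suite can tell the mechanisms apart.

# Assortative roosting

## Classification

Relationships derive from the brood and pair registries: mates are birds
nesting together in a season (year-specific), parent-offspring and
intra-year sibling links are permanent. A dyad with several labels
(possible only in corrupted inputs) resolves by precedence mate >
parent-offspring > sibling. A bird-night is *eligible* when at least one
labelled relative held night locations in the same five-night interval —
relatives that are dead, silent or abroad confer no opportunity. An
optional polygon restricts "present" to in-country locations. Eligible
bird-nights are classified into {communal, non-communal} × {with, without
mate-or-kin}; co-roosting reuses the 300 m detection radius (no separate
threshold is defensible), and each record carries the distance from its
night location to the bird's registry nest (breeding nest if a breeder
that season, else natal nest).

## The permutation null

The null keeps all spatial data — night locations, communal flags, the
eligible record set — fixed and randomises nest identity: within each
cohort year the natal-brood assignment of juvenile-tagged birds is
shuffled, and within each breeding season the male→nest and female→nest
assignments are shuffled independently, so mate links (co-assignment to a
nest), kin links and nest coordinates are all re-derived per iteration.
Reshuffling breeding nests alongside broods is deliberate: with pair bonds
held fixed, every mate-related statistic would have a degenerate null
equal to its observed value. Years with a single brood or nest stay fixed
and are logged. Shuffles preserve the number of birds and the year-wise
multiset of broods by construction.

Per iteration all summary statistics are recomputed: the four cell shares,
the mean distance per cell between each bird's winter-average roosting
location and its (permuted) nest, and the association-type shares. The
observed values are computed through the same evaluation path with the
identity assignment, so observed and null draws are exchangeable under no
assortment — the property that keeps the directional p-values (proportion
of null draws at least as extreme on the side where the observation lies)
calibrated in the rejection tails, which the test-suite verifies over 400
label-shuffled replicates. Exact global uniformity is not attainable in
this design: the record set is selected by eligibility under the observed
labels while null reshuffles are unconditional, which distorts the centre
of the p distribution but leaves the tails — and therefore decisions at
conventional significance levels — calibrated.
A boundary proportion of zero is reported as "< 1/n_iter". The default is
1000 iterations.

Within-season change is modelled by aggregating records to bird × interval
(any mate / any kin co-roost) and fitting logistic mixed models with the
standardised interval sequence as slope and bird as random intercept
(lme4); the kin model is skipped with a warning when kin co-roosting never
occurs, and a single bird degrades to ordinary logistic regression.

# The synthetic population

`generate_population()` + `simulate_winter_nights()` emulate the sampling
situation the pipeline is built for, with defaults matching the study
conditions: 148 juvenile-tagged and 68 adult-tagged birds, six winters, a
387 km² study area, hourly fixes on the 07:00–21:00 duty cycle, major
roost sites with satellites within 2 km, and within-night scatter
σ = 11.35 m per coordinate so the median pairwise distance between a
night's fixes is ≈ 1.665 σ ≈ 18.9 m. Attendance truth defaults are the
juvenile-cohort point estimates of the attendance model (intercept −0.441,
age −0.27, age² −0.453, male +1.731, breeding −1.296; SDs 1.624 / 1.852 /
1.394 / 0.345, intercept–slope correlation −0.581) plus a weak negative
seasonal logit trend (−0.1 per standardised interval) reproducing larger
November than January roosts. Migration-absence and mortality tables
(females and first-winter birds absent most; first-year mortality 0.55)
and the breeding-settlement hazard from age 3 (0.25/0.5/0.6) are chosen
once as field-realistic values and documented here rather than tuned.

Design choices worth stating explicitly:

* **The latent attendance decision is drawn once per bird × five-night
  interval**, not independently per night. The interval is the behavioural
  and modelling unit; nightly draws aggregated by "any night communal"
  would shift the interval-scale intercept by roughly log 5 and make the
  fitted model misspecified with respect to its own generative truth, so
  parameter recovery would be unattainable by construction. Attending
  birds keep one roost site per interval (site fidelity), chosen with
  probability ∝ attractiveness × exp(−distance/5 km) from the bird's
  anchor, which lets satellite structure emerge.
* Non-attending breeders sit near their nest; with probability
  `pair_coroost_prob` (default 0.8) a pair both at home co-roosts at the
  nest (25 m placement jitter). Non-breeders anchor on a home range offset
  from their natal nest — the mechanism for non-breeders without
  territories is unreported in the field, and natal-anchored ranges are
  the conservative choice. A small kin co-roosting probability (0.05)
  exists for planted-effect tests.
* Fixes are emitted only between civil dusk and the 21:00 duty end plus
  the before-dawn morning fixes — the nocturnal subset the pipeline
  consumes.

What the generator does *not* emulate: weather, foraging movement, flight
paths, partial-winter migration (absences are whole-winter), untagged
conspecifics, tag failure and GPS outliers beyond Gaussian scatter.
Passing tests therefore demonstrate that the statistical machinery
recovers known truth under the stated sampling structure — not that the
rule set is robust to every field pathology. At the default tagging
density, detected attendance is a noisy version of latent attendance
(false negatives where few tagged birds share a roost), which is the
realistic regime the five-night window exists for; consequently pipeline-
level effect estimates are attenuated relative to the generative truth,
and coefficient-recovery validation runs on units drawn at the model's own
scale.

# Numerical conventions and degenerate inputs

Timestamps are stored UTC and converted to CET (fixed UTC+1; daylight
saving does not apply in winter) for night assignment. CSV interchange is
comma-separated UTF-8 with ISO-8601 timestamps and fixed-precision
coordinates, so fixture round-trips are byte-identical. Ties at exactly
the detection radius count as inside. Empty inputs yield headers-only
files; malformed fix rows are dropped with their row numbers logged;
missing columns, degenerate polygons, conflicting registries and
longevities below the last observed age are hard errors. Every pipeline
run records seed, configuration hash and package version, and reruns with
the same seed are byte-identical.

Validation problem sizes (the package's own choices): coefficient recovery
at 150 birds × 4 winters × 20 seeds; mechanism discrimination at 43-bird
cohorts × 20 seeds per scenario; detection oracle equivalence on 50
fixtures of up to 500 night locations; permutation calibration over 400
label-shuffled replicates of a 46-bird two-winter world with 99
iterations each.

# Known limitations

* The Wald intervals of the Laplace fit are first-order; with few winters
  the winter variance is weakly identified and can collapse to zero (its
  repeatability contribution is then absorbed conservatively).
* The permutation null randomises natal broods and breeding nests but not
  tag failure or presence patterns; eligibility is treated as fixed.
* The projection is local; inputs spanning hundreds of kilometres should
  be re-projected externally.
* Detection-scale estimates inherit the tagging density of the sample;
  they are comparable across parameter settings, not absolute rates for
  the whole (partly untagged) population.
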