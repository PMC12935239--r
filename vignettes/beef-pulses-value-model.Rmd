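---
title: "An additive value model for dietary substitution scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An additive value model for dietary substitution scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmcda)
```

## The decision problem

Shifting a population's diet away from an animal protein source towards a
plant-based one touches four kinds of concerns at once: health (burden of
disease attributable to dietary risk factors), the environment (greenhouse
gases, water, land, eutrophication, biodiversity), the economy
(supply-chain profitability, consumer affordability, local development) and
social acceptability. The indicators live on incommensurable scales —
DALYs per 100,000 inhabitants, kg CO2-eq per kg of food, percentage changes
in gross operating margin — so "which substitution level is best overall"
is not answerable by any single indicator.

`dietmcda` implements the standard multi-attribute value theory answer. A
*value model* consists of

* evaluation criteria, each operationalized by a **descriptor of
  performance**: an ordered set of plausible performance levels, from most
  attractive (`L1`) downwards, with two reference levels singled out — a
  **Good** level worth 100 points and a **Neutral** (minimally acceptable)
  level worth 0 points;
* a **cardinal value scale** per criterion, assigning points to every
  descriptor level;
* positive **weights** summing to one, elicited by *swing weighting* —
  comparing how attractive the jump from Neutral to Good is on each
  criterion, which makes weights scale factors rather than vague importance
  statements.

An alternative `a` with partial values `v_j(a)` gets the global score

    V(a) = sum_j w_j * v_j(a),   sum_j w_j = 1,  w_j > 0.

Because every `v_j` is anchored at Neutral = 0 / Good = 100, `V(a)` reads
directly: 0 means "minimally acceptable everywhere", 100 means "good
everywhere".

## Value scales from qualitative judgments (MACBETH)

Experts rarely state cardinal values directly. The MACBETH protocol asks
only for qualitative pairwise judgments: for two levels (or two
Neutral-to-Good swings) the difference in attractiveness is placed in one
of seven semantic categories — *null, very weak, weak, moderate, strong,
very strong, extreme* — or a contiguous range of them when the group
hesitates. `derive_scale()` turns a judgment matrix into numbers by solving
the constraint system (category step `delta = 1`):

* a pair judged in category `k >= 1` has a value difference of at least
  `k * delta`;
* a *null* judgment means exact indifference;
* a pair judged in a strictly higher category than another pair has a
  strictly larger value difference (separation `delta`);
* all values are non-negative.

Consistency of a matrix *is* feasibility of this system
(`check_consistency()`); for an infeasible matrix the report names a subset
of judgments whose removal restores feasibility. Among the feasible scales
we return the unique one of **minimum Euclidean norm**, computed by a dual
active-set quadratic program (`quadprog`), and then rescale affinely so the
chosen Neutral and Good entities land on 0 and 100. The minimum-norm
selection was a deliberate design choice over the more traditional
"minimize the largest value, break ties lexicographically" device: both
pick a single point from the optimal set, but the minimum-norm point is
unique by strict convexity, independent of the order in which entities are
listed, and keeps judged indifferences exact (null-judged entities are
merged into one variable before solving). Commercial implementations do not
document their tie-break; none of the published results depend on it, since
the case-study scales are shipped as data rather than re-derived (the
underlying judgment matrices were never published).

`derive_weights()` applies the same machinery to Neutral-to-Good swings,
with two additions: the elicited swing *ranking* enters as order
constraints, and every swing is held at least one category step above zero
(a swing is always a strict improvement). The raw values are normalized to
sum to one. `validation_ratio()` supports the facilitator's classic
checkback — "is going from L4 to L3 really twice as attractive as going
from L3 to L2?" — as an exact ratio of value differences.

## From performance to partial values

`partial_value()` converts performance through the criterion's value
function:

* **quantitative** descriptors use the piecewise-linear function through
  the (performance, value) anchors. Between adjacent anchors the value is
  linearly interpolated on the raw performance axis; beyond the extreme
  anchors it is extrapolated with the terminal segment's slope, without
  clamping. Both conventions were confirmed against the published partial
  values of the case study (e.g. the affordability partials 346.67 and
  396.7 lie above the top anchor value of 300 and are reproduced exactly by
  terminal-slope extrapolation);
* **categorical** descriptors use exact label lookup — no interpolation is
  meaningful between labels. Where a descriptor repeats a label verbatim
  (the fair-practices descriptor does, an artifact of its source), the most
  attractive match wins.

`evaluate()` aggregates. A cell can be fed from three places, in order of
precedence: an explicit partial-value override (how published partial
tables are reproduced), a performance cell run through `partial_value()`,
or nothing — a MISSING cell contributes 0 points, i.e. is scored at the
Neutral reference, and is listed in the result's missing-cell log with a
warning. Scoring missingness as Neutral is the convention the case study
itself uses (the Danish accessibility column is blank throughout and the
published totals are consistent with zero contribution); an alternative
would be imputation, which we deliberately avoid in a transparency-first
tool. A scenario with *no* information at all is an error, not a zero.

## The beef-to-pulses case study

`case_study("PT")` / `case_study("DK")` return the packaged 14-criterion
model (descriptors, cardinal scales, weights) together with each country's
scenario evidence, published partial values and published global scores.
Five scenarios are compared: the current diet (`0%`) and replacement of
25/50/75/100% of beef consumption with an equivalent amount of pulses.

Fixture notes, all visible in the data files and level annotations:

* the local-development descriptor's least attractive level is stored with
  value −66.67; its source prints 66.67, which contradicts both the scale's
  monotonicity and every published partial (−66.7) derived from it;
* evidence columns are carried only where their unit matches the
  descriptor (economic % changes, total DALYs, the environmental
  indicators). Affordability is published as absolute purchasing-power
  prices; the % change interpretation back-derived from the published
  partials reproduces them only to within ~1–2 points, so affordability
  enters evaluations through the published partials instead;
* three published global rows (PT 0%, DK 0%, DK 100%) cannot be
  reproduced from their own published partials and weights (recomputation
  gives 16.35, −3.10 and 91.91). `case_study()` flags them
  `self_consistent = FALSE` and the package reports recomputed values next
  to published ones rather than silently preferring either. Amusingly, the
  PT 0% published score of 16.99 *is* recovered in recompute mode — the
  evidence-based pollution partial (12.5) rather than the published one (5)
  evidently went into the published total;
* `case_study_evaluation(country, recompute = TRUE)` recomputes partials
  from the evidence wherever possible and reproduces all published
  substitution-scenario scores within ±0.05 points.

Scenario construction is linear: `blend_scenario()` forms the convex
combination `(1-f)*reference + f*endpoint` of the 0% and 100% rows. All
published intermediate environmental cells are within last-digit rounding
of this blend. The DALY columns are mildly sublinear in the substitution
fraction, so the fixtures carry them as published inputs rather than
blending them.

## Sensitivity and robustness of the recommendation

`weight_sensitivity()` varies one criterion weight `w` over [0, 1],
rescaling the other weights proportionally by `(1 - w)/(1 - w_j0)` so they
keep their relative sizes and the vector keeps summing to one (the
convention behind the familiar one-line-per-alternative sensitivity plots).
Every global score is then affine in `w`, so crossings are found in closed
form; `recommendation_stability()` reports the smallest weight change that
replaces the top alternative, or that none exists. In the case study the
recommendation is invariant over the whole unit interval for both focal
criteria (diet-related health and water use) in both countries.

`robustness()` handles uncertainty in the value judgments themselves:
closed intervals around partial values. For an ordered pair of scenarios it
reports the strongest of *dominates* (criterion-wise interval ordering),
*robustly preferred* (`V(a) - V(b) >= 0` over the entire box — computed
exactly at the box vertex taking `a`'s lower and `b`'s upper bounds, since
the minimum of an affine function over a box sits at a vertex), *preferred*
(nominal only) or *incomparable*. Widening intervals can only downgrade a
relation, never upgrade it.

The shipped robustness analysis perturbs the three criteria whose inputs
carry the most uncertainty (diet-related health impacts,
environment-related health impacts, acceptance) by ±25 points — a total
interval width of half the Neutral-to-Good swing. The magnitude is a
modelling choice (no magnitude was published): the three criteria together
carry a quarter of the total weight, so independent cell-wise intervals of
half-width `h` can move a pairwise value difference by up to `0.5 * h`
points, and the tightest nominal gap involving the recommended scenario is
about 22 points. Half-width 25 therefore probes roughly half of the
recommendation's safety margin; at half-width 50 the perturbation (up to 25
points) would exceed the tightest gap for *any* additive model with these
weights, i.e. the test would no longer measure the case study but only the
arithmetic identity. Under the shipped choice the full-substitution
scenario remains robustly preferred over every alternative in both
countries, which is the qualitative finding the analysis is designed to
check.

## Synthetic generators and what the tests show

`synth_model()` draws valid random models (strictly monotone descriptors,
strictly decreasing scales hitting the anchors exactly, Dirichlet weights);
`generate_consistent_matrix()` draws a hidden cardinal scale and bins all
pairwise differences into the seven categories by equal-width thresholds,
which guarantees consistency and supplies a ground truth for recovery
tests. Both are deterministic per seed and restore the caller's RNG state.

The property tests built on them show that the engine honours its
contracts — category constraints satisfied, hidden orderings recovered,
feasibility agreeing with an exhaustive search oracle on up to 4 entities
(values gridded over 0..12), vertex robustness agreeing with full vertex
enumeration. They do not show that real panels produce consistent
matrices, nor that linear blending captures real consumption dynamics:
generated matrices are consistent by construction, and the blending
assumption is validated only against the published tables' own rounding.

## Numerical conventions

* weights must sum to 1 within 1e-9; aggregation identities are tested at
  1e-9;
* reported scores are printed at 2 decimals; computation is full double
  precision throughout;
* ranking ties are broken by input order (stable);
* crossover weights are exact roots of affine differences (|ΔV| < 1e-9);
  line intersections within 1e-9 of 0 or 1 are treated as boundary touches,
  not crossovers;
* delimited text is comma-separated UTF-8 with dot decimals; European
  decimal commas and the Unicode minus sign are normalized on ingest;
* problem sizes throughout tests and the acceptance script are desk-scale —
  14 criteria, 5 scenarios, judgment matrices of up to 7 entities — chosen
  to match the case study itself; the whole suite is CPU-seconds.

## Limitations

The model is a single-level additive aggregation: criteria interactions
(e.g. a health benefit that only materializes alongside acceptance) are out
of scope, as are multi-panel preference aggregation and probabilistic
robustness. DALY estimation and life-cycle footprints are inputs, not
computations — the package evaluates substitutions given such evidence; it
does not produce the evidence.
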