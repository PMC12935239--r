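# dietmcda

Multicriteria value measurement for dietary substitution policy.

Replacing part of a population's beef consumption with pulses changes
health burden (DALYs), greenhouse-gas emissions, water and land use,
biodiversity pressure, supply-chain profitability, consumer prices and
social acceptability all at once — on mutually incomparable scales.
`dietmcda` evaluates such substitution scenarios with an additive
multi-attribute value model:

    V(a) = Σ_j w_j · v_j(a),   Σ_j w_j = 1,  w_j > 0

where each partial value function `v_j` is a piecewise-linear cardinal
scale over an ordered descriptor of performance, anchored at a *Neutral*
level (0 points) and a *Good* level (100 points), and the weights `w_j` are
swing weights. The package covers the full workflow:

* **MACBETH engine** — derive cardinal value scales and swing weights from
  qualitative pairwise judgments in the seven semantic categories (*null* …
  *extreme*), with consistency checking by constraint-system feasibility
  (`judgment_matrix()`, `check_consistency()`, `derive_scale()`,
  `derive_weights()`, `validation_ratio()`);
* **valuation** — convert performance to partial values (interpolation
  between anchors, terminal-slope extrapolation beyond them, exact lookup
  for categorical descriptors) and aggregate to global scores with a
  missing-cell log (`partial_value()`, `evaluate()`, `rank_alternatives()`);
* **scenario construction** — build intermediate substitution scenarios by
  convex blending of a reference diet and a full-replacement endpoint
  (`substitution_design()`, `blend_scenario()`, `blend_table()`);
* **sensitivity & robustness** — single-weight sensitivity with closed-form
  crossover detection, and pairwise dominance under interval uncertainty on
  partial values computed exactly at box vertices (`weight_sensitivity()`,
  `recommendation_stability()`, `robustness()`, `uncertainty_box()`);
* **case study** — a packaged 14-criterion beef-to-pulses model with the
  published evidence, partial values and global scores for Portugal and
  Denmark (`case_study()`, `case_study_evaluation()`);
* **I/O and CLI** — versioned JSON model files, CSV performance tables
  (European decimal commas and Unicode minus normalized on ingest), JSON
  reports with model checksums, and a command-line wrapper
  (`inst/cli/dietmcda`) with `evaluate`, `rank`, `derive-scale`,
  `derive-weights`, `sensitivity`, `robustness`, `scenarios` and
  `case-study` subcommands.

## Worked example

Score the Portuguese substitution scenarios from the published partial
values and weights:

```r
library(dietmcda)

cs <- case_study("PT")
res <- evaluate(cs$model, partial_overrides = cs$partials)
res
#> <evaluation_result>
#>   global scores (ranked):
#>     100%     102.37
#>     75%       80.06
#>     50%       57.05
#>     25%       40.89
#>     0%        16.35
```

Full substitution scores 102.37 points — comfortably above the
"good-everywhere" mark of 100 — and every increment of substitution adds
value; the reference diet sits near the minimally-acceptable mark. (The
0% score is the recomputed value; `cs$globals` lists published next to
recomputed scores and flags the three published rows that are not
reproducible from their own partials.)

Is the recommendation fragile? Vary the water-use weight over the whole
unit interval, and perturb the three most uncertain criteria by ±25 points:

```r
recommendation_stability(cs$model, cs$partials, "water_use")
#> <stability_result> water_use: top alternative '100%' stable for all weights in [0, 1]

box <- uncertainty_box(cs$model, cs$partials,
                       c("diet_health", "env_health", "acceptance"), 25)
robustness(cs$model, cs$partials, box)["100%", ]
#>                 100%                  75%                  50%
#>                   "" "robustly_preferred" "robustly_preferred"
#>                  25%                   0%
#> "robustly_preferred" "robustly_preferred"
```

Derive a cardinal scale from qualitative judgments:

```r
jm <- judgment_matrix(c("L1", "L2", "L3"),
                      data.frame(a = c("L1", "L2", "L1"),
                                 b = c("L2", "L3", "L3"),
                                 category = c("moderate", "weak", "very strong")))
derive_scale(jm, neutral = "L3", good = "L1")
#>   entity value
#> 1     L1   100
#> 2     L2    40
#> 3     L3     0
```

The same pipeline runs from a shell:

```sh
inst/cli/dietmcda case-study --country PT --recompute
```

## Documentation

The methods vignette (`vignettes/beef-pulses-value-model.Rmd`) describes
the model and its assumptions, the MACBETH constraint system and the
minimum-norm scale selection, missing-data and extrapolation conventions,
the sensitivity/robustness machinery, the fixture provenance notes, and
the synthetic generators used for property testing.
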