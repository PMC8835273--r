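# parkbbn

Community sports parks are built to get neighbours exercising together, but
*which* spaces actually foster social interaction — the fitness-equipment
corners, the paths, or the sports courts — and through which causal chain?
`parkbbn` implements a complete, testable pipeline for that question, built
around a field study of three community sports parks in Chongqing that were
divided into 35 spatial study units of three space types. It is aimed at
researchers in urban green-space epidemiology and environment–behaviour
studies who work with behaviour-mapping observations and short engagement
questionnaires.

## What it computes

**Interaction metrics.** Social interaction is measured on two dimensions.
The crowds-congregate index of an observation session is

    R = [ Σ_{i=1..N} (B_i / A) · ln T_i ] / ( N · lg S )

where the sum runs over all `N` people present, `B_i` is the size of person
*i*'s congregate group, `T_i` the group's congregate time in minutes (capped
by the 60-minute observation window), `S` the unit area in m², and
`A = (A_start + A_end)/2` the average crowd total over the window.
Engagement with the park is the mean of three 1–7 questionnaire items
(participation intensity, preference, visit frequency).

**Spatial indicators.** Space enclosure `L1/L`, tree cover `S1/S`,
125°-panorama fractions (visual obstacles, green view index), and
Shannon–Wiener vegetation diversity `H = −Σ P_i ln P_i`.

**Belief networks.** Measurements are discretized into ordered categories
(half-open bins, last bin closed) and modelled per space type with a
discrete Bayesian belief network: exact inference by variable elimination,
CPT learning by EM (exact completion-based E-step for missing cells),
prior-constrained random structure search ("spatial factors → activity type
→ social interaction" tiers), held-out selection by accuracy with log-loss
tie-break, and Netica-style mutual-information (entropy-reduction)
sensitivity rankings.

**Synthetic data.** Because the original field data are not deposited, the
package carries ground-truth generator networks per space type — edges
following the published influence mechanisms, CPTs calibrated to the
published conditional-probability tables — so every stage of the pipeline
is exercised against a known truth.

## Worked example

```r
library(parkbbn)

units <- load_spatial_units()
sim <- simulate_sessions(units, seed = 1)
rank_space_types(summarize_by_space_type(sim$sessions, sim$responses, units))
#>          space_type n_sessions congregate_mean engagement_mean
#> 2      sports_court         84       0.5422888        4.638095
#> 3              path         66       0.5004760        4.206061
#> 1 fitness_equipment         60       0.4326524        4.503333
```

Sports-court space ranks first on both congregate level and engagement —
the ordering the generator is calibrated to. Learning a network for one
space type:

```r
ds <- sample_records(scenario_config("fitness_equipment", n_records = 1500,
                                     seed = 1))
sp <- split_dataset(ds, test_fraction = 0.3, seed = 1)
res <- search_structures(sp$train, sp$test,
                         default_constraints(ds$specs),
                         targets = c("crowds_congregate", "engagement"),
                         n_candidates = 60, seed = 1)
res$best$metrics
#>              target log_loss  accuracy n_test
#> 1 crowds_congregate 1.491338 0.2844444    450
#> 2        engagement 1.107169 0.3777778    450

sensitivity_table(res$best$fitted, "crowds_congregate")
#> <sensitivity_report> target 'crowds_congregate' (H = 2.2216 bits)
#>            variable      mi_bits percent_entropy_reduction
#> 1 physical_activity 3.580181e-02              1.611518e+00
#> 2               age 2.918459e-04              1.313663e-02
#> ...
```

The accuracy figures are what a survey-calibrated (deliberately
weak-effect) generator supports; the log loss of ~1.49 sits below the
uniform five-level baseline `ln 5 ≈ 1.609`, i.e. the learned network
carries real predictive signal. `run_pipeline()` chains all stages for all
three space types and writes the full report bundle (selected networks,
candidate ledgers, CPT exports in percent, sensitivity tables, ranking).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the complete demonstration analysis from scratch — samples
records from the packaged generators for each space type, runs the
split/search/selection loop, the sensitivity analysis, and the
session-level space-type ranking — printing a run summary and writing the
results JSON.
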