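---
title: "Methods: modelling social interaction in community sports parks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling social interaction in community sports parks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkbbn)
```

## The problem and the measurement model

Community sports parks bundle three kinds of space — fitness-equipment
areas, paths, and sports courts — and the question the package addresses is
how the spatial make-up of each space type shapes social interaction.
Interaction is operationalized on two dimensions. *Crowds congregate*
captures the opportunity for contact: for one behaviour-mapping session in
a study unit,

$$R = \frac{\sum_{i=1}^{N} (B_i / A)\,\ln T_i}{N \,\log_{10} S},$$

summing over all $N$ people present, with $B_i$ the person's congregate
group size, $T_i$ the group's congregate time in minutes, $S$ the unit area
in m², and $A$ the mean of the crowd totals at the start and end of the
interaction window. *Engagement with the park* captures intensity: the mean
of three 1–7 questionnaire items.

Assumptions worth making explicit:

* Times are restricted to the 1–60 minute observation window. Values
  outside it are an error, not silently capped, so the windowing rule is
  enforced where the data are recorded. $T \ge 1$ and $S > 1$ m² jointly
  guarantee $R \ge 0$.
* The formula's grouping is read as numerator $\sum (B_i/A)\ln T_i$ over
  denominator $N \log_{10} S$ — the only grouping under which the
  denominator acts as the intended per-person, per-log-area normalizer.
  "lg" is base-10, "ln" natural.
* The crowd total $A$ is a session-level constant (it is defined from the
  start/end totals only), and solitary visitors enter the sum with
  $B = 1$: the sum runs over all $N$ present, and excluding singletons
  would contradict $N$'s definition.

## Discretization

Continuous measurements enter the network as ordered categories. Bins are
half-open $[\text{lower}, \text{upper})$ with the last bin closed: the
published category systems print touching integer bins ("0–10", "11–20"),
and normalizing at each bin's printed lower bound removes gap/overlap
ambiguity for non-integer measurements. Two consequences: a vegetation
diversity of exactly 1.8 belongs to the higher "1.8–2.1" bin (the printed
bins overlap at 1.8), and a count of exactly 3 courts or 3 play equipment
falls in "many" (the published wording — "more than three" vs "one or
two" — leaves 3 unassigned; assigning it upward preserves ordinal
continuity).

The two interaction variables have no published numeric edges. Their 5
(congregate) and 3 (engagement) levels are cut by equal-frequency
(quantile) binning computed on the training split and frozen for the test
split — reproducible and scale-free; explicit edges can be supplied
instead. Several spatial variables also lack printed edges (accessibility,
enclosure, tree cover, green view, shrub area, fitness-equipment count);
the packaged edges for those are one-time choices at field-realistic
scales (e.g. accessibility near/medium/far at 30 m and 80 m walking
distance; tree cover low/medium/high at 0.2 and 0.5) and are documented in
the fixture.

Missing cells are an explicit storage-level sentinel (`NA`/empty CSV
cell), never a modelled category.

## The belief-network engine

Each space type gets its own network (never pooled). A network is a DAG
over the categorical variables plus one CPT per node. Inference is exact
variable elimination with a min-fill elimination order and alphabetical
tie-break — determinism matters more than optimality at ≤ 20 nodes.
Posteriors, evidence probabilities, and record log-likelihoods (missing
cells marginalized exactly) all route through it; during candidate
evaluation, records whose non-target variables are fully observed use the
equivalent Markov-blanket product shortcut.

CPTs are fitted by EM. The E-step enumerates each incomplete record's
completions and distributes the record over them in exact posterior
proportion; the M-step renormalizes expected counts with a Dirichlet
pseudo-count added to every cell. Numerical choices, all exposed:
seeded random (uniform-Dirichlet) initialization, relative log-likelihood
tolerance $10^{-6}$, iteration cap 500, default pseudo-count 1 (in the
spirit of Netica-style experience tables; it prevents zero rows — the
exact proprietary smoothing is not reproduced). With a positive
pseudo-count the M-step maximizes the MAP objective, so the *observed*
log-likelihood is guaranteed non-decreasing only for pseudo-count 0; the
tests assert strict monotonicity in that maximum-likelihood setting. On
complete data one M-step reproduces the smoothed relative frequencies
exactly, and the implementation short-circuits to that closed form. In
evaluation, predicted probabilities are floored at $10^{-9}$ before logs
so sparse test sets keep finite log loss.

## Structure search

Search follows a three-step recipe: a draft DAG from prior knowledge,
random candidate generation, and held-out selection.

* **Priors.** Variables are tiered — spatial and individual factors,
  then activity type, then the two interaction variables — and edges
  against the tier direction are forbidden (edges within a tier are
  allowed, e.g. congregate → engagement). The default draft also requires
  the mediation edges (physical activity → crowds congregate, leisure
  activity → engagement), reflecting the "spatial factors → activity type
  → social interaction" mechanism the field study starts from;
  `required_mediation = FALSE` yields an uninformed tier-only search.
* **Candidates.** The published procedure fixes no split fraction,
  candidate count, or mutation kernel. Defaults here: test fraction 0.3,
  200 candidates, random walks of single-edge add/remove/reverse moves of
  geometric length (mean 8) from the draft, at most 4 parents per node,
  deduplicated, deterministic under seed.
* **Selection.** Accuracy on the held-out targets is primary, mean log
  loss breaks ties, then fewer edges — mirroring the dual reporting of
  accuracy and logarithmic loss in this literature.

A caveat the package is explicit about: with an uninformed draft, this
random-walk kernel is not a consistent structure learner at these budgets
(in internal runs it retained the true mediation edge in ~7/10 seeded
replicates at $n = 5000$ with strong effects). With the prior-knowledge
draft — how the procedure is defined to run — required edges are always
present, and the search's value lies in selecting among elaborations. The
test suite therefore verifies the informative signal separately: the
generating structure dominates an edgeless one on held-out log loss, and
more training data never hurts the selected model.

## Sensitivity analysis

Influence strength is mutual information between a findings variable and a
target, computed from the exact pairwise joint — the entropy-reduction
measure popularized by Netica — reported in bits together with percent of
target entropy. Both forms are reported deliberately: published sensitivity
magnitudes in this literature sometimes exceed the entropy bound of a
5-state variable (e.g. values above $\log_2 5 \approx 2.32$), so their
units are ambiguous; bits are well-defined and percent is
unit-free. Sensitivity is computed at the prior by default, optionally
under evidence.

## The synthetic world

No field data are deposited, so the package generates data with the
statistical structure the analysis assumes.

* **Ground-truth networks** per space type use the published influence
  mechanisms as edges. Where the published conditional-probability tables
  print a single-parent slice for a child, the full CPT row for a joint
  parent configuration is the additive (ANOVA-style) combination of the
  printed slices — slices in, slices out: marginalizing the constructed
  CPT over uniform co-parents returns each printed slice to within ~2
  percentage points, the printed tables' own rounding inconsistency.
  Unprinted tables are seeded Dirichlet(1) draws from a frozen build seed,
  root marginals uniform. A second, `"strong"` parameterization replaces
  every non-root table with mode-rotation rows (mode mass 0.7, pairwise
  total variation ≥ 0.3) for recovery studies — the calibrated tables are
  deliberately weak (total variation ~0.1), which is also why realistic
  held-out accuracies sit near the majority-class baseline rather than the
  published 56–78%.
* **Sessions and questionnaires** are drawn so the per-type means of the
  computed congregate index and engagement score match the published
  means (congregate 0.550/0.503/0.426 and engagement 4.69/4.27/4.42 for
  sports court / path / fitness equipment); group times are log-normal
  around the value that hits the target, truncated to the observation
  window, with groups kept large enough (1–2 per session) that truncation
  does not bias the ordering. Unit areas and crowd sizes use
  field-realistic per-type ranges (sports courts congregate the largest
  groups).
* **Missingness** is MCAR only, and the default rate is 0: the field
  questionnaires were screened for validity, so missingness injection is
  an opt-in for exercising the EM path.
* The unit-to-park assignment in the packaged inventory is a synthetic
  stand-in (blocks proportional to park area); the published record maps
  units to space types and subtypes but not to parks. Space-type
  membership is exact.

What a green test establishes: the pipeline's math (formulas, inference,
EM, MI) is exact against brute-force oracles, and the end-to-end chain
recovers what the generator put in. What it does not establish: the
generator's joint distribution of spatial variables across 35 real units
(unknown — roots are uniform), observer effects in behaviour mapping, or
any data-dependent published number (means, accuracies, sensitivity
values), which are irreproducible without the raw data and are treated as
context, not targets.

## Degenerate inputs and tie-breaks

Sessions with no crowd at either endpoint are an error (the index is
undefined); unit areas ≤ 1 m² are rejected (the log-area normalizer
degenerates). Prediction argmax ties break to the lowest state index.
Equal-mean space types keep input order in rankings. Zero-probability
evidence raises an impossible-evidence error rather than returning NaNs.
EM with pseudo-count 0 renders unobserved parent configurations uniform.

## Known limitations

* The E-step enumerates per-record completions; it is exact but scales
  with the product of missing-variable cardinalities, so heavily missing
  wide records are guarded by a completion cap.
* The search kernel is the published-style random mutation walk, not a
  score-decomposable hill climber; no bootstrap edge confidence, no
  approximate inference, no continuous nodes.
* Published sensitivity magnitudes and accuracies are not reproduction
  targets (no raw data); the package reproduces the *procedure*, with the
  bookkeeping facts (35 units; 124 + 133 + 96 = 353 valid questionnaires)
  and all mathematical contracts under test.
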