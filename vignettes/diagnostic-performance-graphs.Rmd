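---
title: "Modelling diagnostic performance indicators and their estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diagnostic performance indicators and their estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesdx)
reset_ids()
```

## The problem

Diagnostic accuracy studies report sensitivity, specificity, positive and
negative predictive values — the Bayesian indicators of performance of a
medical test. Three distinct things hide behind a phrase like "the
sensitivity is 83.8%":

1. a **measurement in a sample**: the proportion, among members of a sample
   `s` who tested positive to a reference test `RT`, of those who tested
   positive to the index test `IT`;
2. an **estimate**: a data item asserting something about a population on
   the basis of that measurement; and
3. the **real population value**: the proportion of diseased people in the
   whole target population `g` who *would* test positive *were the test
   performed on them* — a counterfactual quantity that no study observes
   directly.

`bayesdx` keeps these three apart. Measurements come from recorded test
executions; estimates are data items with explicit aboutness and provenance;
and the real value is carried by a *disposition* borne by the population,
whose probability is defined by exhaustive evaluation over the population's
members. This bookkeeping is what makes two practical operations safe:
deciding which estimates apply to which patients, and deciding which
estimates may be pooled.

Because test response probabilities vary across subgroups (disease severity,
age, sex, ...), the real sensitivity of one and the same test differs
between populations that mix those subgroups differently — the **spectrum
effect**. The package's simulator makes this concrete.

## The model

Every person `i` in a synthetic population carries a latent disease status
and, for each test `T`, a probability `p_{T,i}` of a positive result were
`T` performed. The population-level quantities are defined by exhaustive
evaluation, never by simulation:

* prevalence: fraction of diseased members;
* true (disease-linked) sensitivity: `mean(p_IT)` over diseased members;
  specificity: `mean(1 - p_IT)` over healthy members;
* true PPV / NPV: ratios of expected counts, e.g.
  `sum(p_IT | diseased) / sum(p_IT)`;
* the reference-linked proportion actually targeted by a study:
  `sum(p_RT * p_IT) / sum(p_RT)` over **all** members, using conditional
  independence of the two tests given the person.

The last quantity is what the sample measurement converges to as the sample
grows; it equals the disease-linked value exactly when the reference test
is perfect (`p_RT = 1` for diseased, `0` for healthy), and differs otherwise
— an imperfect reference is a bias, not noise, and no sample size removes
it. Note it is defined as a ratio of expectations, not the expectation of
the per-study ratio; the two agree as populations grow and the ratio form
is the one that is exact under exhaustive evaluation.

```{r spectrum}
pop <- build_population(rf_population_spec(), "IT_rf", "RT_clinical")
true_sensitivity(pop)$value   # 0.8 by construction: 80/20 subgroup split
```

The rheumatoid-factor fixture is the canonical spectrum-effect example: all
members are diseased, 80% would certainly test positive and 20% certainly
negative, so true sensitivity is exactly 0.80 — and reweighting the
subgroups moves it.

### Dispositions and the randomization reading

The real indicator value is formalized as the probability of a disposition
borne by the population: the disposition to draw, under a kind-specific
trigger (e.g. "perform `IT` on everyone in `g`, then draw one diseased
member at random"), an individual realizing the kind-specific outcome
("the drawn member is `IT`-positive"). For a finite population this
probability *is* the exhaustively computed proportion, which the package
asserts as an exact identity for all five kinds:

```{r randomization}
demo <- build_population(randomization_demo_spec(), "IT1", "RT1")
make_disposition(demo, "prevalence", "M")$probability    # exactly 0.10
make_disposition(demo, "sensitivity", "M")$probability   # exactly 0.15
```

Whether the idealized draw is with or without replacement is immaterial
here: a single draw is made, and the two schemes coincide.

### Estimates, Bayes' equations, aggregation

Estimators are the defining sample proportions (`tp/(tp+fn)` etc.), with a
Wilson score interval by default (good coverage at small `n`, never leaves
`[0,1]`); exact Clopper–Pearson is available via `ci_method`. Zero
denominators raise errors: the proportions are undefined there, and a
silent 0 or `NA` would propagate a wrong claim. No continuity correction is
applied to intervals.

Predictive values follow from prevalence, sensitivity and specificity by
Bayes' equations; plugging a table's own three estimates into them returns
the table's direct PPV and NPV exactly (an arithmetic identity, checked to
`1e-12`).

Pooling several estimates into a finer one is only meaningful when the
index tests fall under a common declared index-test class, the reference
tests under a common reference-test class, and the source populations under
a common encompassing population; `check_compatibility()` verifies exactly
this against the declared hierarchies (lowest common ancestor in each
forest; disjoint trees are incompatible, and the package never guesses
similarity that was not declared). The pooling function itself is
statistically open-ended; two auditable defaults are provided:

* `pooled_counts` — sum numerators and denominators; exactly equals
  re-estimating on the cell-wise summed table;
* `inverse_variance_logit` — fixed-effect inverse-variance pooling on the
  logit scale; when any input proportion is 0 or 1, a continuity correction
  of 0.5 is added to both cells of every input and recorded in the output's
  `method` field.

Random-effects and bivariate sensitivity/specificity meta-analysis are out
of scope by design.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `level` | all estimators | 0.95 | the conventional reporting level |
| `ci_method` | all estimators | `"wilson"` | small-`n` coverage, bounded |
| `diseased_fraction` | subgroup specs | — | deterministic count `round(size * fraction)`, so true values are exact |
| response probabilities | subgroup specs | perfect reference | isolates index-test behaviour unless reference error is the object of study |
| `seed` | sampling, execution | explicit everywhere | reproducibility; helpers restore the caller's RNG state |

## What the simulator does and does not emulate

The generator reproduces subgroup-structured response heterogeneity (the
spectrum effect), imperfect reference tests, finite-population sampling
without replacement, and per-person stochastic test results. It
deliberately does **not** model: continuous test traits with thresholds
(persons are dichotomized at the response-probability level), within-person
correlation between index and reference results (responses are
conditionally independent given the person), verification bias, or
latent-class correction for an imperfect reference. Passing tests therefore
show correctness of the estimators and bookkeeping under this generative
model — not robustness to correlated test errors or workup bias in real
studies.

Diseased counts per subgroup are deterministic rounding rather than
binomial draws so that true proportions are exact and identity checks can
be asserted without tolerance.

## Numerical and design choices

* **Problem sizes.** The convergence experiment uses a population of
  20,000, sample sizes {50, 200, 1000} and 200 replicates per size; the
  mean absolute deviation of the sample proportion from its population
  target decreases along the grid and stays below the binomial
  standard-error envelope `sqrt(f3(1-f3)/n)` (valid here because the
  convergence fixture's perfect reference makes every sampled member
  reference-positive, so the denominator is the full sample).
* **Identity tolerances.** Exact identities (randomization, pooled counts,
  perfect-reference equality, Bayes-vs-table) are asserted at `1e-12` or
  `identical()`; they are arithmetic, not statistical.
* **Graph determinism.** Serialized Turtle is sorted
  (subject, predicate, object) and probabilities are written as
  `xsd:decimal` with 12 significant digits, so output is byte-stable.
* **Closed vocabulary.** The instance graph admits only the fixed relation
  set (`instance_of`, `part_of`, `participates_in`,
  `has_specified_input/output`, `is_about`, the kind-specific
  `*_of_test`/`*_for_disease` relations, ...) plus a fixed list of datatype
  properties; foreign predicates are parse-time errors. The
  `se_of_test`-style relations are kept as primitives — reducing them to
  foundational relations is an open theoretical question, and the flat
  relations are what applications need.
* **Degenerate inputs.** Empty samples, empty denominators, indeterminate
  results, duplicated processes, cyclic `part_of` chains and mixed-kind
  aggregations are all rejected with classed errors; graph violations are
  returned as data (a validation report), not exceptions.

## A worked study

```{r study}
reset_ids()
pop <- build_population(albuminuria_study_spec(), "IT1", "RT1")
s <- sample_population(pop, 204, seed = 42)
res <- execute_tests(s, seed = 43)
res$table
d <- make_disposition(pop, "sensitivity", "M_albuminuria")
est <- estimate_sensitivity(res$table, d)
est
d$probability  # the real value the estimate is about
```

The study configuration (2040 diabetic patients, albuminuria prevalence
0.30, a point-of-care index test with sensitivity 0.838 and false-positive
rate 0.05 against a near-perfect laboratory reference) is this package's
own plausible choice of a single dipstick-accuracy study; executing both
tests on the 204 sampled patients creates exactly 408 test processes, and
the full graph — registry, population, sample, execution, results, the
disposition and the estimate with its computation — validates and
round-trips through Turtle losslessly.

## Known limitations

* Sample "representativeness" is a modelling assumption controlled by the
  user; the package offers no statistical test of it.
* Confidence intervals quantify sampling uncertainty only; the gap between
  the reference-linked proportion and the disease-linked one (an imperfect
  reference test) is not folded into the interval.
* The instance graph performs no class-level reasoning beyond the declared
  parent chains; it is a data structure, not a reasoner.
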