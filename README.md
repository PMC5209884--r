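# bayesdx

Typed instance graphs and estimation for the Bayesian indicators of
diagnostic test performance: sensitivity, specificity, positive and
negative predictive values, and prevalence.

## Why

A reported "sensitivity of 83.8%" conflates three different entities: a
proportion *measured* in a sample against a reference test, the *estimate*
(a data item) built from it, and the *real* population value — the
proportion of diseased people in the target population who **would** test
positive were the test performed on them. The real value depends on the
population: subgroups differ in their response probabilities, so the same
test has different sensitivity in differently composed populations (the
*spectrum effect*). `bayesdx` is for biostatisticians and ontology-minded
methodologists who want this bookkeeping to be explicit and machine-checked:

* **Core model** — populations, samples, test processes, executions, 2×2
  results, dispositions and estimates, linked in an instance graph over a
  closed relation vocabulary (`part_of`, `participates_in`,
  `has_specified_input/output`, `is_about`, `se_of_test`, ...), with a
  validator for dangling references, `part_of` cycles, missing aboutness
  and kind mismatches.
* **Estimation** — `Se = tp/(tp+fn)`, `Sp = tn/(tn+fp)`,
  `PPV = tp/(tp+fp)`, `NPV = tn/(tn+fn)`, `Prev = (tp+fn)/n`, with Wilson
  (default) or Clopper–Pearson intervals.
* **Bayes engine** —
  `PPV = Prev·Se / (Prev·Se + (1−Prev)(1−Sp))` and
  `NPV = (1−Prev)·Sp / (Prev(1−Se) + (1−Prev)·Sp)`, plus the exact
  consistency identity against any 2×2 table.
* **Aggregation** — pooling of estimates guarded by a compatibility check
  (common subsuming index-test class, reference-test class and encompassing
  population); pooled counts (exact) or fixed-effect inverse-variance on
  logits.
* **Simulator** — subgroup-structured populations with latent response
  probabilities; true values computed by exhaustive evaluation; sampling,
  test execution and convergence experiments, all seed-deterministic.
* **Turtle I/O** — deterministic serialization of the instance graph to
  W3C Turtle over a minted vocabulary, with a strict round-tripping parser.

## Worked example

```r
library(bayesdx)
reset_ids()

# a synthetic dipstick-vs-laboratory-ACR study in 2040 diabetic patients
pop <- build_population(albuminuria_study_spec(), "IT1", "RT1")
s   <- sample_population(pop, 204, seed = 42)
res <- execute_tests(s, seed = 43)
res$table
#> <2x2 table tbl_1> tp=52 fp=7 fn=16 tn=129 (n=204)

d   <- make_disposition(pop, "sensitivity", "M_albuminuria")
est <- estimate_sensitivity(res$table, d)
est
#> <sensitivity estimate estimate_1> 52/68 = 0.7647 [0.6514, 0.8497] (95%) via proportion/wilson
d$probability          # the real value the estimate is about
#> [1] 0.838

ppv_from_bayes(0.1, 0.8, 0.9)
#> [1] 0.4705882
```

52 of the 68 reference-positive sampled patients were index-positive, so
the measured proportion is 0.7647 (Wilson 95% CI 0.651–0.850); it estimates
the population's true reference-linked sensitivity, which the simulator
knows exactly (0.838 disease-linked). The graph of the whole study —
registry, population, sample, the 408 test processes, results, disposition
and estimate — validates and serializes to Turtle:

```r
g <- instance_graph()
for (x in list(albuminuria_registry(), pop, s, res$execution, res$table, d, est))
  g <- ig_add(g, x)
validate_instance_graph(g)
#> <validation: graph is valid>
writeLines(substr(to_turtle(g), 1, 120))
```

A thin command-line wrapper ships in `inst/cli/bdxo.R`
(`bayes`, `estimate`, `simulate`, `validate` subcommands).

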