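test_that("pooled counts equal the member-level recomputation", {
  # two sensitivity tables, (tp=8, fn=2) and (tp=6, fn=4)
  t1 <- contingency_table(8, 0, 2, 0)
  t2 <- contingency_table(6, 0, 4, 0)
  e1 <- estimate_sensitivity(t1)
  e2 <- estimate_sensitivity(t2)
  pooled <- aggregate_estimates(list(e1, e2))
  expect_equal(pooled$value, 0.7)

  # oracle: concatenate the 20 members into one execution and re-measure
  idx <- c(rep("positive", 8), rep("negative", 2),
           rep("positive", 6), rep("negative", 4))
  ex <- build_tests_execution(toy_sample(20), "IT1", "RT1",
                              toy_results(idx, rep("positive", 20)))
  direct <- estimate_sensitivity(record_tests_results(ex))
  expect_equal(pooled$value, direct$value)
  expect_identical(pooled$inputs, c(e1$id, e2$id))
})

test_that("pooling duplicated estimates is idempotent on the value", {
  e <- estimate_sensitivity(contingency_table(8, 0, 2, 0))
  pooled <- aggregate_estimates(list(e, e))
  expect_equal(pooled$value, e$value)
})

test_that("pooling k tables equals estimating on the summed table", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    tables <- replicate(k, contingency_table(sample(0:30, 1) + 1,
                                             sample(0:30, 1),
                                             sample(0:30, 1),
                                             sample(0:30, 1)),
                        simplify = FALSE)
    ests <- lapply(tables, estimate_sensitivity)
    pooled <- aggregate_estimates(ests)
    summed <- contingency_table(sum(sapply(tables, `[[`, "tp")),
                                sum(sapply(tables, `[[`, "fp")),
                                sum(sapply(tables, `[[`, "fn")),
                                sum(sapply(tables, `[[`, "tn")))
    expect_identical(pooled$value, estimate_sensitivity(summed)$value)
    vals <- vapply(ests, `[[`, numeric(1), "value")
    expect_gte(pooled$value, min(vals))
    expect_lte(pooled$value, max(vals))
  }
})

test_that("compatibility follows the declared hierarchies", {
  fx <- aggregation_fixture()
  rep <- check_compatibility(fx$estimates, fx$registry, fx$graph)
  expect_true(rep$compatible)
  expect_equal(rep$common_index_class, "IT0")
  expect_equal(rep$common_reference_class, "RT0")
  expect_equal(rep$common_population, "g0")

  # single estimate is compatible with its own classes
  rep1 <- check_compatibility(fx$estimates[1], fx$registry, fx$graph)
  expect_true(rep1$compatible)
  expect_equal(rep1$common_index_class, "IT1")

  # disjoint index hierarchies are refused with a recorded reason
  reg2 <- test_registry(
    tests = list(
      test_class("IT1", role = "index", target_disease = "M_albuminuria"),
      test_class("IT2", role = "index", target_disease = "M_albuminuria"),
      test_class("RT0", role = "reference",
                 target_disease = "M_albuminuria"),
      test_class("RT1", role = "reference", parent = "RT0",
                 target_disease = "M_albuminuria"),
      test_class("RT2", role = "reference", parent = "RT0",
                 target_disease = "M_albuminuria")),
    diseases = list(disease_class("M_albuminuria")))
  rep2 <- check_compatibility(fx$estimates, reg2, fx$graph)
  expect_false(rep2$compatible)
  expect_true(any(grepl("no common subsuming class", rep2$reasons)))
  expect_error(
    aggregate_estimates(fx$estimates, registry = reg2, graph = fx$graph),
    class = "bdx_incompatible_estimates")

  # mixed kinds are an error, not an incompatibility report
  sp <- estimate_specificity(contingency_table(5, 2, 3, 40))
  expect_error(check_compatibility(c(fx$estimates[1], list(sp)),
                                   fx$registry),
               class = "bdx_kind_mismatch")
})

test_that("aggregation records provenance in the graph", {
  fx <- aggregation_fixture()
  pooled <- aggregate_estimates(fx$estimates, registry = fx$registry,
                                graph = fx$graph)
  g <- instance_graph()
  for (e in fx$estimates) g <- ig_add(g, e)
  n_process_before <- sum(g$nodes$type == "Planned_process")
  g <- ig_add(g, pooled)
  expect_equal(sum(g$nodes$type == "Planned_process"),
               n_process_before + 1)
  comp <- paste0("comp_", pooled$id)
  inputs <- g$edges[g$edges$subject == comp &
                      g$edges$predicate == "has_specified_input", ]
  outputs <- g$edges[g$edges$subject == comp &
                       g$edges$predicate == "has_specified_output", ]
  expect_setequal(inputs$object, pooled$inputs)
  expect_equal(nrow(outputs), 1)
  expect_equal(outputs$object, pooled$id)
})

test_that("logit pooling agrees with a reference meta-analysis fit", {
  k <- c(42, 18, 77)
  n <- c(60, 30, 100)
  ests <- mapply(function(kk, nn) {
    estimate_sensitivity(contingency_table(kk, 0, nn - kk, 0))
  }, k, n, SIMPLIFY = FALSE)
  pooled <- aggregate_estimates(ests,
                                aggregation_method("inverse_variance_logit"))
  fit <- metafor::rma(measure = "PLO", xi = k, ni = n, method = "FE")
  expect_equal(pooled$value, plogis(as.numeric(fit$beta)),
               tolerance = 1e-10)
  expect_equal(pooled$ci_low, plogis(fit$ci.lb), tolerance = 1e-8)
  expect_equal(pooled$ci_high, plogis(fit$ci.ub), tolerance = 1e-8)
})

test_that("boundary proportions trigger the continuity correction", {
  ests <- list(estimate_sensitivity(contingency_table(10, 0, 0, 0)),
               estimate_sensitivity(contingency_table(8, 0, 2, 0)))
  pooled <- aggregate_estimates(ests,
                                aggregation_method("inverse_variance_logit"))
  expect_match(pooled$method, "cc0.5")
  expect_gt(pooled$value, 0)
  expect_lt(pooled$value, 1)
})
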