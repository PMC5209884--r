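test_that("population realization is exact and deterministic", {
  pop <- build_population(randomization_demo_spec(), "IT1", "RT1")
  expect_equal(nrow(pop$members), 1000)
  expect_equal(sum(pop$members$diseased), 100)
  pop2 <- build_population(randomization_demo_spec(), "IT1", "RT1")
  expect_identical(pop$members[-1], pop2$members[-1])
  expect_error(
    build_population(
      population_spec(list(subgroup_spec("x", 0, 0.5, 0.5)), id = "gx")),
    class = "bdx_domain_error")
})

test_that("the rheumatoid-factor population has true sensitivity 0.80", {
  pop <- build_population(rf_population_spec(), "IT_rf", "RT_clinical")
  expect_identical(true_sensitivity(pop)$value, 0.8)
  # deterministic subgroups: every member responds with certainty
  expect_true(all(pop$members$p_index %in% c(0, 1)))
})

test_that("true proportions are the exact means of response probabilities", {
  pop <- build_population(randomization_demo_spec(), "IT1", "RT1")
  expect_identical(true_prevalence(pop)$value, 0.1)
  expect_identical(true_sensitivity(pop)$value, 0.15)
  expect_identical(true_specificity(pop)$value, 0.95)
  healthy_only <- build_population(
    population_spec(list(subgroup_spec("h", 10, 0, 0.5))), "IT", "RT")
  expect_error(true_sensitivity(healthy_only),
               class = "bdx_undefined_proportion")
  diseased_only <- build_population(rf_population_spec(), "IT", "RT")
  expect_error(true_specificity(diseased_only),
               class = "bdx_undefined_proportion")
})

test_that("a perfect reference test makes the linked proportion exact", {
  spec <- population_spec(list(
    subgroup_spec("a", 60, 0.5, 0.8, 0.1),
    subgroup_spec("b", 40, 0.25, 0.5, 0.02)))
  pop <- build_population(spec, "IT", "RT")
  expect_equal(true_rt_linked_proportion(pop, "se")$value,
               true_sensitivity(pop)$value, tolerance = 1e-12)
  expect_equal(true_rt_linked_proportion(pop, "sp")$value,
               true_specificity(pop)$value, tolerance = 1e-12)
})

test_that("reference-test false positives dilute the linked proportion", {
  # 10-person population: 4 diseased (index responds at 0.9), 6 healthy of
  # whom some are reference false positives but never index-positive.
  spec <- population_spec(list(
    subgroup_spec("dis", 4, 1, 0.9, p_ref_pos_given_diseased = 1),
    subgroup_spec("fp_healthy", 6, 0, p_index_pos_given_diseased = 0,
                  p_index_pos_given_healthy = 0,
                  p_ref_pos_given_healthy = 0.5)))
  pop <- build_population(spec, "IT", "RT")
  f2 <- true_sensitivity(pop)$value
  f3 <- true_rt_linked_proportion(pop, "se")$value
  # brute-force enumeration over the 10 members
  num <- den <- 0
  for (i in seq_len(10)) {
    num <- num + pop$members$p_ref[i] * pop$members$p_index[i]
    den <- den + pop$members$p_ref[i]
  }
  expect_equal(f3, num / den, tolerance = 1e-14)
  expect_equal(f3, (4 * 0.9) / (4 + 3))  # 3 expected healthy RT-positives
  expect_lt(f3, f2)

  no_ref <- build_population(population_spec(list(
    subgroup_spec("d", 5, 1, 0.5, p_ref_pos_given_diseased = 0))), "IT", "RT")
  expect_error(true_rt_linked_proportion(no_ref, "se"),
               class = "bdx_undefined_proportion")
})

test_that("disposition probabilities equal the enumerated proportions", {
  spec <- population_spec(list(
    subgroup_spec("a", 50, 0.4, 0.8, 0.1),
    subgroup_spec("b", 50, 0.2, 0.6, 0.05)))
  pop <- build_population(spec, "IT", "RT")
  m <- pop$members
  expect_identical(make_disposition(pop, "prevalence", "M")$probability,
                   mean(m$diseased))
  expect_identical(make_disposition(pop, "sensitivity", "M")$probability,
                   mean(m$p_index[m$diseased]))
  expect_identical(make_disposition(pop, "specificity", "M")$probability,
                   mean(1 - m$p_index[!m$diseased]))
  expect_identical(make_disposition(pop, "ppv", "M")$probability,
                   sum(m$p_index[m$diseased]) / sum(m$p_index))
  expect_identical(make_disposition(pop, "npv", "M")$probability,
                   sum((1 - m$p_index)[!m$diseased]) / sum(1 - m$p_index))
  all_dis <- build_population(rf_population_spec(), "IT", "RT")
  expect_identical(make_disposition(all_dis, "prevalence", "M")$probability,
                   1)
})

test_that("the spectrum effect follows the subgroup-weight closed form", {
  p1 <- 0.9; p2 <- 0.3
  for (w in c(0.2, 0.5, 0.8)) {
    n <- 1000
    spec <- population_spec(list(
      subgroup_spec("hi", round(w * n), 1, p1),
      subgroup_spec("lo", round((1 - w) * n), 1, p2)))
    pop <- build_population(spec, "IT", "RT")
    expect_equal(true_sensitivity(pop)$value, w * p1 + (1 - w) * p2,
                 tolerance = 1e-12)
  }
  # same subgroups, different weights => different sensitivity
  se_a <- true_sensitivity(build_population(population_spec(list(
    subgroup_spec("hi", 800, 1, p1), subgroup_spec("lo", 200, 1, p2))),
    "IT", "RT"))$value
  se_b <- true_sensitivity(build_population(population_spec(list(
    subgroup_spec("hi", 200, 1, p1), subgroup_spec("lo", 800, 1, p2))),
    "IT", "RT"))$value
  expect_false(isTRUE(all.equal(se_a, se_b)))
})

test_that("sampling is seed-deterministic, bounded and without replacement", {
  pop <- build_population(randomization_demo_spec(), "IT1", "RT1")
  s1 <- sample_population(pop, 50, seed = 3)
  s2 <- sample_population(pop, 50, seed = 3)
  expect_identical(s1$member_ids, s2$member_ids)
  expect_false(anyDuplicated(s1$member_ids) > 0)
  s_all <- sample_population(pop, 1000, seed = 1)
  expect_setequal(s_all$member_ids, pop$members$id)
  expect_error(sample_population(pop, 0), class = "bdx_domain_error")
  expect_error(sample_population(pop, 1001), class = "bdx_domain_error")
})

test_that("test execution is reproducible and exact for degenerate draws", {
  pop <- build_population(rf_population_spec(), "IT_rf", "RT_clinical")
  s <- sample_population(pop, 100, seed = 2)
  r1 <- execute_tests(s, seed = 9)
  r2 <- execute_tests(s, seed = 9)
  expect_identical(
    r1$table[c("tp", "fp", "fn", "tn")],
    r2$table[c("tp", "fp", "fn", "tn")])
  # all response probabilities are 0/1: counts are the closed-form ones
  expect_equal(r1$table$tp, 80)
  expect_equal(r1$table$fn, 20)
  expect_equal(r1$table$fp + r1$table$tn, 0)
})

test_that("execution leaves the caller's RNG stream untouched", {
  pop <- build_population(randomization_demo_spec(), "IT1", "RT1")
  set.seed(99)
  before <- .Random.seed
  s <- sample_population(pop, 10, seed = 4)
  invisible(execute_tests(s, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("sample measurements concentrate around the linked proportion", {
  pop <- build_population(spectrum_convergence_spec(4000), "IT", "RT")
  f3 <- true_rt_linked_proportion(pop, "se")$value
  conv <- run_convergence_experiment(pop, c(100, 400), replicates = 100,
                                     seed = 13)
  # mean of f4 within 4 standard errors of f3
  expect_lt(conv$mean_abs_dev[conv$n == 400],
            4 * sqrt(f3 * (1 - f3) / 400))
  expect_equal(conv$excluded, c(0, 0))
  expect_error(run_convergence_experiment(pop, integer(0)),
               class = "bdx_domain_error")
})

test_that("a full census with deterministic responses has zero deviation", {
  pop <- build_population(rf_population_spec(50), "IT", "RT")
  conv <- run_convergence_experiment(pop, nrow(pop$members),
                                     replicates = 5, seed = 1)
  expect_identical(conv$mean_abs_dev, 0)
})

test_that("simulator configurations round-trip through JSON", {
  path <- system.file("extdata", "albuminuria_sim.json", package = "bayesdx")
  spec <- read_population_spec(path)
  pop <- build_population(spec, "IT1", "RT1")
  expect_equal(nrow(pop$members), 2040)
  expect_equal(true_prevalence(pop)$value, 0.3)
  expect_equal(true_sensitivity(pop)$value, 0.838)
})
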