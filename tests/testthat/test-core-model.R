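test_that("an execution holds two processes per member", {
  s <- toy_sample(204)
  results <- toy_results(rep("positive", 204), rep("negative", 204))
  ex <- build_tests_execution(s, "IT1", "RT1", results)
  expect_equal(nrow(ex$processes), 408)
  expect_setequal(unique(ex$processes$test_class), c("IT1", "RT1"))
  expect_equal(sum(ex$processes$test_class == "IT1"), 204)

  s1 <- toy_sample(1)
  ex1 <- build_tests_execution(s1, "IT1", "RT1",
                               toy_results("positive", "positive"))
  expect_equal(nrow(ex1$processes), 2)
})

test_that("malformed result sets are rejected", {
  s <- toy_sample(3)
  expect_error(
    build_tests_execution(s, "IT1", "RT1",
                          toy_results(rep("positive", 2), rep("negative", 2))),
    class = "bdx_input_shape_error")
  expect_error(
    build_tests_execution(s, "IT1", "RT1",
                          toy_results(c("positive", "indeterminate",
                                        "negative"),
                                      rep("negative", 3))),
    class = "bdx_input_shape_error")
  expect_error(
    build_tests_execution(toy_sample(0), "IT1", "RT1",
                          toy_results(character(0), character(0))),
    class = "bdx_input_shape_error")
  expect_error(
    build_tests_execution(s, "IT1", "IT1",
                          toy_results(rep("positive", 3), rep("negative", 3))),
    class = "bdx_input_shape_error")
})

test_that("results recording classifies against the reference test", {
  # index-positive, reference-negative is a false positive
  ex <- build_tests_execution(toy_sample(1), "IT1", "RT1",
                              toy_results("positive", "negative"))
  tbl <- record_tests_results(ex)
  expect_equal(c(tbl$tp, tbl$fp, tbl$fn, tbl$tn), c(0, 1, 0, 0))

  ex <- build_tests_execution(toy_sample(1), "IT1", "RT1",
                              toy_results("positive", "positive"))
  tbl <- record_tests_results(ex)
  expect_equal(c(tbl$tp, tbl$fp, tbl$fn, tbl$tn), c(1, 0, 0, 0))
})

test_that("classification partitions the sample for random executions", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:60, 1)
    s <- toy_sample(n, id = sprintf("s_r%d", rep))
    results <- toy_results(
      sample(c("positive", "negative"), n, replace = TRUE),
      sample(c("positive", "negative"), n, replace = TRUE))
    ex <- build_tests_execution(s, "IT1", "RT1", results)
    expect_equal(nrow(ex$processes), 2 * n)
    tbl <- record_tests_results(ex)
    expect_equal(tbl$tp + tbl$fp + tbl$fn + tbl$tn, n)
    # each member lands in exactly one cell: recompute per member
    ipos <- results$index == "positive"
    rpos <- results$reference == "positive"
    expect_equal(tbl$tp, sum(ipos & rpos))
    expect_equal(tbl$fp, sum(ipos & !rpos))
    expect_equal(tbl$fn, sum(!ipos & rpos))
    expect_equal(tbl$tn, sum(!ipos & !rpos))
  }
})

test_that("a well-formed study graph validates cleanly and idempotently", {
  fx <- study_graph_fixture()
  rep1 <- validate_instance_graph(fx$graph)
  rep2 <- validate_instance_graph(fx$graph)
  expect_true(is_valid_report(rep1))
  expect_true(is_valid_report(rep2))
})

test_that("validation reports estimates without aboutness", {
  g <- instance_graph()
  est <- estimate_sensitivity(contingency_table(3, 0, 1, 0))
  g <- ig_add(g, est)
  g <- bayesdx:::add_node(g, est$inputs[[1]], "Data_set")
  report <- validate_instance_graph(g)
  expect_false(is_valid_report(report))
  expect_true("missing_is_about" %in% report$rule)
})

test_that("validation reports part_of cycles and dangling edges", {
  g <- instance_graph()
  g <- bayesdx:::add_node(g, "A", "Collection_of_humans")
  g <- bayesdx:::add_node(g, "B", "Collection_of_humans")
  g <- bayesdx:::add_edge(g, "A", "part_of", "B")
  g <- bayesdx:::add_edge(g, "B", "part_of", "A")
  report <- validate_instance_graph(g)
  expect_true("part_of_cycle" %in% report$rule)

  g2 <- instance_graph()
  g2 <- bayesdx:::add_node(g2, "A", "Human")
  g2 <- bayesdx:::add_edge(g2, "A", "participates_in", "ghost")
  report2 <- validate_instance_graph(g2)
  expect_true("dangling_edge" %in% report2$rule)
})

test_that("validation reports estimate/disposition kind mismatches", {
  fx <- study_graph_fixture(n = 10)
  d_sp <- make_disposition(fx$population, "specificity", "M_albuminuria")
  wrong <- fx$graph
  wrong <- ig_add(wrong, d_sp)
  wrong <- bayesdx:::add_edge(wrong, fx$estimate$id, "is_about", d_sp$id)
  report <- validate_instance_graph(wrong)
  expect_true("kind_mismatch" %in% report$rule)
})

test_that("registry declarations are checked", {
  expect_error(
    test_registry(
      tests = list(test_class("A", role = "index", parent = "B",
                              target_disease = "M"),
                   test_class("B", role = "reference", parent = NULL,
                              target_disease = "M")),
      diseases = list(disease_class("M"))),
    class = "bdx_integrity_error")
  reg <- albuminuria_registry()
  expect_equal(class_ancestors(reg, "IT1"), c("IT1", "IT0"))
  expect_equal(common_test_class(reg, c("IT1", "IT2")), "IT0")
  expect_null(common_test_class(reg, c("IT1", "RT1")))
})
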