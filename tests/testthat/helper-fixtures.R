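# Shared fixture builders. Everything is generated in code; no stored data.

# A tiny sample object without going through the simulator.
toy_sample <- function(n, id = "s_toy", population_id = "g_toy") {
  list(id = id, population_id = population_id,
       member_ids = sprintf("%s_p%d", id, seq_len(n)))
}

# Paired results data frame from two result vectors.
toy_results <- function(index, reference) {
  data.frame(index = index, reference = reference, stringsAsFactors = FALSE)
}

# Independent closed-form Wilson score interval (the oracle for the
# implementation, which goes through prop.test).
wilson_oracle <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = centre - half, high = centre + half)
}

# Complete, valid instance graph for a simulated accuracy study:
# registry + population + sample + execution + table + disposition +
# estimate. Returns the pieces alongside the graph.
study_graph_fixture <- function(n = 20, seed = 11) {
  reg <- albuminuria_registry()
  pop <- build_population(albuminuria_study_spec(), "IT1", "RT1")
  s <- sample_population(pop, n, seed = seed)
  res <- execute_tests(s, seed = seed + 1)
  d <- make_disposition(pop, "sensitivity", "M_albuminuria")
  est <- estimate_sensitivity(res$table, d)
  g <- instance_graph()
  g <- ig_add(g, reg)
  g <- ig_add(g, pop)
  g <- ig_add(g, s)
  g <- ig_add(g, res$execution)
  g <- ig_add(g, res$table)
  g <- ig_add(g, d)
  g <- ig_add(g, est)
  list(graph = g, registry = reg, population = pop, sample = s,
       execution = res$execution, table = res$table, disposition = d,
       estimate = est)
}

# Two estimates from distinct samples of populations g1 and g2, both part of
# g0, with index tests IT1/IT2 under IT0 and references RT1/RT2 under RT0 —
# the canonical aggregation setting.
aggregation_fixture <- function(seed = 5) {
  reg <- albuminuria_registry()
  spec1 <- population_spec(list(
    subgroup_spec("a", 400, 0.3, 0.85, 0.05, 0.98, 0.02)), id = "g1")
  spec2 <- population_spec(list(
    subgroup_spec("b", 400, 0.25, 0.80, 0.06, 0.98, 0.02)), id = "g2")
  pop1 <- build_population(spec1, "IT1", "RT1", parent_id = "g0")
  pop2 <- build_population(spec2, "IT2", "RT2", parent_id = "g0")
  s1 <- sample_population(pop1, 120, seed = seed)
  s2 <- sample_population(pop2, 150, seed = seed + 1)
  r1 <- execute_tests(s1, seed = seed + 2)
  r2 <- execute_tests(s2, seed = seed + 3)
  e1 <- estimate_sensitivity(r1$table)
  e2 <- estimate_sensitivity(r2$table)
  g <- instance_graph()
  g <- ig_add(g, reg)
  g <- ig_add(g, pop1)
  g <- ig_add(g, pop2)
  list(registry = reg, graph = g, estimates = list(e1, e2),
       tables = list(r1$table, r2$table))
}
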