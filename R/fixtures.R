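# Ready-made study configurations used in examples, tests and the vignette.

#' Rheumatoid-factor spectrum-effect population
#'
#' A diseased-only population split into a subgroup certain to test positive
#' to the rheumatoid-factor index test (80% of members) and a subgroup
#' certain to test negative (20%); the reference test is perfect. True
#' sensitivity is exactly 0.80 by construction, and reweighting the two
#' subgroups changes it — the spectrum effect in its purest form.
#'
#' @param n Total population size (default 100; must keep the 80/20 split
#'   integral).
#' @param seed Seed stored in the specification.
#' @return A [population_spec()].
#' @export
#' @examples
#' pop <- build_population(rf_population_spec(), "IT_rf", "RT_clinical")
#' true_sensitivity(pop)$value
rf_population_spec <- function(n = 100, seed = 1L) {
  n <- assert_count(n, "n", positive = TRUE)
  n1 <- round(0.8 * n)
  population_spec(list(
    subgroup_spec("rf_positive", n1, diseased_fraction = 1,
                  p_index_pos_given_diseased = 1),
    subgroup_spec("rf_negative", n - n1, diseased_fraction = 1,
                  p_index_pos_given_diseased = 0)
  ), seed = seed, id = "g_rf")
}

#' Randomization-illustration population
#'
#' One homogeneous subgroup with 10% diseased members, of whom 15% would
#' test index-positive: the prevalence disposition has probability exactly
#' 0.10 and the sensitivity disposition exactly 0.15.
#'
#' @param size Population size (default 1000).
#' @param seed Seed stored in the specification.
#' @return A [population_spec()].
#' @export
randomization_demo_spec <- function(size = 1000, seed = 1L) {
  population_spec(list(
    subgroup_spec("general", size, diseased_fraction = 0.10,
                  p_index_pos_given_diseased = 0.15,
                  p_index_pos_given_healthy = 0.05)
  ), seed = seed, id = "g_demo")
}

#' Albuminuria point-of-care study configuration
#'
#' A synthetic stand-in for a single dipstick-versus-laboratory-ACR accuracy
#' study in diabetic patients: 2040 patients with albuminuria prevalence
#' 0.30, a point-of-care index test with sensitivity 0.838 and false-positive
#' rate 0.05, and a near-perfect laboratory reference (sensitivity 0.98,
#' false-positive rate 0.02). Sampling 204 patients and executing both tests
#' reproduces the structure of such a study: 204 persons, 408 test
#' processes. The response probabilities are this package's own plausible
#' choices; no real patient data are involved.
#'
#' @param seed Seed stored in the specification.
#' @return A [population_spec()].
#' @export
albuminuria_study_spec <- function(seed = 1L) {
  population_spec(list(
    subgroup_spec("diabetic", 2040, diseased_fraction = 0.30,
                  p_index_pos_given_diseased = 0.838,
                  p_index_pos_given_healthy = 0.05,
                  p_ref_pos_given_diseased = 0.98,
                  p_ref_pos_given_healthy = 0.02)
  ), seed = seed, id = "g_diabetic")
}

#' Default test-class registry for the albuminuria example
#'
#' Point-of-care index tests (`IT0`) with two cutoff-specific children
#' (`IT1`, `IT2`) and laboratory ACR reference tests (`RT0`) with two
#' children (`RT1`, `RT2`), all targeting albuminuria.
#'
#' @return A `bdx_registry`.
#' @export
albuminuria_registry <- function() {
  test_registry(
    tests = list(
      test_class("IT0", "point-of-care albuminuria test", "index",
                 target_disease = "M_albuminuria"),
      test_class("IT1", "dipstick, cutoff 3.4 mg/mmol", "index",
                 parent = "IT0", target_disease = "M_albuminuria"),
      test_class("IT2", "dipstick, cutoff 2.65 mg/mmol", "index",
                 parent = "IT0", target_disease = "M_albuminuria"),
      test_class("RT0", "laboratory ACR", "reference",
                 target_disease = "M_albuminuria"),
      test_class("RT1", "laboratory ACR, cutoff 3.4 mg/mmol", "reference",
                 parent = "RT0", target_disease = "M_albuminuria"),
      test_class("RT2", "laboratory ACR, cutoff 2.65 mg/mmol", "reference",
                 parent = "RT0", target_disease = "M_albuminuria")
    ),
    diseases = list(disease_class("M_albuminuria", "albuminuria"))
  )
}

#' Heterogeneous diseased population for convergence experiments
#'
#' Diseased-only population with three severity subgroups whose index-test
#' response probabilities differ (0.95 / 0.70 / 0.40) and a perfect
#' reference test, so the reference-linked proportion equals the
#' disease-linked one and every sampled member is reference-positive.
#'
#' @param size Total size (default 20000), split 50/30/20 across subgroups.
#' @param seed Seed stored in the specification.
#' @return A [population_spec()].
#' @export
spectrum_convergence_spec <- function(size = 20000, seed = 1L) {
  size <- assert_count(size, "size", positive = TRUE)
  population_spec(list(
    subgroup_spec("severe", round(0.5 * size), diseased_fraction = 1,
                  p_index_pos_given_diseased = 0.95),
    subgroup_spec("moderate", round(0.3 * size), diseased_fraction = 1,
                  p_index_pos_given_diseased = 0.70),
    subgroup_spec("mild", round(0.2 * size), diseased_fraction = 1,
                  p_index_pos_given_diseased = 0.40)
  ), seed = seed, id = "g_spectrum")
}
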