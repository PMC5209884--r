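# Point estimates of the indicators of performance from 2x2 tables, with
# binomial confidence intervals. Each estimator is the sample analogue of a
# population proportion: sensitivity is the proportion index-positive among
# reference-positives, specificity the proportion index-negative among
# reference-negatives, and so on.

#' Wilson score confidence interval for a binomial proportion
#'
#' Computed via [stats::prop.test()] without continuity correction; the
#' interval always lies in `[0, 1]` and contains the point estimate.
#'
#' @param successes,trials Non-negative integer counts, `trials > 0`.
#' @param level Confidence level in `(0, 1)`.
#' @return A `bdx_ci` list with `low`, `high`, `level`.
#' @export
#' @examples
#' wilson_interval(8, 10)
wilson_interval <- function(successes, trials, level = 0.95) {
  successes <- assert_count(successes, "successes")
  trials <- assert_count(trials, "trials", positive = TRUE)
  if (successes > trials) {
    bdx_stop("bdx_domain_error", "successes (%d) exceed trials (%d)",
             successes, trials)
  }
  assert_probability(level, "level")
  # the chi-square approximation warning concerns the test, not the interval
  ci <- suppressWarnings(stats::prop.test(successes, trials,
                                          conf.level = level,
                                          correct = FALSE))$conf.int
  structure(list(low = max(0, ci[1]), high = min(1, ci[2]), level = level),
            class = "bdx_ci")
}

#' Exact Clopper-Pearson confidence interval
#'
#' @inheritParams wilson_interval
#' @return A `bdx_ci` list with `low`, `high`, `level`.
#' @export
clopper_pearson_interval <- function(successes, trials, level = 0.95) {
  successes <- assert_count(successes, "successes")
  trials <- assert_count(trials, "trials", positive = TRUE)
  if (successes > trials) {
    bdx_stop("bdx_domain_error", "successes (%d) exceed trials (%d)",
             successes, trials)
  }
  assert_probability(level, "level")
  ci <- stats::binom.test(successes, trials, conf.level = level)$conf.int
  structure(list(low = ci[1], high = ci[2], level = level), class = "bdx_ci")
}

proportion_ci <- function(successes, trials, level, ci_method) {
  switch(match.arg(ci_method, c("wilson", "clopper-pearson")),
         "wilson" = wilson_interval(successes, trials, level),
         "clopper-pearson" = clopper_pearson_interval(successes, trials,
                                                      level))
}

estimate_from_table <- function(table, k, n, kind, about, level, ci_method,
                                what) {
  stopifnot(inherits(table, "bdx_table"))
  if (n == 0) {
    bdx_stop("bdx_undefined_proportion",
             "%s is undefined: empty denominator", what)
  }
  ci <- proportion_ci(k, n, level, ci_method)
  new_ip_estimate(
    kind = kind, value = k / n, ci = ci,
    n_numerator = as.integer(k), n_denominator = as.integer(n),
    about = about, inputs = table$id,
    method = sprintf("proportion/%s", ci_method),
    index_class = table$index_class,
    reference_class = table$reference_class,
    population_id = table$population_id
  )
}

#' Estimate sensitivity from a 2x2 table
#'
#' The sample proportion `tp / (tp + fn)`: among members who tested positive
#' to the reference test, the fraction positive to the index test.
#'
#' @param table A `bdx_table`.
#' @param about Optional [disposition()] of kind `"sensitivity"` the estimate
#'   is about (the real population value it approximates).
#' @param level Confidence level in `(0, 1)`.
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @return A `bdx_estimate`.
#' @export
#' @examples
#' estimate_sensitivity(contingency_table(tp = 3, fp = 0, fn = 1, tn = 0))
estimate_sensitivity <- function(table, about = NULL, level = 0.95,
                                 ci_method = "wilson") {
  estimate_from_table(table, table$tp, table$tp + table$fn, "sensitivity",
                      about, level, ci_method, "sensitivity")
}

#' Estimate specificity from a 2x2 table
#'
#' The sample proportion `tn / (tn + fp)`: among reference-negatives, the
#' fraction negative to the index test.
#'
#' @inheritParams estimate_sensitivity
#' @return A `bdx_estimate`.
#' @export
estimate_specificity <- function(table, about = NULL, level = 0.95,
                                 ci_method = "wilson") {
  estimate_from_table(table, table$tn, table$tn + table$fp, "specificity",
                      about, level, ci_method, "specificity")
}

#' Estimate the positive predictive value from a 2x2 table
#'
#' The proportion of tested positives who are true positives,
#' `tp / (tp + fp)`.
#'
#' @inheritParams estimate_sensitivity
#' @return A `bdx_estimate`.
#' @export
estimate_ppv <- function(table, about = NULL, level = 0.95,
                         ci_method = "wilson") {
  estimate_from_table(table, table$tp, table$tp + table$fp, "ppv",
                      about, level, ci_method, "PPV")
}

#' Estimate the negative predictive value from a 2x2 table
#'
#' The proportion of tested negatives who are true negatives,
#' `tn / (tn + fn)`.
#'
#' @inheritParams estimate_sensitivity
#' @return A `bdx_estimate`.
#' @export
estimate_npv <- function(table, about = NULL, level = 0.95,
                         ci_method = "wilson") {
  estimate_from_table(table, table$tn, table$tn + table$fn, "npv",
                      about, level, ci_method, "NPV")
}

#' Estimate prevalence from a 2x2 table
#'
#' The proportion reference-positive in the whole sample,
#' `(tp + fn) / (tp + fp + fn + tn)` — prevalence as operationalized by the
#' reference test.
#'
#' @inheritParams estimate_sensitivity
#' @return A `bdx_estimate`.
#' @export
estimate_prevalence <- function(table, about = NULL, level = 0.95,
                                ci_method = "wilson") {
  total <- table$tp + table$fp + table$fn + table$tn
  estimate_from_table(table, table$tp + table$fn, total, "prevalence",
                      about, level, ci_method, "prevalence")
}
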