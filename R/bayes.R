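# Bayes' equations linking predictive values to prevalence, sensitivity and
# specificity:
#   PPV = Prev*Se / (Prev*Se + (1-Prev)*(1-Sp))
#   NPV = (1-Prev)*Sp / (Prev*(1-Se) + (1-Prev)*Sp)

#' Positive predictive value from prevalence, sensitivity and specificity
#'
#' @param prev,se,sp Probabilities in `[0, 1]`; out-of-range values raise an
#'   error rather than being clamped.
#' @return The PPV, a probability.
#' @export
#' @examples
#' ppv_from_bayes(0.1, 0.8, 0.9)
ppv_from_bayes <- function(prev, se, sp) {
  assert_probability(prev, "prev")
  assert_probability(se, "se")
  assert_probability(sp, "sp")
  den <- prev * se + (1 - prev) * (1 - sp)
  if (den == 0) {
    bdx_stop("bdx_undefined_value",
             "PPV undefined: no individual can test positive (denominator 0)")
  }
  prev * se / den
}

#' Negative predictive value from prevalence, sensitivity and specificity
#'
#' @inheritParams ppv_from_bayes
#' @return The NPV, a probability.
#' @export
#' @examples
#' npv_from_bayes(0.1, 0.8, 0.9)
npv_from_bayes <- function(prev, se, sp) {
  assert_probability(prev, "prev")
  assert_probability(se, "se")
  assert_probability(sp, "sp")
  den <- prev * (1 - se) + (1 - prev) * sp
  if (den == 0) {
    bdx_stop("bdx_undefined_value",
             "NPV undefined: no individual can test negative (denominator 0)")
  }
  (1 - prev) * sp / den
}

#' Check the algebraic identity between Bayes' equations and a 2x2 table
#'
#' Plugging the table's own prevalence, sensitivity and specificity estimates
#' into Bayes' equations must return exactly the table's direct PPV
#' `tp/(tp+fp)` and NPV `tn/(tn+fn)`; the identity is pure arithmetic. The
#' report carries both discrepancies and whether they stay below `tolerance`.
#'
#' @param table A `bdx_table` with all four marginal denominators positive.
#' @param tolerance Absolute tolerance for the identity (default `1e-12`).
#' @return A `bdx_consistency` list with the Bayes-derived and direct values,
#'   the two absolute discrepancies, their maximum, and `consistent`.
#' @export
#' @examples
#' bayes_table_consistency(contingency_table(80, 90, 20, 810))
bayes_table_consistency <- function(table, tolerance = 1e-12) {
  stopifnot(inherits(table, "bdx_table"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  if (tp + fn == 0 || tn + fp == 0 || tp + fp == 0 || tn + fn == 0) {
    bdx_stop("bdx_undefined_proportion",
             "all four marginal denominators must be positive")
  }
  n <- tp + fp + fn + tn
  prev <- (tp + fn) / n
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  ppv_b <- ppv_from_bayes(prev, se, sp)
  npv_b <- npv_from_bayes(prev, se, sp)
  ppv_t <- tp / (tp + fp)
  npv_t <- tn / (tn + fn)
  out <- list(ppv_bayes = ppv_b, ppv_table = ppv_t,
              npv_bayes = npv_b, npv_table = npv_t,
              ppv_discrepancy = abs(ppv_b - ppv_t),
              npv_discrepancy = abs(npv_b - npv_t))
  out$max_discrepancy <- max(out$ppv_discrepancy, out$npv_discrepancy)
  out$tolerance <- tolerance
  out$consistent <- out$max_discrepancy <= tolerance
  structure(out, class = "bdx_consistency")
}

#' @export
print.bdx_consistency <- function(x, ...) {
  cat(sprintf(
    "<Bayes/table consistency> max discrepancy %.3g (tolerance %.3g): %s\n",
    x$max_discrepancy, x$tolerance,
    if (x$consistent) "consistent" else "INCONSISTENT"))
  invisible(x)
}
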