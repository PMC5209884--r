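# Core instance-level entities: contingency tables, dispositions, estimates.
# Populations, samples and executions live in simulator.R / execution.R.

IP_KINDS <- c("prevalence", "sensitivity", "specificity", "ppv", "npv")

#' Create a 2x2 contingency table
#'
#' Cell conventions follow the standard diagnostic 2x2 layout against the
#' reference test: a true positive is index-positive and reference-positive,
#' a false positive is index-positive but reference-negative, and so on.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @param id Identifier; minted automatically when `NULL`.
#' @param source_execution Identifier of the tests execution the counts were
#'   recorded from, or `NULL` for externally supplied counts.
#' @param index_class,reference_class,sample_id,population_id Optional
#'   provenance identifiers, carried into estimates built from this table.
#' @return A `bdx_table` object.
#' @export
#' @examples
#' contingency_table(tp = 8, fp = 2, fn = 2, tn = 88)
contingency_table <- function(tp, fp, fn, tn, id = NULL,
                              source_execution = NULL,
                              index_class = NULL, reference_class = NULL,
                              sample_id = NULL, population_id = NULL) {
  tp <- assert_count(tp, "tp"); fp <- assert_count(fp, "fp")
  fn <- assert_count(fn, "fn"); tn <- assert_count(tn, "tn")
  structure(list(id = id %||% bdx_id("tbl"),
                 tp = tp, fp = fp, fn = fn, tn = tn,
                 source_execution = source_execution,
                 index_class = index_class,
                 reference_class = reference_class,
                 sample_id = sample_id,
                 population_id = population_id),
            class = "bdx_table")
}

#' @export
print.bdx_table <- function(x, ...) {
  cat(sprintf("<2x2 table %s> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$id, x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Read a 2x2 contingency table from CSV
#'
#' The file must contain a single header line `tp,fp,fn,tn` followed by one
#' row of integer counts.
#'
#' @param path Path to a CSV file.
#' @return A `bdx_table`.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("tp", "fp", "fn", "tn")) || nrow(df) != 1L) {
    bdx_stop("bdx_input_shape_error",
             "counts CSV must have header tp,fp,fn,tn and exactly one row")
  }
  contingency_table(df$tp, df$fp, df$fn, df$tn)
}

# Standard trigger / realization wording for each indicator kind, filled with
# the population, index test and disease identifiers.
disposition_descriptors <- function(kind, bearer_id, index_class, disease) {
  g <- bearer_id; it <- index_class %||% "?"; m <- disease
  switch(kind,
    prevalence = list(
      trigger = sprintf("random draw of an individual in %s", g),
      realization = sprintf(
        "drawing by the trigger of someone who has the disease %s", m)),
    sensitivity = list(
      trigger = sprintf(paste0(
        "performance of test %s on the individuals in %s, and random draw ",
        "of an individual among those who have the disease %s"), it, g, m),
      realization = sprintf(
        "drawing by the trigger of someone who got a positive result to %s",
        it)),
    specificity = list(
      trigger = sprintf(paste0(
        "performance of test %s on the individuals in %s, and random draw ",
        "of an individual among those who do not have the disease %s"),
        it, g, m),
      realization = sprintf(
        "drawing by the trigger of someone who got a negative result to %s",
        it)),
    ppv = list(
      trigger = sprintf(paste0(
        "performance of test %s on the individuals in %s, and random draw ",
        "of an individual among those who got a positive result to %s"),
        it, g, it),
      realization = sprintf(
        "drawing by the trigger of someone who has the disease %s", m)),
    npv = list(
      trigger = sprintf(paste0(
        "performance of test %s on the individuals in %s, and random draw ",
        "of an individual among those who got a negative result to %s"),
        it, g, it),
      realization = sprintf(
        "drawing by the trigger of someone who does not have the disease %s",
        m))
  )
}

#' Create an indicator-of-performance disposition
#'
#' A disposition is borne by a population; its assigned probability is the
#' real (population-level) value of the indicator. A prevalence disposition
#' has no index test; all other kinds require one. Trigger and realization
#' descriptors default to the standard random-draw wording.
#'
#' @param kind One of `"prevalence"`, `"sensitivity"`, `"specificity"`,
#'   `"ppv"`, `"npv"`.
#' @param disease Disease class identifier.
#' @param probability Real indicator value in `[0, 1]`.
#' @param bearer_id Identifier of the bearing population.
#' @param index_class Index test class identifier (`NULL` for prevalence).
#' @param trigger_descriptor,realization_descriptor Free-text descriptions of
#'   the trigger and realization processes; defaulted when `NULL`.
#' @param id Identifier; minted automatically when `NULL`.
#' @return A `bdx_disposition` object. Field `class_id` names the disposition
#'   class (the kind-test-disease universal the disposition instantiates).
#' @export
#' @examples
#' disposition("prevalence", disease = "M", probability = 0.1, bearer_id = "g")
disposition <- function(kind, disease, probability, bearer_id,
                        index_class = NULL,
                        trigger_descriptor = NULL,
                        realization_descriptor = NULL,
                        id = NULL) {
  kind <- match.arg(kind, IP_KINDS)
  assert_string(disease, "disease")
  assert_probability(probability, "probability")
  assert_string(bearer_id, "bearer_id")
  if (kind == "prevalence" && !is.null(index_class)) {
    bdx_stop("bdx_domain_error",
             "a prevalence disposition takes no index test class")
  }
  if (kind != "prevalence" && is.null(index_class)) {
    bdx_stop("bdx_domain_error",
             "a %s disposition requires an index test class", kind)
  }
  desc <- disposition_descriptors(kind, bearer_id, index_class, disease)
  structure(list(
    id = id %||% bdx_id("d"),
    kind = kind,
    bearer_id = bearer_id,
    index_class = index_class,
    disease = disease,
    trigger_descriptor = trigger_descriptor %||% desc$trigger,
    realization_descriptor = realization_descriptor %||% desc$realization,
    probability = probability,
    class_id = sprintf("D_%s_%s_%s", kind, index_class %||% "any", disease)
  ), class = "bdx_disposition")
}

#' @export
print.bdx_disposition <- function(x, ...) {
  cat(sprintf("<%s disposition %s> bearer=%s p=%.6g\n",
              x$kind, x$id, x$bearer_id, x$probability))
  invisible(x)
}

# Internal estimate constructor shared by estimation.R and aggregation.R.
new_ip_estimate <- function(kind, value, ci, n_numerator, n_denominator,
                            about, inputs, method,
                            index_class = NULL, reference_class = NULL,
                            population_id = NULL, id = NULL) {
  kind <- match.arg(kind, IP_KINDS)
  assert_probability(value, "value")
  if (!is.null(about)) {
    stopifnot(inherits(about, "bdx_disposition"))
    if (about$kind != kind) {
      bdx_stop("bdx_kind_mismatch",
               "estimate kind '%s' does not match disposition kind '%s'",
               kind, about$kind)
    }
  }
  if (!is.null(ci) && (ci$low > value + 1e-12 || ci$high < value - 1e-12)) {
    bdx_stop("bdx_integrity_error",
             "confidence interval does not contain the point estimate")
  }
  structure(list(
    id = id %||% bdx_id("estimate"),
    kind = kind,
    value = value,
    ci_low = if (is.null(ci)) NA_real_ else ci$low,
    ci_high = if (is.null(ci)) NA_real_ else ci$high,
    level = if (is.null(ci)) NA_real_ else ci$level,
    n_numerator = n_numerator,
    n_denominator = n_denominator,
    about = if (is.null(about)) NA_character_ else about$id,
    inputs = inputs,
    method = method,
    index_class = index_class,
    reference_class = reference_class,
    population_id = population_id
  ), class = "bdx_estimate")
}

#' @export
print.bdx_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else {
    sprintf(" [%0.4f, %0.4f] (%g%%)", x$ci_low, x$ci_high, 100 * x$level)
  }
  cat(sprintf("<%s estimate %s> %d/%d = %.4f%s via %s\n",
              x$kind, x$id, x$n_numerator, x$n_denominator, x$value, ci,
              x$method))
  invisible(x)
}

#' Write an estimate to JSON
#'
#' Schema:
#' `{"kind","value","ci":[low,high],"level","n","about","inputs","method"}`.
#'
#' @param estimate A `bdx_estimate`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_estimate_json <- function(estimate, path = NULL) {
  stopifnot(inherits(estimate, "bdx_estimate"))
  obj <- list(
    kind = estimate$kind,
    value = estimate$value,
    ci = c(estimate$ci_low, estimate$ci_high),
    level = estimate$level,
    n = estimate$n_denominator,
    about = estimate$about,
    inputs = as.list(estimate$inputs),
    method = estimate$method
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
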