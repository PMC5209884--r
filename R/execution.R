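# Paired index/reference test executions on a sample and the recording of
# their results as a 2x2 table.

#' Build a tests execution from paired results
#'
#' An execution bundles, for every member of the sample, one index-test
#' process and one reference-test process, each with a strictly binary
#' result. Indeterminate results are rejected.
#'
#' @param sample A `bdx_sample` (see [sample_population()]), or any list with
#'   `id`, `population_id` and `member_ids`.
#' @param index_class,reference_class Test class identifiers (or
#'   [test_class()] objects).
#' @param results Data frame with one row per sample member and columns
#'   `index` and `reference`, each `"positive"` or `"negative"`. An optional
#'   `person_id` column matches rows to members; otherwise rows are taken in
#'   member order.
#' @param id Identifier; minted automatically when `NULL`.
#' @return A `bdx_execution` whose `processes` data frame holds the
#'   2 x sample-size test processes.
#' @export
build_tests_execution <- function(sample, index_class, reference_class,
                                  results, id = NULL) {
  member_ids <- sample$member_ids
  if (length(member_ids) == 0) {
    bdx_stop("bdx_input_shape_error", "sample is empty")
  }
  if (is.list(index_class) && !is.null(index_class$id)) {
    index_class <- index_class$id
  }
  if (is.list(reference_class) && !is.null(reference_class$id)) {
    reference_class <- reference_class$id
  }
  assert_string(index_class, "index_class")
  assert_string(reference_class, "reference_class")
  if (identical(index_class, reference_class)) {
    bdx_stop("bdx_input_shape_error",
             "index and reference test classes must differ")
  }
  if (!is.data.frame(results) ||
      !all(c("index", "reference") %in% names(results))) {
    bdx_stop("bdx_input_shape_error",
             "results must be a data frame with columns index and reference")
  }
  if (nrow(results) != length(member_ids)) {
    bdx_stop("bdx_input_shape_error",
             "expected one result pair per member (%d), got %d rows",
             length(member_ids), nrow(results))
  }
  if ("person_id" %in% names(results)) {
    if (!setequal(results$person_id, member_ids) ||
        anyDuplicated(results$person_id)) {
      bdx_stop("bdx_input_shape_error",
               "results person_id does not match the sample members")
    }
    results <- results[match(member_ids, results$person_id), , drop = FALSE]
  }
  ok <- c("positive", "negative")
  if (!all(results$index %in% ok) || !all(results$reference %in% ok)) {
    bdx_stop("bdx_input_shape_error",
             "test results must be 'positive' or 'negative'")
  }
  n <- length(member_ids)
  exec_id <- id %||% bdx_id("exec")
  processes <- data.frame(
    id = c(vapply(seq_len(n), function(i) bdx_id("it_proc"), character(1)),
           vapply(seq_len(n), function(i) bdx_id("rt_proc"), character(1))),
    test_class = rep(c(index_class, reference_class), each = n),
    person_id = rep(member_ids, 2L),
    result = c(results$index, results$reference),
    stringsAsFactors = FALSE
  )
  structure(list(id = exec_id,
                 sample_id = sample$id,
                 population_id = sample$population_id %||% NA_character_,
                 index_class = index_class,
                 reference_class = reference_class,
                 processes = processes),
            class = "bdx_execution")
}

#' @export
print.bdx_execution <- function(x, ...) {
  cat(sprintf("<tests execution %s> sample=%s, %d processes (%s vs %s)\n",
              x$id, x$sample_id, nrow(x$processes), x$index_class,
              x$reference_class))
  invisible(x)
}

#' Record the results of an execution as a 2x2 table
#'
#' Each member is classified against the reference test: true positive
#' (index-positive, reference-positive), false positive (index-positive,
#' reference-negative), false negative (index-negative, reference-positive)
#' or true negative (both negative). The four counts always sum to the
#' sample size.
#'
#' @param execution A `bdx_execution`.
#' @return A `bdx_table` with provenance fields filled from the execution.
#' @export
record_tests_results <- function(execution) {
  stopifnot(inherits(execution, "bdx_execution"))
  pr <- execution$processes
  idx <- pr[pr$test_class == execution$index_class, ]
  ref <- pr[pr$test_class == execution$reference_class, ]
  persons <- unique(pr$person_id)
  if (nrow(idx) != length(persons) || nrow(ref) != length(persons) ||
      anyDuplicated(idx$person_id) || anyDuplicated(ref$person_id)) {
    bdx_stop("bdx_integrity_error",
             "each member needs exactly one index and one reference process")
  }
  ref <- ref[match(idx$person_id, ref$person_id), ]
  ipos <- idx$result == "positive"
  rpos <- ref$result == "positive"
  contingency_table(
    tp = sum(ipos & rpos), fp = sum(ipos & !rpos),
    fn = sum(!ipos & rpos), tn = sum(!ipos & !rpos),
    source_execution = execution$id,
    index_class = execution$index_class,
    reference_class = execution$reference_class,
    sample_id = execution$sample_id,
    population_id = execution$population_id
  )
}
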