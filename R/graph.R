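# The typed instance graph: nodes (id, type), object-property edges over a
# closed relation vocabulary, and datatype-property literals. Entity objects
# are converted to nodes/edges/literals by ig_add() methods; the graph is a
# plain value, so every ig_add() returns an updated copy.

GRAPH_RELATIONS <- c(
  "instance_of", "is_a", "part_of", "participates_in",
  "has_specified_input", "has_specified_output", "is_about",
  "se_of_test", "se_for_disease", "sp_of_test", "sp_for_disease",
  "ppv_of_test", "ppv_for_disease", "npv_of_test", "npv_for_disease"
)

GRAPH_DATA_PROPERTIES <- c(
  "has_specified_value", "has_probability_value", "has_kind", "has_label",
  "has_role", "has_bearer", "tp", "fp", "fn", "tn", "ci_low", "ci_high",
  "confidence_level", "denominator", "has_trigger_description",
  "has_realization_description"
)

GRAPH_TYPES <- c(
  "Disease", "Medical_test", "Collection_of_humans", "Sample_of_humans",
  "Human", "Test_process", "Planned_process", "Data_set", "Data_item",
  "Disposition", "Disposition_class"
)

# relations linking a disposition class to its index test and disease
KIND_RELATIONS <- list(
  sensitivity = c(test = "se_of_test", disease = "se_for_disease"),
  specificity = c(test = "sp_of_test", disease = "sp_for_disease"),
  ppv = c(test = "ppv_of_test", disease = "ppv_for_disease"),
  npv = c(test = "npv_of_test", disease = "npv_for_disease")
)

#' Create an empty instance graph
#'
#' @return A `bdx_graph` with empty `nodes`, `edges` and `literals` tables.
#' @seealso [ig_add()], [validate_instance_graph()], [to_turtle()]
#' @export
instance_graph <- function() {
  structure(list(
    nodes = data.frame(id = character(0), type = character(0),
                       stringsAsFactors = FALSE),
    edges = data.frame(subject = character(0), predicate = character(0),
                       object = character(0), stringsAsFactors = FALSE),
    literals = data.frame(subject = character(0), predicate = character(0),
                          value = character(0), datatype = character(0),
                          stringsAsFactors = FALSE)
  ), class = "bdx_graph")
}

#' @export
print.bdx_graph <- function(x, ...) {
  cat(sprintf("<instance graph> %d nodes, %d edges, %d literals\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$literals)))
  invisible(x)
}

add_node <- function(g, id, type) {
  check_local_name(id)
  if (!type %in% GRAPH_TYPES) {
    bdx_stop("bdx_vocabulary_error", "unknown node type '%s'", type)
  }
  i <- match(id, g$nodes$id)
  if (!is.na(i)) {
    if (g$nodes$type[i] != type) {
      bdx_stop("bdx_integrity_error",
               "node '%s' already present with type '%s' (adding '%s')",
               id, g$nodes$type[i], type)
    }
    return(g)
  }
  g$nodes <- rbind(g$nodes, data.frame(id = id, type = type,
                                       stringsAsFactors = FALSE))
  g
}

add_edge <- function(g, subject, predicate, object) {
  if (!predicate %in% GRAPH_RELATIONS) {
    bdx_stop("bdx_vocabulary_error", "unknown relation '%s'", predicate)
  }
  new <- data.frame(subject = subject, predicate = predicate, object = object,
                    stringsAsFactors = FALSE)
  g$edges <- unique(rbind(g$edges, new))
  g
}

format_decimal <- function(x) {
  # 12 significant digits, plain notation
  sub("\\.?0+$", "", formatC(x, digits = 12, format = "f"))
}

add_literal <- function(g, subject, predicate, value,
                        datatype = c("decimal", "integer", "string")) {
  datatype <- match.arg(datatype)
  if (!predicate %in% GRAPH_DATA_PROPERTIES) {
    bdx_stop("bdx_vocabulary_error", "unknown data property '%s'", predicate)
  }
  value <- switch(datatype,
    decimal = format_decimal(as.numeric(value)),
    integer = as.character(as.integer(value)),
    string = as.character(value)
  )
  new <- data.frame(subject = subject, predicate = predicate, value = value,
                    datatype = datatype, stringsAsFactors = FALSE)
  g$literals <- unique(rbind(g$literals, new))
  g
}

#' Add an entity to an instance graph
#'
#' Methods exist for registries, populations, samples, executions,
#' contingency tables, dispositions and estimates. Each method adds the
#' entity's node(s), its datatype properties and the relation edges the
#' formal model prescribes: e.g. adding an execution creates its test-process
#' nodes with `part_of` and `participates_in` edges; adding an estimate
#' creates the computation node with `has_specified_input` /
#' `has_specified_output` edges and the `is_about` edge to its disposition.
#'
#' @param graph A `bdx_graph`.
#' @param x Entity to add.
#' @param ... Passed to methods.
#' @return The updated `bdx_graph`.
#' @export
ig_add <- function(graph, x, ...) {
  stopifnot(inherits(graph, "bdx_graph"))
  UseMethod("ig_add", x)
}

#' @export
ig_add.default <- function(graph, x, ...) {
  bdx_stop("bdx_domain_error", "cannot add object of class '%s' to a graph",
           paste(class(x), collapse = "/"))
}

#' @export
ig_add.bdx_registry <- function(graph, x, ...) {
  for (i in seq_len(nrow(x$diseases))) {
    graph <- add_node(graph, x$diseases$id[i], "Disease")
    graph <- add_literal(graph, x$diseases$id[i], "has_label",
                         x$diseases$label[i], "string")
  }
  for (i in seq_len(nrow(x$tests))) {
    graph <- add_node(graph, x$tests$id[i], "Medical_test")
    graph <- add_literal(graph, x$tests$id[i], "has_label",
                         x$tests$label[i], "string")
    graph <- add_literal(graph, x$tests$id[i], "has_role",
                         x$tests$role[i], "string")
    if (!is.na(x$tests$parent[i])) {
      graph <- add_edge(graph, x$tests$id[i], "is_a", x$tests$parent[i])
    }
  }
  graph
}

#' @export
ig_add.bdx_population <- function(graph, x, ...) {
  graph <- add_node(graph, x$id, "Collection_of_humans")
  if (!is.null(x$parent_id)) {
    graph <- add_node(graph, x$parent_id, "Collection_of_humans")
    graph <- add_edge(graph, x$id, "part_of", x$parent_id)
  }
  graph
}

#' @export
ig_add.bdx_sample <- function(graph, x, ...) {
  graph <- add_node(graph, x$id, "Sample_of_humans")
  graph <- add_node(graph, x$population_id, "Collection_of_humans")
  graph <- add_edge(graph, x$id, "part_of", x$population_id)
  for (p in x$member_ids) {
    graph <- add_node(graph, p, "Human")
    graph <- add_edge(graph, p, "part_of", x$id)
  }
  graph
}

#' @export
ig_add.bdx_execution <- function(graph, x, ...) {
  graph <- add_node(graph, x$id, "Planned_process")
  pr <- x$processes
  for (i in seq_len(nrow(pr))) {
    graph <- add_node(graph, pr$id[i], "Test_process")
    graph <- add_edge(graph, pr$id[i], "instance_of", pr$test_class[i])
    graph <- add_edge(graph, pr$id[i], "part_of", x$id)
    graph <- add_node(graph, pr$person_id[i], "Human")
    graph <- add_edge(graph, pr$person_id[i], "participates_in", pr$id[i])
  }
  graph
}

#' @export
ig_add.bdx_table <- function(graph, x, ...) {
  graph <- add_node(graph, x$id, "Data_set")
  for (cell in c("tp", "fp", "fn", "tn")) {
    graph <- add_literal(graph, x$id, cell, x[[cell]], "integer")
  }
  if (!is.null(x$source_execution)) {
    graph <- add_node(graph, x$source_execution, "Planned_process")
    graph <- add_edge(graph, x$source_execution, "has_specified_output", x$id)
  }
  graph
}

#' @export
ig_add.bdx_disposition <- function(graph, x, ...) {
  graph <- add_node(graph, x$id, "Disposition")
  graph <- add_literal(graph, x$id, "has_probability_value", x$probability,
                       "decimal")
  graph <- add_literal(graph, x$id, "has_kind", x$kind, "string")
  graph <- add_literal(graph, x$id, "has_bearer", x$bearer_id, "string")
  graph <- add_literal(graph, x$id, "has_trigger_description",
                       x$trigger_descriptor, "string")
  graph <- add_literal(graph, x$id, "has_realization_description",
                       x$realization_descriptor, "string")
  graph <- add_node(graph, x$class_id, "Disposition_class")
  graph <- add_edge(graph, x$id, "instance_of", x$class_id)
  rel <- KIND_RELATIONS[[x$kind]]
  if (!is.null(rel)) {
    graph <- add_edge(graph, x$class_id, rel[["test"]], x$index_class)
    graph <- add_edge(graph, x$class_id, rel[["disease"]], x$disease)
  }
  graph
}

#' @export
ig_add.bdx_estimate <- function(graph, x, ...) {
  graph <- add_node(graph, x$id, "Data_item")
  graph <- add_literal(graph, x$id, "has_specified_value", x$value, "decimal")
  graph <- add_literal(graph, x$id, "has_kind", x$kind, "string")
  graph <- add_literal(graph, x$id, "denominator", x$n_denominator, "integer")
  if (!is.na(x$ci_low)) {
    graph <- add_literal(graph, x$id, "ci_low", x$ci_low, "decimal")
    graph <- add_literal(graph, x$id, "ci_high", x$ci_high, "decimal")
    graph <- add_literal(graph, x$id, "confidence_level", x$level, "decimal")
  }
  comp <- paste0("comp_", x$id)
  graph <- add_node(graph, comp, "Planned_process")
  for (inp in x$inputs) {
    graph <- add_edge(graph, comp, "has_specified_input", inp)
  }
  graph <- add_edge(graph, comp, "has_specified_output", x$id)
  if (!is.na(x$about)) {
    graph <- add_edge(graph, x$id, "is_about", x$about)
  }
  graph
}

part_of_cycles <- function(g) {
  po <- g$edges[g$edges$predicate == "part_of", , drop = FALSE]
  bad <- character(0)
  for (start in unique(po$subject)) {
    seen <- character(0)
    frontier <- start
    while (length(frontier) > 0) {
      nxt <- po$object[po$subject %in% frontier]
      if (start %in% nxt) {
        bad <- c(bad, start)
        break
      }
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
  }
  bad
}

literal_of <- function(g, subject, predicate) {
  v <- g$literals$value[g$literals$subject == subject &
                          g$literals$predicate == predicate]
  if (length(v) == 0) NA_character_ else v[[1]]
}

#' Validate an instance graph
#'
#' Checks referential integrity (no dangling edge endpoints), the closed
#' relation vocabulary, acyclicity of `part_of`, that every estimate
#' (`Data_item`) has an `is_about` edge, and that the kind recorded on an
#' estimate matches the kind of the disposition it is about. Violations are
#' data, not errors: a valid graph yields an empty report, and validation is
#' idempotent.
#'
#' @param graph A `bdx_graph`.
#' @return A `bdx_validation` data frame with columns `rule`, `subject` and
#'   `message`; zero rows iff the graph is valid.
#' @export
validate_instance_graph <- function(graph) {
  stopifnot(inherits(graph, "bdx_graph"))
  v <- list()
  flag <- function(rule, subject, message) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, subject = subject,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  ids <- graph$nodes$id
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    if (!e$predicate %in% GRAPH_RELATIONS) {
      flag("closed_vocabulary", e$subject,
           sprintf("relation '%s' outside the closed vocabulary",
                   e$predicate))
    }
    if (!e$subject %in% ids) {
      flag("dangling_edge", e$subject,
           sprintf("edge subject '%s' is not a node", e$subject))
    }
    if (!e$object %in% ids) {
      flag("dangling_edge", e$object,
           sprintf("edge object '%s' is not a node", e$object))
    }
  }
  for (id in part_of_cycles(graph)) {
    flag("part_of_cycle", id, sprintf("part_of cycle through '%s'", id))
  }
  estimates <- graph$nodes$id[graph$nodes$type == "Data_item"]
  for (est in estimates) {
    about <- graph$edges$object[graph$edges$subject == est &
                                  graph$edges$predicate == "is_about"]
    if (length(about) == 0) {
      flag("missing_is_about", est,
           sprintf("estimate '%s' lacks an is_about edge", est))
      next
    }
    ekind <- literal_of(graph, est, "has_kind")
    for (d in about) {
      dkind <- literal_of(graph, d, "has_kind")
      if (!is.na(ekind) && !is.na(dkind) && ekind != dkind) {
        flag("kind_mismatch", est,
             sprintf("estimate '%s' (%s) is about disposition '%s' (%s)",
                     est, ekind, d, dkind))
      }
    }
  }
  out <- if (length(v) == 0) {
    data.frame(rule = character(0), subject = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
  structure(out, class = c("bdx_validation", "data.frame"))
}

#' Test whether a validation report is clean
#'
#' @param report A `bdx_validation` report.
#' @return `TRUE` iff the report contains no violations.
#' @export
is_valid_report <- function(report) {
  stopifnot(inherits(report, "bdx_validation"))
  nrow(report) == 0
}

#' @export
print.bdx_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation: graph is valid>\n")
  } else {
    cat(sprintf("<validation: %d violation(s)>\n", nrow(x)))
    print.data.frame(x)
  }
  invisible(x)
}
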