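# Turtle (W3C RDF 1.1) serialization of instance graphs over a minted
# project vocabulary. Local names for the OBI/IAO-style relations
# (has_specified_input/output/value, is_about, ...) are reused as labels
# only; no live OBO imports, so everything works offline. Output is fully
# deterministic: one triple per line, sorted by subject, predicate, object.

BDX_VOCAB_NS <- "https://w3id.org/bayesdx/vocab#"
BDX_INST_NS <- "https://w3id.org/bayesdx/instance#"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

turtle_escape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  gsub('"', '\\\\"', x)
}

turtle_unescape <- function(x) {
  x <- gsub('\\\\"', '"', x)
  gsub("\\\\\\\\", "\\\\", x)
}

#' Serialize an instance graph to Turtle
#'
#' The graph is validated first (refused with the validation report attached
#' when invalid). Node types are emitted as `rdf:type` (`a`) triples to
#' vocabulary classes, relations as object properties between instance IRIs,
#' and field values as typed literals (`xsd:decimal` with 12 significant
#' digits, `xsd:integer`, or plain strings).
#'
#' @param graph A `bdx_graph`.
#' @param validate Set `FALSE` to skip validation.
#' @return A single string: the Turtle document.
#' @seealso [from_turtle()]
#' @export
to_turtle <- function(graph, validate = TRUE) {
  stopifnot(inherits(graph, "bdx_graph"))
  if (validate) {
    report <- validate_instance_graph(graph)
    if (!is_valid_report(report)) {
      cond <- errorCondition(
        sprintf("refusing to serialize an invalid graph (%d violations)",
                nrow(report)),
        class = c("bdx_invalid_graph", "bdx_error"))
      cond$report <- report
      stop(cond)
    }
  }
  lines <- character(0)
  for (i in seq_len(nrow(graph$nodes))) {
    lines <- c(lines, sprintf("inst:%s a bdx:%s .", graph$nodes$id[i],
                              graph$nodes$type[i]))
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    lines <- c(lines, sprintf("inst:%s bdx:%s inst:%s .", e$subject,
                              e$predicate, e$object))
  }
  for (i in seq_len(nrow(graph$literals))) {
    l <- graph$literals[i, ]
    obj <- switch(l$datatype,
      decimal = sprintf('"%s"^^xsd:decimal', l$value),
      integer = sprintf('"%s"^^xsd:integer', l$value),
      string = sprintf('"%s"', turtle_escape(l$value))
    )
    lines <- c(lines, sprintf("inst:%s bdx:%s %s .", l$subject, l$predicate,
                              obj))
  }
  header <- c(
    sprintf("@prefix bdx: <%s> .", BDX_VOCAB_NS),
    sprintf("@prefix inst: <%s> .", BDX_INST_NS),
    sprintf("@prefix xsd: <%s> .", XSD_NS),
    ""
  )
  paste(c(header, sort(lines)), collapse = "\n")
}

#' Write an instance graph to a Turtle file
#'
#' @param graph A `bdx_graph`.
#' @param path Output path.
#' @param ... Passed to [to_turtle()].
#' @return Invisibly, the path.
#' @export
write_turtle <- function(graph, path, ...) {
  writeLines(to_turtle(graph, ...), path)
  invisible(path)
}

resolve_term <- function(term, prefixes) {
  m <- regmatches(term, regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", term))[[1]]
  if (length(m) == 0) {
    bdx_stop("bdx_parse_error", "cannot resolve term '%s'", term)
  }
  ns <- prefixes[[m[2]]]
  if (is.null(ns)) {
    bdx_stop("bdx_parse_error", "undeclared prefix '%s'", m[2])
  }
  c(ns = ns, local = m[3])
}

#' Parse a Turtle document into an instance graph
#'
#' Accepts the restricted Turtle dialect emitted by [to_turtle()]: prefix
#' declarations, one triple per line, vocabulary and instance namespaces as
#' minted by this package. Triples using predicates or types outside the
#' closed vocabulary are rejected with the offending IRIs listed, so
#' `from_turtle(to_turtle(g))` is edge-set and literal-equal to `g`.
#'
#' @param text A Turtle document (single string or character vector of
#'   lines), or the path of a file to read when `is_path = TRUE`.
#' @param is_path Treat `text` as a file path.
#' @return A `bdx_graph`.
#' @export
from_turtle <- function(text, is_path = FALSE) {
  lines <- if (is_path) readLines(text) else unlist(strsplit(text, "\n",
                                                             fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  prefixes <- list()
  graph <- instance_graph()
  offending <- character(0)
  for (line in lines) {
    if (startsWith(line, "@prefix")) {
      m <- regmatches(line, regexec(
        "^@prefix\\s+([A-Za-z][A-Za-z0-9]*):\\s+<([^>]*)>\\s*\\.\\s*$",
        line))[[1]]
      if (length(m) == 0) {
        bdx_stop("bdx_parse_error", "malformed prefix line: %s", line)
      }
      prefixes[[m[2]]] <- m[3]
      next
    }
    m <- regmatches(line, regexec(
      "^(\\S+)\\s+(\\S+)\\s+(.+?)\\s*\\.$", line))[[1]]
    if (length(m) == 0) {
      bdx_stop("bdx_parse_error", "malformed triple line: %s", line)
    }
    subj <- resolve_term(m[2], prefixes)
    if (subj[["ns"]] != BDX_INST_NS) {
      bdx_stop("bdx_parse_error", "subject outside the instance namespace: %s",
               m[2])
    }
    sid <- subj[["local"]]
    pred_raw <- m[3]
    obj_raw <- m[4]

    if (pred_raw == "a") {
      obj <- resolve_term(obj_raw, prefixes)
      if (obj[["ns"]] != BDX_VOCAB_NS ||
          !obj[["local"]] %in% GRAPH_TYPES) {
        offending <- c(offending, paste0(obj[["ns"]], obj[["local"]]))
        next
      }
      graph <- add_node(graph, sid, obj[["local"]])
      next
    }

    pred <- resolve_term(pred_raw, prefixes)
    if (pred[["ns"]] != BDX_VOCAB_NS) {
      offending <- c(offending, paste0(pred[["ns"]], pred[["local"]]))
      next
    }
    pname <- pred[["local"]]

    lit <- regmatches(obj_raw, regexec(
      '^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(\\S+))?$', obj_raw))[[1]]
    if (length(lit) > 0) {
      if (!pname %in% GRAPH_DATA_PROPERTIES) {
        offending <- c(offending, paste0(BDX_VOCAB_NS, pname))
        next
      }
      dtype <- "string"
      value <- turtle_unescape(lit[2])
      if (nzchar(lit[3])) {
        dt <- resolve_term(lit[3], prefixes)
        if (dt[["ns"]] != XSD_NS ||
            !dt[["local"]] %in% c("decimal", "integer")) {
          bdx_stop("bdx_parse_error", "unsupported literal datatype: %s",
                   lit[3])
        }
        dtype <- dt[["local"]]
      }
      graph$literals <- unique(rbind(
        graph$literals,
        data.frame(subject = sid, predicate = pname, value = value,
                   datatype = dtype, stringsAsFactors = FALSE)))
    } else {
      if (!pname %in% GRAPH_RELATIONS) {
        offending <- c(offending, paste0(BDX_VOCAB_NS, pname))
        next
      }
      obj <- resolve_term(obj_raw, prefixes)
      if (obj[["ns"]] != BDX_INST_NS) {
        bdx_stop("bdx_parse_error",
                 "object of relation '%s' outside the instance namespace",
                 pname)
      }
      graph$edges <- unique(rbind(
        graph$edges,
        data.frame(subject = sid, predicate = pname, object = obj[["local"]],
                   stringsAsFactors = FALSE)))
    }
  }
  if (length(offending) > 0) {
    bdx_stop("bdx_vocabulary_error",
             "triples outside the closed vocabulary: %s",
             paste(unique(offending), collapse = ", "))
  }
  graph
}

#' Test two instance graphs for equality
#'
#' Equality of the node set, edge set and literal set, ignoring row order.
#'
#' @param a,b `bdx_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
graphs_equal <- function(a, b) {
  stopifnot(inherits(a, "bdx_graph"), inherits(b, "bdx_graph"))
  norm <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  identical(norm(a$nodes), norm(b$nodes)) &&
    identical(norm(a$edges), norm(b$edges)) &&
    identical(norm(a$literals), norm(b$literals))
}
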