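# Declared hierarchies of index / reference test classes and target diseases.
# Subsumption used by the aggregation compatibility check is exactly the
# declared parent chain: no inference beyond it.

#' Declare a disease class
#'
#' @param id Unique identifier within a registry.
#' @param label Human-readable label.
#' @return A `bdx_disease_class` object.
#' @export
#' @examples
#' disease_class("M_albuminuria", "albuminuria")
disease_class <- function(id, label = id) {
  assert_string(id, "id")
  check_local_name(id)
  assert_string(label, "label")
  structure(list(id = id, label = label), class = "bdx_disease_class")
}

#' Declare a medical test class
#'
#' A test class is either an index test (the test whose accuracy is under
#' evaluation) or a reference test (the proxy for true disease status).
#' Classes form a forest via `parent`; a child must have the same role as its
#' parent, and chains must be acyclic.
#'
#' @param id Unique identifier within a registry.
#' @param label Human-readable label.
#' @param role `"index"` or `"reference"`.
#' @param parent Identifier of the subsuming test class, or `NULL` for a root.
#' @param target_disease Identifier of the disease the test aims to detect.
#' @return A `bdx_test_class` object.
#' @export
#' @examples
#' test_class("IT1", "dipstick", "index", parent = "IT0",
#'            target_disease = "M_albuminuria")
test_class <- function(id, label = id, role = c("index", "reference"),
                       parent = NULL, target_disease) {
  assert_string(id, "id")
  check_local_name(id)
  assert_string(label, "label")
  role <- match.arg(role)
  if (!is.null(parent)) assert_string(parent, "parent")
  assert_string(target_disease, "target_disease")
  structure(list(id = id, label = label, role = role, parent = parent,
                 target_disease = target_disease),
            class = "bdx_test_class")
}

#' Build a validated test-class registry
#'
#' @param tests List of [test_class()] objects.
#' @param diseases List of [disease_class()] objects.
#' @return A `bdx_registry` with data frames `tests` and `diseases`.
#' @export
test_registry <- function(tests = list(), diseases = list()) {
  stopifnot(all(vapply(tests, inherits, logical(1), "bdx_test_class")),
            all(vapply(diseases, inherits, logical(1), "bdx_disease_class")))
  dis <- data.frame(
    id = vapply(diseases, `[[`, character(1), "id"),
    label = vapply(diseases, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  )
  tst <- data.frame(
    id = vapply(tests, `[[`, character(1), "id"),
    label = vapply(tests, `[[`, character(1), "label"),
    role = vapply(tests, `[[`, character(1), "role"),
    parent = vapply(tests, function(t) t$parent %||% NA_character_,
                    character(1)),
    target_disease = vapply(tests, `[[`, character(1), "target_disease"),
    stringsAsFactors = FALSE
  )
  reg <- structure(list(tests = tst, diseases = dis), class = "bdx_registry")
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$tests$id) || anyDuplicated(reg$diseases$id)) {
    bdx_stop("bdx_integrity_error", "registry identifiers must be unique")
  }
  known <- reg$tests$id
  for (i in seq_len(nrow(reg$tests))) {
    p <- reg$tests$parent[i]
    if (is.na(p)) next
    if (!p %in% known) {
      bdx_stop("bdx_integrity_error",
               "test class '%s' has unknown parent '%s'", reg$tests$id[i], p)
    }
    if (reg$tests$role[reg$tests$id == p] != reg$tests$role[i]) {
      bdx_stop("bdx_integrity_error",
               "test class '%s' and its parent '%s' differ in role",
               reg$tests$id[i], p)
    }
  }
  if (nrow(reg$tests) > 0 &&
      !all(reg$tests$target_disease %in% reg$diseases$id)) {
    bdx_stop("bdx_integrity_error",
             "every test class must target a declared disease")
  }
  # acyclicity of the parent chains
  for (id in reg$tests$id) {
    seen <- character(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) {
        bdx_stop("bdx_integrity_error",
                 "cyclic parent chain at test class '%s'", id)
      }
      seen <- c(seen, cur)
      cur <- reg$tests$parent[match(cur, reg$tests$id)]
    }
  }
  invisible(reg)
}

#' Read a test-class registry from JSON
#'
#' Expected schema:
#' `{"tests": [{"id","label","role","parent","target_disease"}, ...],
#'   "diseases": [{"id","label"}, ...]}`
#' where `"parent"` may be `null` for roots.
#'
#' @param path Path to a JSON file.
#' @return A `bdx_registry`.
#' @export
read_test_registry <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tests <- lapply(raw$tests, function(t) {
    test_class(t$id, t$label %||% t$id, t$role, t$parent,
               target_disease = t$target_disease)
  })
  diseases <- lapply(raw$diseases, function(d) {
    disease_class(d$id, d$label %||% d$id)
  })
  test_registry(tests, diseases)
}

#' Ancestor chain of a test class
#'
#' @param registry A `bdx_registry`.
#' @param id Test class identifier.
#' @return Character vector: the class itself, then each parent up to the
#'   root.
#' @export
class_ancestors <- function(registry, id) {
  stopifnot(inherits(registry, "bdx_registry"))
  if (!id %in% registry$tests$id) {
    bdx_stop("bdx_integrity_error", "unknown test class '%s'", id)
  }
  chain <- character(0)
  cur <- id
  while (!is.na(cur)) {
    chain <- c(chain, cur)
    cur <- registry$tests$parent[match(cur, registry$tests$id)]
  }
  chain
}

#' Lowest common subsuming test class
#'
#' Returns the nearest class that subsumes all of `ids` along the declared
#' parent chains, or `NULL` when the classes live in disjoint hierarchies.
#'
#' @param registry A `bdx_registry`.
#' @param ids Character vector of test class identifiers.
#' @return A single identifier, or `NULL`.
#' @export
common_test_class <- function(registry, ids) {
  ids <- unique(ids)
  chains <- lapply(ids, function(id) class_ancestors(registry, id))
  candidates <- chains[[1]]
  for (ch in chains[-1]) candidates <- candidates[candidates %in% ch]
  if (length(candidates) == 0) NULL else candidates[[1]]
}

#' @export
print.bdx_registry <- function(x, ...) {
  cat(sprintf("<test registry: %d test classes, %d diseases>\n",
              nrow(x$tests), nrow(x$diseases)))
  invisible(x)
}
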