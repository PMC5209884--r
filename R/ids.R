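.bdx_ids <- new.env(parent = emptyenv())

#' Mint an opaque identifier
#'
#' Identifiers are `<prefix>_<counter>` strings; the counter is per-prefix and
#' package-global, giving stable, human-readable node names in serialized
#' graphs. Identifiers are restricted to characters that form valid Turtle
#' local names.
#'
#' @param prefix Short alphanumeric prefix naming the entity kind.
#' @return A single string.
#' @seealso [reset_ids()]
#' @export
#' @examples
#' reset_ids()
#' bdx_id("estimate")
bdx_id <- function(prefix) {
  assert_string(prefix, "prefix")
  check_local_name(prefix)
  n <- get0(prefix, envir = .bdx_ids, ifnotfound = 0L) + 1L
  assign(prefix, n, envir = .bdx_ids)
  sprintf("%s_%d", prefix, n)
}

#' Reset all identifier counters
#'
#' Restarts every prefix counter at 1. Call at the top of a script when
#' byte-identical Turtle output across runs is wanted.
#'
#' @return Invisibly, `NULL`.
#' @export
reset_ids <- function() {
  rm(list = ls(envir = .bdx_ids), envir = .bdx_ids)
  invisible(NULL)
}

check_local_name <- function(id) {
  if (!grepl("^[A-Za-z][A-Za-z0-9_.-]*$", id)) {
    bdx_stop("bdx_domain_error",
             "identifier '%s' is not a valid graph local name", id)
  }
  invisible(id)
}
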