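# Pooling several estimates of the same indicator into a finer estimate.
# Pooling is only meaningful when the index tests are subsumed by a common
# index-test class, the reference tests by a common reference-test class,
# and the sampled populations by a common encompassing population; the
# compatibility check verifies exactly that against the declared hierarchies
# and the graph's part_of edges.

#' Describe an aggregation method
#'
#' @param name `"pooled_counts"` (sum numerators and denominators; exact) or
#'   `"inverse_variance_logit"` (fixed-effect inverse-variance pooling on the
#'   logit scale with back-transform).
#' @param parameters Optional named list of method parameters.
#' @return A `bdx_aggregation_method`.
#' @export
aggregation_method <- function(name = c("pooled_counts",
                                        "inverse_variance_logit"),
                               parameters = list()) {
  name <- match.arg(name)
  structure(list(name = name, parameters = parameters),
            class = "bdx_aggregation_method")
}

population_ancestors <- function(graph, id) {
  chain <- id
  po <- graph$edges[graph$edges$predicate == "part_of", , drop = FALSE]
  pops <- graph$nodes$id[graph$nodes$type == "Collection_of_humans"]
  cur <- id
  repeat {
    nxt <- po$object[po$subject == cur & po$object %in% pops]
    if (length(nxt) == 0 || nxt[[1]] %in% chain) break
    cur <- nxt[[1]]
    chain <- c(chain, cur)
  }
  chain
}

#' Check whether estimates may be aggregated
#'
#' Compatible iff (i) all estimates are of the same indicator kind, (ii)
#' their index test classes share a common subsuming class in `registry`,
#' (iii) their reference test classes do too, and (iv) their source
#' populations share a common encompassing population along the graph's
#' `part_of` edges. The common classes returned are the lowest such
#' ancestors.
#'
#' @param estimates List of `bdx_estimate` objects, all of the same kind.
#' @param registry A `bdx_registry` with the declared test hierarchies.
#' @param graph A `bdx_graph` holding the populations and their `part_of`
#'   edges; may be `NULL` when all estimates come from the same population.
#' @return A `bdx_compatibility` list: `compatible`, `common_index_class`,
#'   `common_reference_class`, `common_population`, `reasons`.
#' @export
check_compatibility <- function(estimates, registry, graph = NULL) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, logical(1), "bdx_estimate")))
  kinds <- unique(vapply(estimates, `[[`, character(1), "kind"))
  if (length(kinds) != 1) {
    bdx_stop("bdx_kind_mismatch",
             "cannot aggregate estimates of mixed kinds: %s",
             paste(kinds, collapse = ", "))
  }
  reasons <- character(0)
  get_ids <- function(field) {
    vals <- lapply(estimates, `[[`, field)
    if (any(vapply(vals, is.null, logical(1)))) NULL else unique(unlist(vals))
  }

  idx <- get_ids("index_class")
  common_it <- NULL
  if (is.null(idx)) {
    reasons <- c(reasons, "an estimate lacks an index test class")
  } else {
    common_it <- common_test_class(registry, idx)
    if (is.null(common_it)) {
      reasons <- c(reasons, sprintf(
        "index test classes {%s} have no common subsuming class",
        paste(idx, collapse = ", ")))
    }
  }

  ref <- get_ids("reference_class")
  common_rt <- NULL
  if (is.null(ref)) {
    reasons <- c(reasons, "an estimate lacks a reference test class")
  } else {
    common_rt <- common_test_class(registry, ref)
    if (is.null(common_rt)) {
      reasons <- c(reasons, sprintf(
        "reference test classes {%s} have no common subsuming class",
        paste(ref, collapse = ", ")))
    }
  }

  pops <- get_ids("population_id")
  common_g <- NULL
  if (is.null(pops) || anyNA(pops)) {
    reasons <- c(reasons, "an estimate lacks a source population")
  } else if (length(pops) == 1) {
    common_g <- pops
  } else if (is.null(graph)) {
    reasons <- c(reasons,
                 "distinct populations but no graph to relate them")
  } else {
    chains <- lapply(pops, function(p) population_ancestors(graph, p))
    cand <- chains[[1]]
    for (ch in chains[-1]) cand <- cand[cand %in% ch]
    if (length(cand) == 0) {
      reasons <- c(reasons, sprintf(
        "populations {%s} share no encompassing population",
        paste(pops, collapse = ", ")))
    } else {
      common_g <- cand[[1]]
    }
  }

  structure(list(
    compatible = length(reasons) == 0,
    common_index_class = common_it,
    common_reference_class = common_rt,
    common_population = common_g,
    reasons = reasons
  ), class = "bdx_compatibility")
}

#' @export
print.bdx_compatibility <- function(x, ...) {
  if (x$compatible) {
    cat(sprintf("<compatible> index=%s reference=%s population=%s\n",
                x$common_index_class, x$common_reference_class,
                x$common_population))
  } else {
    cat("<incompatible>\n")
    for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  }
  invisible(x)
}

logit <- function(p) log(p / (1 - p))

#' Aggregate compatible estimates into a finer estimate
#'
#' With `pooled_counts` the numerators and denominators are summed, which
#' equals re-estimating on the cell-wise summed table. With
#' `inverse_variance_logit` the estimates are pooled by fixed-effect
#' inverse-variance weighting on the logit scale and back-transformed; when
#' any input proportion is 0 or 1, a continuity correction of 0.5 is added to
#' both cells of every input (recorded in the output's `method`).
#'
#' @param estimates List of `bdx_estimate` objects of one kind.
#' @param method A [aggregation_method()] (default pooled counts).
#' @param about Optional [disposition()] the pooled estimate is about
#'   (typically for the encompassing population and common test classes).
#' @param registry,graph When both supplied, [check_compatibility()] is run
#'   first and incompatible inputs are refused.
#' @param level Confidence level for the pooled interval.
#' @return A `bdx_estimate` whose `inputs` are the source estimate ids.
#' @export
aggregate_estimates <- function(estimates,
                                method = aggregation_method("pooled_counts"),
                                about = NULL, registry = NULL, graph = NULL,
                                level = 0.95) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, logical(1), "bdx_estimate")),
            inherits(method, "bdx_aggregation_method"))
  kinds <- unique(vapply(estimates, `[[`, character(1), "kind"))
  if (length(kinds) != 1) {
    bdx_stop("bdx_kind_mismatch",
             "cannot aggregate estimates of mixed kinds")
  }
  compat <- NULL
  if (!is.null(registry)) {
    compat <- check_compatibility(estimates, registry, graph)
    if (!compat$compatible) {
      bdx_stop("bdx_incompatible_estimates",
               "estimates are not compatible for aggregation: %s",
               paste(compat$reasons, collapse = "; "))
    }
  }
  k <- vapply(estimates, `[[`, numeric(1), "n_numerator")
  n <- vapply(estimates, `[[`, numeric(1), "n_denominator")
  ids <- vapply(estimates, `[[`, character(1), "id")

  if (method$name == "pooled_counts") {
    value <- sum(k) / sum(n)
    ci <- wilson_interval(sum(k), sum(n), level)
    label <- "pooled_counts"
    num <- as.integer(sum(k)); den <- as.integer(sum(n))
  } else {
    cc <- any(k == 0 | k == n)
    kk <- if (cc) k + 0.5 else k
    nn <- if (cc) n + 1 else n
    y <- logit(kk / nn)
    v <- 1 / kk + 1 / (nn - kk)
    w <- 1 / v
    y_pool <- sum(w * y) / sum(w)
    se_pool <- sqrt(1 / sum(w))
    z <- stats::qnorm(1 - (1 - level) / 2)
    value <- stats::plogis(y_pool)
    ci <- structure(list(low = stats::plogis(y_pool - z * se_pool),
                         high = stats::plogis(y_pool + z * se_pool),
                         level = level), class = "bdx_ci")
    label <- if (cc) "inverse_variance_logit+cc0.5" else
      "inverse_variance_logit"
    num <- as.integer(sum(k)); den <- as.integer(sum(n))
  }

  new_ip_estimate(
    kind = kinds, value = value, ci = ci,
    n_numerator = num, n_denominator = den,
    about = about, inputs = ids, method = label,
    index_class = if (!is.null(compat)) compat$common_index_class else NULL,
    reference_class = if (!is.null(compat)) compat$common_reference_class
      else NULL,
    population_id = if (!is.null(compat)) compat$common_population else NULL
  )
}
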