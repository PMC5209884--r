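# Synthetic populations with subgroup-structured latent response
# probabilities. Each person carries a latent disease status and, for the
# index and reference test, the probability of a positive result were the
# test performed — the dispositional reading of the indicators. Subgroup
# heterogeneity in those probabilities is what produces the spectrum effect:
# the same test has different true sensitivity in populations that mix the
# subgroups differently.

#' Specify a population subgroup
#'
#' @param name Subgroup label.
#' @param size Number of members.
#' @param diseased_fraction Fraction of members with the disease; the
#'   diseased count is `round(size * diseased_fraction)`, deterministic so
#'   that true proportions are exact.
#' @param p_index_pos_given_diseased,p_index_pos_given_healthy Probability of
#'   a positive index-test result for diseased / healthy members.
#' @param p_ref_pos_given_diseased,p_ref_pos_given_healthy Same for the
#'   reference test; the defaults describe a perfect reference test.
#' @return A `bdx_subgroup_spec`.
#' @export
subgroup_spec <- function(name, size, diseased_fraction,
                          p_index_pos_given_diseased,
                          p_index_pos_given_healthy = 0,
                          p_ref_pos_given_diseased = 1,
                          p_ref_pos_given_healthy = 0) {
  assert_string(name, "name")
  size <- assert_count(size, "size")
  assert_probability(diseased_fraction, "diseased_fraction")
  assert_probability(p_index_pos_given_diseased, "p_index_pos_given_diseased")
  assert_probability(p_index_pos_given_healthy, "p_index_pos_given_healthy")
  assert_probability(p_ref_pos_given_diseased, "p_ref_pos_given_diseased")
  assert_probability(p_ref_pos_given_healthy, "p_ref_pos_given_healthy")
  structure(list(name = name, size = size,
                 diseased_fraction = diseased_fraction,
                 p_index_pos_given_diseased = p_index_pos_given_diseased,
                 p_index_pos_given_healthy = p_index_pos_given_healthy,
                 p_ref_pos_given_diseased = p_ref_pos_given_diseased,
                 p_ref_pos_given_healthy = p_ref_pos_given_healthy),
            class = "bdx_subgroup_spec")
}

#' Specify a synthetic population
#'
#' @param subgroups List of [subgroup_spec()] objects; total size must be at
#'   least 1.
#' @param seed Default seed for sampling/execution helpers run on this
#'   population (each helper also accepts an explicit seed).
#' @param id Population identifier; minted when `NULL`.
#' @return A `bdx_population_spec`.
#' @export
population_spec <- function(subgroups, seed = 1L, id = NULL) {
  stopifnot(length(subgroups) >= 1,
            all(vapply(subgroups, inherits, logical(1), "bdx_subgroup_spec")))
  if (sum(vapply(subgroups, `[[`, numeric(1), "size")) < 1) {
    bdx_stop("bdx_domain_error", "total population size must be >= 1")
  }
  structure(list(subgroups = subgroups, seed = assert_count(seed, "seed"),
                 id = id), class = "bdx_population_spec")
}

#' Read a simulator configuration from JSON
#'
#' Schema: `{"subgroups": [{"name","size","diseased_fraction",
#' "p_index_pos_given_diseased","p_index_pos_given_healthy",
#' "p_ref_pos_given_diseased","p_ref_pos_given_healthy"}, ...],
#' "seed": 1}`.
#'
#' @param path Path to a JSON file.
#' @return A `bdx_population_spec`.
#' @export
read_population_spec <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sgs <- lapply(raw$subgroups, function(s) {
    subgroup_spec(
      name = s$name, size = s$size,
      diseased_fraction = s$diseased_fraction,
      p_index_pos_given_diseased = s$p_index_pos_given_diseased,
      p_index_pos_given_healthy = s$p_index_pos_given_healthy %||% 0,
      p_ref_pos_given_diseased = s$p_ref_pos_given_diseased %||% 1,
      p_ref_pos_given_healthy = s$p_ref_pos_given_healthy %||% 0
    )
  })
  population_spec(sgs, seed = raw$seed %||% 1L, id = raw$id %||% NULL)
}

#' Realize a population from its specification
#'
#' Fully deterministic: per subgroup the first `round(size *
#' diseased_fraction)` members are diseased and every member's response
#' probabilities are copied from the subgroup specification, so that true
#' proportions computed on the population are exact.
#'
#' @param spec A [population_spec()].
#' @param index_class,reference_class Test class identifiers keying the
#'   response probabilities.
#' @param parent_id Optional encompassing population identifier (`part_of`).
#' @return A `bdx_population`; `members` is a data frame with columns `id`,
#'   `subgroup`, `diseased`, `p_index`, `p_ref`.
#' @export
build_population <- function(spec, index_class = "IT", reference_class = "RT",
                             parent_id = NULL) {
  stopifnot(inherits(spec, "bdx_population_spec"))
  assert_string(index_class, "index_class")
  assert_string(reference_class, "reference_class")
  pop_id <- spec$id %||% bdx_id("g")
  rows <- lapply(spec$subgroups, function(sg) {
    if (sg$size == 0) return(NULL)
    n_dis <- round(sg$size * sg$diseased_fraction)
    diseased <- c(rep(TRUE, n_dis), rep(FALSE, sg$size - n_dis))
    data.frame(
      subgroup = sg$name,
      diseased = diseased,
      p_index = ifelse(diseased, sg$p_index_pos_given_diseased,
                       sg$p_index_pos_given_healthy),
      p_ref = ifelse(diseased, sg$p_ref_pos_given_diseased,
                     sg$p_ref_pos_given_healthy),
      stringsAsFactors = FALSE
    )
  })
  members <- do.call(rbind, rows)
  if (is.null(members) || nrow(members) == 0) {
    bdx_stop("bdx_domain_error", "population specification is empty")
  }
  members <- cbind(
    data.frame(id = sprintf("%s_p%d", pop_id, seq_len(nrow(members))),
               stringsAsFactors = FALSE),
    members
  )
  structure(list(id = pop_id, members = members, parent_id = parent_id,
                 index_class = index_class,
                 reference_class = reference_class,
                 seed = spec$seed),
            class = "bdx_population")
}

#' @export
print.bdx_population <- function(x, ...) {
  cat(sprintf(
    "<population %s> %d members (%d diseased), tests %s vs %s\n",
    x$id, nrow(x$members), sum(x$members$diseased), x$index_class,
    x$reference_class))
  invisible(x)
}

new_true_proportion <- function(kind, value, pop, index_class = NULL,
                                reference_class = NULL) {
  structure(list(kind = kind, value = value, population_id = pop$id,
                 index_class = index_class,
                 reference_class = reference_class),
            class = "bdx_true_proportion")
}

#' @export
print.bdx_true_proportion <- function(x, ...) {
  cat(sprintf("<true %s in %s> %.6g\n", x$kind, x$population_id, x$value))
  invisible(x)
}

#' True prevalence of a population
#'
#' Diseased count over total count; exact, no randomness.
#'
#' @param pop A `bdx_population`.
#' @return A `bdx_true_proportion` of kind `"prev"`.
#' @export
true_prevalence <- function(pop) {
  stopifnot(inherits(pop, "bdx_population"))
  new_true_proportion("prev", mean(pop$members$diseased), pop)
}

#' True sensitivity of the index test in a population
#'
#' The exhaustively evaluated disease-linked proportion: the mean, over the
#' diseased members, of the probability of a positive index-test result.
#'
#' @param pop A `bdx_population`.
#' @param index_class Test class identifier (defaults to the population's).
#' @return A `bdx_true_proportion` of kind `"f2_se"`.
#' @export
true_sensitivity <- function(pop, index_class = pop$index_class) {
  stopifnot(inherits(pop, "bdx_population"))
  d <- pop$members$diseased
  if (!any(d)) {
    bdx_stop("bdx_undefined_proportion",
             "true sensitivity undefined: no diseased members")
  }
  new_true_proportion("f2_se", mean(pop$members$p_index[d]), pop,
                      index_class = index_class)
}

#' True specificity of the index test in a population
#'
#' The mean, over the healthy members, of the probability of a negative
#' index-test result.
#'
#' @inheritParams true_sensitivity
#' @return A `bdx_true_proportion` of kind `"f2_sp"`.
#' @export
true_specificity <- function(pop, index_class = pop$index_class) {
  stopifnot(inherits(pop, "bdx_population"))
  h <- !pop$members$diseased
  if (!any(h)) {
    bdx_stop("bdx_undefined_proportion",
             "true specificity undefined: no healthy members")
  }
  new_true_proportion("f2_sp", mean(1 - pop$members$p_index[h]), pop,
                      index_class = index_class)
}

#' True reference-test-linked proportion
#'
#' The population quantity the sample measurement actually estimates: among
#' individuals who would test positive to the reference test, the proportion
#' who would test positive to the index test (kind `"se"`), computed exactly
#' from the joint response probabilities (responses independent given the
#' person): `sum(p_ref * p_index) / sum(p_ref)` over all members. Kind
#' `"sp"` is the analogue on the negative side. With a perfect reference
#' test this equals the disease-linked proportion exactly.
#'
#' @param pop A `bdx_population`.
#' @param kind `"se"` or `"sp"`.
#' @return A `bdx_true_proportion` of kind `"f3_se"` or `"f3_sp"`.
#' @export
true_rt_linked_proportion <- function(pop, kind = c("se", "sp")) {
  stopifnot(inherits(pop, "bdx_population"))
  kind <- match.arg(kind)
  pi <- pop$members$p_index
  pr <- pop$members$p_ref
  if (kind == "se") {
    den <- sum(pr)
    if (den == 0) {
      bdx_stop("bdx_undefined_proportion",
               "no member can test reference-positive")
    }
    val <- sum(pr * pi) / den
  } else {
    den <- sum(1 - pr)
    if (den == 0) {
      bdx_stop("bdx_undefined_proportion",
               "no member can test reference-negative")
    }
    val <- sum((1 - pr) * (1 - pi)) / den
  }
  new_true_proportion(paste0("f3_", kind), val, pop,
                      index_class = pop$index_class,
                      reference_class = pop$reference_class)
}

#' Build the disposition carrying a population's real indicator value
#'
#' The randomization reading: the real indicator value is the probability of
#' the disposition, borne by the population, to draw (under the
#' kind-specific trigger) an individual realizing the kind-specific outcome.
#' The probability is the exhaustively computed true proportion — prevalence
#' from the diseased count, sensitivity/specificity from response
#' probabilities among diseased/healthy members, PPV/NPV from the joint
#' expected counts.
#'
#' @param pop A `bdx_population`.
#' @param kind One of `"prevalence"`, `"sensitivity"`, `"specificity"`,
#'   `"ppv"`, `"npv"`.
#' @param disease Disease class identifier.
#' @param index_class Index test class identifier (ignored for prevalence).
#' @return A [disposition()] whose `probability` is the true value.
#' @export
make_disposition <- function(pop, kind, disease = "M",
                             index_class = pop$index_class) {
  stopifnot(inherits(pop, "bdx_population"))
  kind <- match.arg(kind, IP_KINDS)
  m <- pop$members
  value <- switch(kind,
    prevalence = true_prevalence(pop)$value,
    sensitivity = true_sensitivity(pop)$value,
    specificity = true_specificity(pop)$value,
    ppv = {
      den <- sum(m$p_index)
      if (den == 0) {
        bdx_stop("bdx_undefined_proportion",
                 "no member can test index-positive")
      }
      sum(m$p_index[m$diseased]) / den
    },
    npv = {
      den <- sum(1 - m$p_index)
      if (den == 0) {
        bdx_stop("bdx_undefined_proportion",
                 "no member can test index-negative")
      }
      sum((1 - m$p_index)[!m$diseased]) / den
    }
  )
  disposition(kind = kind, disease = disease, probability = value,
              bearer_id = pop$id,
              index_class = if (kind == "prevalence") NULL else index_class)
}

#' Draw a simple random sample from a population
#'
#' Sampling is without replacement and deterministic given the seed; the
#' caller's RNG state is left untouched.
#'
#' @param pop A `bdx_population`.
#' @param n Sample size, `1 <= n <=` population size.
#' @param seed Integer seed (defaults to the population's).
#' @return A `bdx_sample` carrying the sampled members (with their response
#'   probabilities) for downstream test execution.
#' @export
sample_population <- function(pop, n, seed = pop$seed) {
  stopifnot(inherits(pop, "bdx_population"))
  n <- assert_count(n, "n", positive = TRUE)
  total <- nrow(pop$members)
  if (n > total) {
    bdx_stop("bdx_domain_error",
             "sample size %d exceeds population size %d", n, total)
  }
  idx <- with_seed(seed, sample.int(total, n))
  members <- pop$members[idx, , drop = FALSE]
  structure(list(id = bdx_id("s"),
                 population_id = pop$id,
                 member_ids = members$id,
                 members = members,
                 index_class = pop$index_class,
                 reference_class = pop$reference_class),
            class = "bdx_sample")
}

#' @export
print.bdx_sample <- function(x, ...) {
  cat(sprintf("<sample %s> %d members from %s\n", x$id,
              length(x$member_ids), x$population_id))
  invisible(x)
}

#' Execute index and reference tests on a sample
#'
#' Each member's two results are drawn independently with the member's
#' latent response probabilities (conditional independence given the
#' person), deterministically for a given seed. The execution is recorded
#' into a 2x2 table via [record_tests_results()].
#'
#' @param sample A `bdx_sample` from [sample_population()].
#' @param index_class,reference_class Test class identifiers (default to the
#'   sample's).
#' @param seed Integer seed.
#' @return A list with elements `execution` (`bdx_execution`) and `table`
#'   (`bdx_table`).
#' @export
execute_tests <- function(sample, index_class = sample$index_class,
                          reference_class = sample$reference_class,
                          seed = 1L) {
  stopifnot(inherits(sample, "bdx_sample"))
  m <- sample$members
  if (is.null(m) || anyNA(m$p_index) || anyNA(m$p_ref)) {
    bdx_stop("bdx_integrity_error",
             "every member needs response probabilities for both tests")
  }
  n <- nrow(m)
  draws <- with_seed(seed, list(u_index = stats::runif(n),
                                u_ref = stats::runif(n)))
  results <- data.frame(
    person_id = m$id,
    index = ifelse(draws$u_index < m$p_index, "positive", "negative"),
    reference = ifelse(draws$u_ref < m$p_ref, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  execution <- build_tests_execution(sample, index_class, reference_class,
                                     results)
  list(execution = execution, table = record_tests_results(execution))
}

#' Convergence of the sample proportion to its population value
#'
#' For each sample size in `n_grid`, draws `replicates` samples, simulates
#' both tests, computes the sample sensitivity measurement (proportion
#' index-positive among reference-positives) and its absolute deviation from
#' the population reference-linked proportion. Replicates with an empty
#' denominator (no reference-positives) are excluded and counted. The
#' simulation is vectorized (results are drawn directly from the latent
#' probabilities rather than through full per-process graph objects), which
#' is draw-for-draw the same model as [execute_tests()].
#'
#' @param pop A `bdx_population`.
#' @param n_grid Vector of sample sizes.
#' @param replicates Replicates per size (default 200).
#' @param seed Integer seed for the whole experiment.
#' @return A `bdx_convergence` data frame with columns `n`,
#'   `replicates_used`, `excluded`, `mean_abs_dev` and `se_envelope`
#'   (`sqrt(f3 (1 - f3) / n)`), plus attributes `f3` and `monotone`
#'   (whether `mean_abs_dev` decreases along increasing `n`).
#' @export
run_convergence_experiment <- function(pop, n_grid, replicates = 200,
                                       seed = 1L) {
  stopifnot(inherits(pop, "bdx_population"))
  if (length(n_grid) == 0) {
    bdx_stop("bdx_domain_error", "n_grid must be non-empty")
  }
  n_grid <- vapply(n_grid, assert_count, integer(1), what = "n")
  replicates <- assert_count(replicates, "replicates", positive = TRUE)
  f3 <- true_rt_linked_proportion(pop, "se")$value
  total <- nrow(pop$members)
  p_index <- pop$members$p_index
  p_ref <- pop$members$p_ref
  res <- with_seed(seed, {
    lapply(sort(n_grid), function(n) {
      devs <- numeric(0)
      excluded <- 0L
      for (r in seq_len(replicates)) {
        idx <- sample.int(total, n)
        ref_pos <- stats::runif(n) < p_ref[idx]
        ind_pos <- stats::runif(n) < p_index[idx]
        den <- sum(ref_pos)
        if (den == 0) {
          excluded <- excluded + 1L
        } else {
          devs <- c(devs, abs(sum(ind_pos & ref_pos) / den - f3))
        }
      }
      data.frame(n = n, replicates_used = length(devs), excluded = excluded,
                 mean_abs_dev = mean(devs),
                 se_envelope = sqrt(f3 * (1 - f3) / n))
    })
  })
  out <- do.call(rbind, res)
  structure(out,
            class = c("bdx_convergence", "data.frame"),
            f3 = f3,
            monotone = all(diff(out$mean_abs_dev) < 0))
}
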