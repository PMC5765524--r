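#' Decompose inter-individual variance into stochasticity and heterogeneity
#'
#' The law of total variance applied to a finite mixture: the variance of an
#' outcome across a heterogeneous cohort equals the mixing-weighted mean of
#' the within-group variances (individual stochasticity - variance produced
#' by chance alone among individuals sharing identical rates) plus the
#' mixing-weighted variance of the group means (heterogeneity).
#'
#' @param mixing Mixing distribution over groups (non-negative, sums to 1).
#' @param group_means,group_vars Numeric vectors of per-group outcome means
#'   and variances.
#' @param outcome Optional outcome label stored in the result.
#' @return An object of class `variance_decomposition` with fields `within`,
#'   `between`, `total` (= within + between exactly), `pct_heterogeneity`
#'   and a `by_group` tibble.
#' @examples
#' decompose_variance(c(0.5, 0.5), group_means = c(0, 2),
#'                    group_vars = c(0, 0)) # all variance from heterogeneity
#' @export
decompose_variance <- function(mixing, group_means, group_vars,
                               outcome = NULL) {
  g <- length(mixing)
  check_probability(mixing, "mixing", g)
  if (abs(sum(mixing) - 1) > 1e-8) {
    abort(sprintf("`mixing` must sum to 1 (got %.10f).", sum(mixing)))
  }
  if (length(group_means) != g || length(group_vars) != g) {
    abort("`group_means` and `group_vars` must match `mixing` in length.")
  }
  if (anyNA(group_means) || anyNA(group_vars)) {
    abort("Group moments contain missing values; check for no-path groups upstream.")
  }
  if (any(group_vars < 0)) abort("`group_vars` must be non-negative.")
  within <- sum(mixing * group_vars)
  grand_mean <- sum(mixing * group_means)
  between <- sum(mixing * (group_means - grand_mean)^2)
  structure(
    list(
      within = within, between = between, total = within + between,
      pct_heterogeneity = if (within + between > 0) {
        100 * between / (within + between)
      } else 0,
      mean = grand_mean,
      outcome = outcome %||% "outcome",
      by_group = tibble(
        group = names(mixing) %||% paste0("group", seq_len(g)),
        weight = as.numeric(mixing),
        mean = as.numeric(group_means),
        variance = as.numeric(group_vars)
      )
    ),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("<variance_decomposition: %s>\n", x$outcome))
  cat(sprintf("  within (stochasticity): %.4f\n", x$within))
  cat(sprintf("  between (heterogeneity): %.4f\n", x$between))
  cat(sprintf("  total: %.4f  (%% heterogeneity: %.1f%%)\n",
              x$total, x$pct_heterogeneity))
  invisible(x)
}

#' @describeIn decompose_variance per-group moments as a tibble.
#' @param x A `variance_decomposition`.
#' @param ... Unused.
#' @export
tidy.variance_decomposition <- function(x, ...) x$by_group

#' @describeIn decompose_variance one-row summary of the decomposition.
#' @export
glance.variance_decomposition <- function(x, ...) {
  tibble(
    outcome = x$outcome, mean = x$mean, within = x$within,
    between = x$between, total = x$total,
    pct_heterogeneity = x$pct_heterogeneity
  )
}

# Per-group moments of a supported outcome, as a tibble with prob_event.
group_moments <- function(mixture, outcome, start) {
  start_name <- .stages[stage_index(start, "start")]
  rows <- lapply(mixture$chains, function(ch) {
    res <- switch(outcome,
      longevity = longevity(ch),
      lro = lifetime_output(ch),
      age_first_reproduction = first_passage(ch, target = c("S", "F")),
      age_first_success = first_passage(ch, target = "S"),
      abort(sprintf("Unsupported outcome '%s'.", outcome))
    )
    res[res$start == start_name, ]
  })
  out <- dplyr::bind_rows(rows)
  if ("no_path" %in% names(out) && any(out$no_path)) {
    abort(sprintf(
      "Outcome '%s' is unreachable from stage %s for group(s): %s.",
      outcome, start_name,
      paste(out$group[out$no_path], collapse = ", ")
    ))
  }
  out
}

#' Variance decomposition of a demographic outcome across a mixture
#'
#' Computes each group's analytic outcome moments from its absorbing chain
#' and feeds them into [decompose_variance()]. For first-passage outcomes
#' (age at first reproduction or first success), the group moments are
#' conditional on the event occurring before death; by default these
#' conditional moments are weighted by the unconditional mixing
#' distribution. Set `weights = "conditional"` to reweight groups by their
#' probability of experiencing the event.
#'
#' @param mixture A [mixture_model()].
#' @param outcome One of `"longevity"`, `"lro"`, `"age_first_reproduction"`,
#'   `"age_first_success"`.
#' @param start Starting stage (default pre-breeder).
#' @param weights `"mixing"` (default) or `"conditional"`.
#' @return A `variance_decomposition`.
#' @examples
#' decompose_outcome(southern_fulmar(), "lro")
#' @export
decompose_outcome <- function(mixture,
                              outcome = c("longevity", "lro",
                                          "age_first_reproduction",
                                          "age_first_success"),
                              start = "PB",
                              weights = c("mixing", "conditional")) {
  stopifnot(inherits(mixture, "mixture_model"))
  outcome <- match.arg(outcome)
  weights <- match.arg(weights)
  mom <- group_moments(mixture, outcome, start)
  w <- mixture$mixing
  if (weights == "conditional") {
    w <- w * mom$prob_event
    if (sum(w) == 0) {
      abort(sprintf("No group can reach outcome '%s'; cannot reweight.", outcome))
    }
    w <- w / sum(w)
  }
  decompose_variance(w, mom$mean, mom$variance, outcome = outcome)
}

#' Mixture-wide mean of a demographic outcome
#'
#' The mixing-weighted average of the per-group (conditional, for
#' first-passage outcomes) means - e.g. the expected longevity or lifetime
#' reproductive output of a fledgling drawn at random from the
#' heterogeneous cohort.
#'
#' @inheritParams decompose_outcome
#' @return A single number.
#' @examples
#' mixture_mean(southern_fulmar(), "lro") # about 3.7 offspring
#' @export
mixture_mean <- function(mixture, outcome = c("longevity", "lro",
                                              "age_first_reproduction",
                                              "age_first_success"),
                         start = "PB") {
  stopifnot(inherits(mixture, "mixture_model"))
  outcome <- match.arg(outcome)
  mom <- group_moments(mixture, outcome, start)
  sum(mixture$mixing * mom$mean)
}

#' Variance-component table across the standard outcomes
#'
#' Runs [decompose_outcome()] for longevity, lifetime reproductive output
#' and age at first reproduction from the pre-breeder stage and stacks the
#' results.
#'
#' @param mixture A [mixture_model()].
#' @return A tibble with one row per outcome: `outcome`, `mean`, `within`,
#'   `between`, `total`, `pct_heterogeneity`.
#' @examples
#' variance_table(southern_fulmar())
#' @export
variance_table <- function(mixture) {
  outcomes <- c("longevity", "lro", "age_first_reproduction")
  dplyr::bind_rows(lapply(outcomes, function(oc) {
    glance(decompose_outcome(mixture, oc))
  }))
}

#' Pooled (homogenized) chain of a mixture
#'
#' Replaces every group by the mixing-weighted average transient matrix.
#' Decomposing any outcome of the resulting mixture yields a between-group
#' component of exactly zero - useful as a no-heterogeneity reference.
#'
#' @param mixture A [mixture_model()].
#' @return A [mixture_model()] with the same number of groups, all sharing
#'   the averaged chain.
#' @export
homogenize_mixture <- function(mixture) {
  stopifnot(inherits(mixture, "mixture_model"))
  Ubar <- Reduce(`+`, Map(function(ch, w) w * ch$U,
                          mixture$chains, mixture$mixing))
  rates_bar <- recover_rates(list(U = Ubar, label = "pooled"))
  chains <- lapply(names(mixture$chains), function(lb) {
    r <- rates_bar
    r$label <- lb
    absorbing_chain(r)
  })
  mixture_model(chains, mixture$mixing)
}
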