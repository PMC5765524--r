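#' Finite mixture of absorbing life-cycle chains
#'
#' A cohort with fixed unobserved heterogeneity is modelled as a finite
#' mixture: each individual is assigned at fledging to one of `g` latent
#' groups (with probabilities given by the mixing distribution `mixing`) and
#' then follows that group's absorbing Markov chain for life.
#'
#' @param chains A list of [absorbing_chain()] or [vital_rates()] objects,
#'   one per group (vital rates are promoted to chains).
#' @param mixing Numeric vector of group probabilities; non-negative, summing
#'   to 1 (tolerance `1e-8`).
#' @return An object of class `mixture_model` with elements `chains`
#'   (named list), `mixing` (named vector), `g` and `s`.
#' @seealso [southern_fulmar()] for the packaged worked example,
#'   [mixture_from_rates()] to build one from a tidy rates table.
#' @export
mixture_model <- function(chains, mixing) {
  chains <- lapply(chains, function(ch) {
    if (inherits(ch, "vital_rates")) ch <- absorbing_chain(ch)
    if (!inherits(ch, "absorbing_chain")) {
      abort("`chains` must contain vital_rates or absorbing_chain objects.")
    }
    ch
  })
  g <- length(chains)
  if (g < 1) abort("`chains` must contain at least one group.")
  check_probability(mixing, "mixing", g)
  if (abs(sum(mixing) - 1) > 1e-8) {
    abort(sprintf("`mixing` must sum to 1 (got %.10f).", sum(mixing)))
  }
  labels <- vapply(chains, function(ch) ch$label, character(1))
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  names(chains) <- labels
  structure(
    list(chains = chains, mixing = setNames(as.numeric(mixing), labels),
         g = g, s = length(.stages)),
    class = "mixture_model"
  )
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model: %d groups x %d stages>\nmixing:\n", x$g, x$s))
  print(round(x$mixing, 4))
  invisible(x)
}

#' @describeIn mixture_model all vital rates as a long tibble.
#' @param x A `mixture_model`.
#' @param ... Unused.
#' @export
tidy.mixture_model <- function(x, ...) {
  dplyr::bind_rows(lapply(x$chains, function(ch) tidy(ch$rates)))
}

#' @describeIn mixture_model one-row summary (groups, stages, mixing range).
#' @export
glance.mixture_model <- function(x, ...) {
  tibble(
    groups = x$g, stages = x$s,
    mixing_min = min(x$mixing), mixing_max = max(x$mixing)
  )
}

#' Build a mixture model from a tidy rates table
#'
#' @param rates A tibble as returned by [read_vital_rates()]: columns
#'   `vital_rate`, `stage`, `group`, `value`.
#' @param mixing Either a numeric vector of group probabilities (in the order
#'   of `sort(unique(rates$group))` or named by group), or a named list/config
#'   with elements `groups` and `mixing`.
#' @return A [mixture_model()].
#' @export
mixture_from_rates <- function(rates, mixing) {
  stopifnot(is.data.frame(rates))
  groups <- sort(unique(rates$group))
  if (is.list(mixing) && !is.null(mixing$mixing)) {
    if (!is.null(mixing$groups)) {
      missing_groups <- setdiff(mixing$groups, groups)
      if (length(missing_groups) > 0) {
        abort(sprintf("Config names group(s) absent from the rates table: %s.",
                      paste(missing_groups, collapse = ", ")))
      }
      groups <- as.character(mixing$groups)
    }
    mixing <- as.numeric(mixing$mixing)
  } else if (!is.null(names(mixing))) {
    groups <- names(mixing)
  }
  chains <- lapply(groups, function(gr) {
    rates_from_table(rates[rates$group == gr, ], label = gr)
  })
  mixture_model(chains, mixing)
}

#' Read a mixture model from a rates CSV and a mixing config
#'
#' @param rates_file CSV path, see [read_vital_rates()] for the layout.
#' @param config_file YAML or JSON file with fields `mixing` (numeric vector)
#'   and optionally `groups` (character vector ordering the groups).
#' @return A [mixture_model()].
#' @export
read_mixture <- function(rates_file, config_file) {
  rates <- read_vital_rates(rates_file)
  config <- if (grepl("\\.json$", config_file, ignore.case = TRUE)) {
    jsonlite::read_json(config_file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config_file)
  }
  if (is.null(config$mixing)) {
    abort(sprintf("Config '%s' lacks a `mixing` field.", config_file))
  }
  mixture_from_rates(rates, config)
}

#' Southern fulmar heterogeneity fixture
#'
#' The packaged worked example: model-averaged stage-specific survival,
#' breeding and success probabilities for the southern fulmar (*Fulmarus
#' glacialoides*) breeding at Ile des Petrels, Antarctica, under ordinary
#' sea-ice conditions, with three latent heterogeneity groups (UH-1, UH-2,
#' UH-3) and fledgling mixing distribution (0.14, 0.67, 0.19).
#'
#' @return A [mixture_model()] with three groups.
#' @examples
#' fulmar <- southern_fulmar()
#' fulmar$mixing
#' @export
southern_fulmar <- function() {
  read_mixture(
    system.file("extdata", "fulmar_vital_rates.csv", package = "lifemix",
                mustWork = TRUE),
    system.file("extdata", "fulmar_mixing.yaml", package = "lifemix",
                mustWork = TRUE)
  )
}
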