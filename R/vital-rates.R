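#' Stage-specific vital rates for one heterogeneity group
#'
#' Bundles the three stage-specific vital rates that parameterize the annual
#' life cycle: survival \eqn{\sigma_j}, the conditional probability of
#' breeding given survival \eqn{\beta_j}, and the conditional probability of
#' success given survival and breeding \eqn{\gamma_j}. Stages are indexed in
#' the fixed order pre-breeder (PB), successful breeder (S), failed breeder
#' (F), non-breeder (NB).
#'
#' @param sigma,beta,gamma Numeric vectors of length 4 with entries in
#'   \[0, 1\], ordered PB, S, F, NB.
#' @param label Group identifier used in printed matrices and error messages.
#' @return An object of class `vital_rates`.
#' @examples
#' vital_rates(
#'   sigma = c(1.00, 0.93, 0.94, 0.88),
#'   beta  = c(0.10, 0.96, 0.81, 0.42),
#'   gamma = c(0.81, 0.80, 0.65, 0.66),
#'   label = "UH-1"
#' )
#' @export
vital_rates <- function(sigma, beta, gamma, label = "group") {
  s <- length(.stages)
  check_probability(sigma, "sigma", s)
  check_probability(beta, "beta", s)
  check_probability(gamma, "gamma", s)
  structure(
    list(
      sigma = setNames(as.numeric(sigma), .stages),
      beta = setNames(as.numeric(beta), .stages),
      gamma = setNames(as.numeric(gamma), .stages),
      label = as.character(label)[1]
    ),
    class = "vital_rates"
  )
}

#' @export
print.vital_rates <- function(x, ...) {
  cat(sprintf("<vital_rates: %s>\n", x$label))
  print(round(rbind(sigma = x$sigma, beta = x$beta, gamma = x$gamma), 4))
  invisible(x)
}

#' @describeIn vital_rates tidy the rates into a long tibble
#'   (`vital_rate`, `stage`, `value`, `group`).
#' @param x A `vital_rates` object.
#' @param ... Unused.
#' @export
tidy.vital_rates <- function(x, ...) {
  tibble(
    vital_rate = rep(c("survival", "breeding", "success"), each = 4),
    stage = rep(.stages, 3),
    value = unname(c(x$sigma, x$beta, x$gamma)),
    group = x$label
  )
}

#' Read a stage-by-group vital rates table
#'
#' Reads a CSV with columns `vital_rate` (`survival`, `breeding`, `success`),
#' `stage` (`PB`, `S`, `F`, `NB`) and one numeric column per heterogeneity
#' group, and returns a validated long tibble. Values outside \[0, 1\],
#' missing rate-stage combinations, or unknown labels are rejected (never
#' clamped), with the offending field named.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `vital_rate`, `stage`, `group`, `value`.
#' @seealso [mixture_from_rates()], [read_mixture()]
#' @export
read_vital_rates <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("vital_rate", "stage")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Rates file '%s' lacks required column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")))
  }
  groups <- setdiff(names(raw), required)
  if (length(groups) == 0) {
    abort(sprintf("Rates file '%s' has no group columns.", path))
  }
  long <- tidyr::pivot_longer(raw, cols = dplyr::all_of(groups),
                              names_to = "group", values_to = "value")
  bad_rate <- setdiff(unique(long$vital_rate),
                      c("survival", "breeding", "success"))
  if (length(bad_rate) > 0) {
    abort(sprintf("Unknown vital_rate value(s) in '%s': %s.",
                  path, paste(bad_rate, collapse = ", ")))
  }
  bad_stage <- setdiff(unique(long$stage), .stages)
  if (length(bad_stage) > 0) {
    abort(sprintf("Unknown stage value(s) in '%s': %s.",
                  path, paste(bad_stage, collapse = ", ")))
  }
  combos <- tidyr::expand_grid(
    vital_rate = c("survival", "breeding", "success"),
    stage = .stages, group = groups
  )
  merged <- dplyr::left_join(combos, long, by = c("vital_rate", "stage", "group"))
  if (anyNA(merged$value)) {
    miss <- merged[is.na(merged$value), c("vital_rate", "stage", "group")]
    abort(sprintf(
      "Rates file '%s' is missing value(s) for: %s.",
      path,
      paste(sprintf("%s/%s/%s", miss$vital_rate, miss$stage, miss$group),
            collapse = "; ")
    ))
  }
  check_probability(merged$value, sprintf("values in '%s'", path))
  merged$stage <- factor(merged$stage, levels = .stages)
  dplyr::arrange(as_tibble(merged), .data$group, .data$vital_rate, .data$stage)
}

# Long rates tibble (one group) -> vital_rates object.
rates_from_table <- function(tbl, label) {
  wide <- tidyr::pivot_wider(tbl, id_cols = "stage",
                             names_from = "vital_rate",
                             values_from = "value")
  wide <- wide[match(.stages, as.character(wide$stage)), ]
  vital_rates(wide$survival, wide$breeding, wide$success, label = label)
}
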