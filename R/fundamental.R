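#' Fundamental matrix of an absorbing chain
#'
#' `N = (I - U)^{-1}`, computed by a conditioned linear solve. Entry
#' `N[i, j]` is the expected number of annual censuses spent in stage `i`
#' before death by an individual currently in stage `j`, counting the
#' current census (so diagonal entries are at least 1).
#'
#' @param chain An [absorbing_chain()], or a transient matrix `U` directly.
#' @return A 4 x 4 matrix of expected occupancy times.
#' @examples
#' fundamental_matrix(matrix(0.5)) # geometric: 1 / (1 - 0.5)
#' @export
fundamental_matrix <- function(chain) {
  U <- if (inherits(chain, "absorbing_chain")) chain$U else as.matrix(chain)
  label <- if (inherits(chain, "absorbing_chain")) chain$label else NULL
  N <- solve_survival_system(U, label = label)
  dimnames(N) <- dimnames(U)
  N
}

#' Variance of stage occupancy times
#'
#' `V = (2 N_dg - I) N - N * N` (elementwise square in the last term), where
#' `N_dg` carries the diagonal of the fundamental matrix. Entry `V[i, j]` is
#' the variance of the time spent in stage `i` over the remaining life of an
#' individual in stage `j`.
#'
#' @param N A fundamental matrix, or an [absorbing_chain()] from which one is
#'   computed.
#' @return A matrix of occupancy-time variances (non-negative).
#' @export
occupancy_variance <- function(N) {
  if (inherits(N, "absorbing_chain")) N <- fundamental_matrix(N)
  N <- as.matrix(N)
  s <- nrow(N)
  V <- (2 * diag(diag(N), s) - diag(s)) %*% N - N * N
  # exact zeros can come out as -1e-16 from the subtraction
  V[V < 0 & V > -1e-9] <- 0
  dimnames(V) <- dimnames(N)
  V
}

# Shared shape for per-starting-stage outcome moments.
outcome_tibble <- function(start, mean, variance, prob_event = 1,
                           group = NULL) {
  out <- tibble(
    start = start,
    prob_event = rep_len(prob_event, length(start)),
    mean = as.numeric(mean),
    variance = as.numeric(variance)
  )
  if (!is.null(group)) out <- dplyr::mutate(out, group = group, .before = 1)
  out
}

#' Moments of longevity by starting stage
#'
#' Longevity is the total number of annual censuses an individual is alive,
#' counting the current one: its mean by starting stage is the column sum of
#' the fundamental matrix, and its variance is
#' `1' N (2N - I) - mean * mean`.
#'
#' @param chain An [absorbing_chain()].
#' @return A tibble with one row per starting stage: `group`, `start`,
#'   `prob_event` (1: death is certain), `mean`, `variance`.
#' @examples
#' ch <- absorbing_chain(vital_rates(
#'   c(1.00, 0.92, 0.93, 0.88), c(0.10, 0.80, 0.80, 0.55),
#'   c(0.81, 0.85, 0.64, 0.66)))
#' longevity(ch)
#' @export
longevity <- function(chain) {
  stopifnot(inherits(chain, "absorbing_chain"))
  N <- fundamental_matrix(chain)
  s <- nrow(N)
  eta <- colSums(N)
  second <- colSums(N %*% (2 * N - diag(s)))
  outcome_tibble(.stages, eta, second - eta^2, 1, chain$label)
}

#' Moments of lifetime reproductive output by starting stage
#'
#' With one offspring per successful breeding season, lifetime reproductive
#' output equals the time spent in the successful-breeder stage, so its mean
#' (variance) by starting stage is row `S` of the fundamental (occupancy
#' variance) matrix.
#'
#' @param chain An [absorbing_chain()].
#' @return A tibble with one row per starting stage: `group`, `start`,
#'   `prob_event`, `mean`, `variance`.
#' @export
lifetime_output <- function(chain) {
  stopifnot(inherits(chain, "absorbing_chain"))
  N <- fundamental_matrix(chain)
  V <- occupancy_variance(N)
  outcome_tibble(.stages, N["S", ], V["S", ], 1, chain$label)
}

#' Expected stage occupancy and proportion of life per stage
#'
#' Divides each expected stage-occupancy time by the total expected
#' remaining lifetime, giving the mean proportion of (remaining) life spent
#' in each stage. `start` may be a single stage or a probability
#' distribution over stages (e.g. the recruitment outcome distribution of
#' [recruitment_start()] for "adult life" summaries), in which case columns
#' of the fundamental matrix are mixed before normalizing.
#'
#' @param chain An [absorbing_chain()].
#' @param start A stage name/index, or a numeric vector of length 4 of
#'   starting-stage weights (need not sum to 1; rescaled).
#' @return A tibble with columns `group`, `stage`, `expected_years`,
#'   `proportion`.
#' @examples
#' fulmar <- southern_fulmar()
#' stage_occupancy(fulmar$chains[["UH-2"]], start = "PB")
#' @export
stage_occupancy <- function(chain, start = "PB") {
  stopifnot(inherits(chain, "absorbing_chain"))
  N <- fundamental_matrix(chain)
  if (is.numeric(start) && length(start) == nrow(N)) {
    w <- start / sum(start)
    occ <- as.vector(N %*% w)
  } else {
    occ <- N[, stage_index(start, "start")]
  }
  occ <- unname(occ)
  tibble(
    group = chain$label,
    stage = .stages,
    expected_years = occ,
    proportion = occ / sum(occ)
  )
}

#' Starting distribution over breeding states at recruitment
#'
#' The outcome of the recruitment event for a pre-breeder of this group:
#' weight `gamma_PB` on the successful-breeder stage and `1 - gamma_PB` on
#' the failed-breeder stage. Used as the starting distribution for
#' adult-life occupancy summaries.
#'
#' @param chain An [absorbing_chain()].
#' @return A numeric vector of length 4 summing to 1.
#' @export
recruitment_start <- function(chain) {
  stopifnot(inherits(chain, "absorbing_chain"))
  g1 <- chain$rates$gamma[["PB"]]
  setNames(c(0, g1, 1 - g1, 0), .stages)
}
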