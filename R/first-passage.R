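#' Conditional first-passage analysis of a life-cycle event
#'
#' Computes, for each starting stage, the probability that the individual
#' ever *enters* one of the `target` stages before dying, and the mean and
#' variance of the number of annual steps until that first entry,
#' conditional on it happening.
#'
#' The event is made into an absorbing state competing with death: every
#' transition into the target set is redirected to a new "event" absorbing
#' state (the target stages themselves stay in the state space, so a chain
#' may *start* in a target stage - e.g. an inter-breeding interval starts at
#' a breeding stage and waits for the next entry). Conditioning uses the
#' standard Bayes reweighting of the transient matrix,
#' `Uc[i, j] = U'[i, j] * b[i] / b[j]`, where `b[j]` is the probability of
#' eventual event-absorption from stage `j`; stages that cannot reach the
#' event (`b = 0`) are dropped from the conditional chain. Moments then
#' follow from the fundamental matrix of `Uc`.
#'
#' @param chain An [absorbing_chain()].
#' @param target Stage names or indices whose entry constitutes the event
#'   (e.g. `c("S", "F")` for recruitment, `"S"` for a successful season).
#' @param start Optional subset of starting stages to report (default: all).
#' @return A tibble with one row per starting stage: `group`, `start`,
#'   `prob_event`, `mean`, `variance`, and `no_path` (`TRUE` where the event
#'   is unreachable; such rows carry `prob_event = 0` and `NA` moments
#'   rather than `NaN`).
#' @examples
#' fulmar <- southern_fulmar()
#' # age at first recruitment of a UH-3 fledgling
#' first_passage(fulmar$chains[["UH-3"]], target = c("S", "F"), start = "PB")
#' @export
first_passage <- function(chain, target, start = NULL) {
  stopifnot(inherits(chain, "absorbing_chain"))
  tset <- unique(stage_index(target, "target"))
  if (length(tset) == 0) abort("`target` must name at least one stage.")
  U <- chain$U
  s <- nrow(U)

  # redirect entries into the target set to an absorbing "event" state
  event_row <- colSums(U[tset, , drop = FALSE])
  Umod <- U
  Umod[tset, ] <- 0

  Nmod <- solve_survival_system(Umod, label = chain$label)
  b <- as.vector(event_row %*% Nmod) # P(event before death | start j)
  b <- pmin(pmax(b, 0), 1)           # guard roundoff outside [0, 1]
  names(b) <- .stages

  means <- vars <- rep(NA_real_, s)
  reachable <- b > 1e-14
  if (any(reachable)) {
    keep <- which(reachable)
    Uc <- Umod[keep, keep, drop = FALSE] *
      outer(b[keep], b[keep], function(bi, bj) bi / bj)
    k <- length(keep)
    Nc <- solve_survival_system(Uc, label = chain$label)
    mu <- colSums(Nc)
    second <- colSums(Nc %*% (2 * Nc - diag(k)))
    means[keep] <- mu
    vars[keep] <- pmax(second - mu^2, 0)
  }
  b[!reachable] <- 0

  out <- outcome_tibble(.stages, means, vars, prob_event = b,
                        group = chain$label)
  out$no_path <- !reachable
  if (!is.null(start)) out <- out[stage_index(start, "start"), ]
  out
}

#' Age at first reproduction and first successful reproduction
#'
#' Convenience wrappers around [first_passage()] for a fledgling
#' (pre-breeder) start. "First reproduction" (recruitment) is the first
#' entry into either breeding stage; "first successful reproduction" is the
#' first entry into the successful-breeder stage, with failed attempts en
#' route treated as transient detours.
#'
#' @param chain An [absorbing_chain()].
#' @return A tibble row as in [first_passage()] (start = `PB`).
#' @export
age_first_reproduction <- function(chain) {
  first_passage(chain, target = c("S", "F"), start = "PB")
}

#' @rdname age_first_reproduction
#' @export
age_first_success <- function(chain) {
  first_passage(chain, target = "S", start = "PB")
}

#' Inter-breeding interval from each adult stage
#'
#' Conditional mean time for an adult to reach its next breeding event. The
#' default (`type = "success"`) measures the interval to the next
#' *successful* breeding season (first entry into the successful-breeder
#' stage, failed seasons en route being transient), which is the convention
#' under which the published fulmar interval table is reproduced.
#' `type = "attempt"` instead absorbs on the next breeding attempt of either
#' outcome (first entry into `{S, F}`).
#'
#' @param chain An [absorbing_chain()].
#' @param from Adult starting stage(s): subset of `S`, `F`, `NB`.
#' @param type `"success"` (default) or `"attempt"`.
#' @return A tibble as in [first_passage()], one row per `from` stage.
#' @examples
#' fulmar <- southern_fulmar()
#' breeding_interval(fulmar$chains[["UH-1"]])
#' @export
breeding_interval <- function(chain, from = c("S", "F", "NB"),
                              type = c("success", "attempt")) {
  type <- match.arg(type)
  idx <- stage_index(from, "from")
  if (any(idx == 1L)) {
    abort("`from` must be an adult stage (S, F or NB); use age_first_reproduction() for pre-breeders.")
  }
  target <- if (type == "success") "S" else c("S", "F")
  first_passage(chain, target = target, start = from)
}

#' Published-style demographic outcome table for a mixture
#'
#' Assembles, per heterogeneity group, the first-passage outcomes of the
#' life cycle: age at first recruitment, age at first successful
#' reproduction (each with the probability that the event precedes death),
#' and the inter-breeding interval from each adult stage.
#'
#' @param mixture A [mixture_model()].
#' @param interval_type Passed to [breeding_interval()].
#' @return A tibble with columns `group`, `outcome`, `start`, `prob_event`,
#'   `mean`, `variance`, `no_path`.
#' @examples
#' outcome_table(southern_fulmar())
#' @export
outcome_table <- function(mixture, interval_type = "success") {
  stopifnot(inherits(mixture, "mixture_model"))
  per_chain <- function(ch) {
    dplyr::bind_rows(
      dplyr::mutate(age_first_reproduction(ch),
                    outcome = "age_first_reproduction"),
      dplyr::mutate(age_first_success(ch), outcome = "age_first_success"),
      dplyr::mutate(breeding_interval(ch, type = interval_type),
                    outcome = "breeding_interval")
    )
  }
  out <- dplyr::bind_rows(lapply(mixture$chains, per_chain))
  dplyr::relocate(out, "group", "outcome", "start")
}
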