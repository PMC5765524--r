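#' Simulate a single life trajectory
#'
#' Individual-based realization of one group's life cycle: each year the
#' individual survives with the probability of its current stage, then (if
#' alive) breeds, then (if breeding) succeeds, and moves to the stage
#' implied by those outcomes. The stage sequence starts at the fledging
#' census (pre-breeder, year 0); longevity counts every census at which the
#' individual is alive, including the first.
#'
#' @param rates A [vital_rates()] object.
#' @param max_years Safety cap on lifespan; a trajectory still alive at the
#'   cap is flagged `censored` rather than silently truncated.
#' @return An object of class `life_trajectory`: list with `stages`
#'   (character vector of annual stages), `group`, `longevity`, `lro`,
#'   `age_first_reproduction`, `age_first_success` (each `NA` if the event
#'   never happened) and `censored`.
#' @examples
#' set.seed(1)
#' simulate_individual(vital_rates(
#'   c(1.00, 0.89, 0.93, 0.88), c(0.16, 0.97, 0.80, 0.55),
#'   c(1.00, 0.99, 0.66, 0.66)))
#' @export
simulate_individual <- function(rates, max_years = 1000) {
  stopifnot(inherits(rates, "vital_rates"))
  stage <- 1L
  stages <- integer(0)
  for (t in seq_len(max_years)) {
    stages[t] <- stage
    if (runif(1) >= rates$sigma[stage]) {
      return(new_life_trajectory(stages, rates$label, censored = FALSE))
    }
    if (runif(1) < rates$beta[stage]) {
      stage <- if (runif(1) < rates$gamma[stage]) 2L else 3L
    } else {
      stage <- if (stage == 1L) 1L else 4L
    }
  }
  new_life_trajectory(stages, rates$label, censored = TRUE)
}

new_life_trajectory <- function(stages, group, censored) {
  first_rep <- match(TRUE, stages %in% c(2L, 3L)) - 1L
  first_succ <- match(2L, stages) - 1L
  structure(
    list(
      stages = .stages[stages],
      group = group,
      longevity = length(stages),
      lro = sum(stages == 2L),
      age_first_reproduction = if (is.na(first_rep)) NA_integer_ else first_rep,
      age_first_success = if (is.na(first_succ)) NA_integer_ else first_succ,
      censored = censored
    ),
    class = "life_trajectory"
  )
}

#' @export
print.life_trajectory <- function(x, ...) {
  cat(sprintf(
    "<life_trajectory: %s> longevity %d, lro %d%s\n  %s\n",
    x$group, x$longevity, x$lro,
    if (x$censored) " (censored)" else "",
    paste(x$stages, collapse = " ")
  ))
  invisible(x)
}

# Vectorized engine shared by simulate_cohort() and simulate_captures().
# Groups are drawn i.i.d. from the mixing distribution, then the whole
# cohort is advanced year by year with a single RNG stream; `record`
# additionally stores the full stage sequence (0 = dead).
simulate_engine <- function(mixture, n, seed = NULL, max_years = 1000,
                            record = FALSE, record_years = max_years) {
  stopifnot(inherits(mixture, "mixture_model"))
  n <- as.integer(n)
  if (n < 1) abort("`n` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)

  g <- mixture$g
  sig <- t(vapply(mixture$chains, function(ch) ch$rates$sigma, numeric(4)))
  bet <- t(vapply(mixture$chains, function(ch) ch$rates$beta, numeric(4)))
  gam <- t(vapply(mixture$chains, function(ch) ch$rates$gamma, numeric(4)))

  grp <- sample.int(g, n, replace = TRUE, prob = mixture$mixing)
  stage <- rep(1L, n)
  alive <- rep(TRUE, n)
  longevity <- rep(1L, n)
  lro <- integer(n)
  first_rep <- rep(NA_integer_, n)
  first_succ <- rep(NA_integer_, n)
  hist <- NULL
  if (record) {
    hist <- matrix(0L, n, record_years)
    hist[, 1L] <- 1L
  }

  t <- 0L
  while (any(alive) && t < max_years - 1L) {
    t <- t + 1L
    ia <- which(alive)
    idx <- cbind(grp[ia], stage[ia])
    surv <- runif(length(ia)) < sig[idx]
    died <- ia[!surv]
    alive[died] <- FALSE
    ia <- ia[surv]
    if (length(ia) > 0) {
      idx <- cbind(grp[ia], stage[ia])
      breeds <- runif(length(ia)) < bet[idx]
      succ <- logical(length(ia))
      if (any(breeds)) {
        ib <- which(breeds)
        succ[ib] <- runif(length(ib)) <
          gam[cbind(grp[ia[ib]], stage[ia[ib]])]
      }
      new_stage <- ifelse(breeds, ifelse(succ, 2L, 3L),
                          ifelse(stage[ia] == 1L, 1L, 4L))
      stage[ia] <- new_stage
      longevity[ia] <- longevity[ia] + 1L
      lro[ia] <- lro[ia] + (new_stage == 2L)
      newly_rep <- ia[new_stage %in% c(2L, 3L) & is.na(first_rep[ia])]
      first_rep[newly_rep] <- t
      newly_succ <- ia[new_stage == 2L & is.na(first_succ[ia])]
      first_succ[newly_succ] <- t
      if (record && t < record_years) {
        hist[cbind(ia, t + 1L)] <- new_stage
      }
    }
  }

  list(
    outcomes = tibble(
      id = seq_len(n),
      group = names(mixture$chains)[grp],
      longevity = longevity,
      lro = lro,
      age_first_reproduction = first_rep,
      age_first_success = first_succ,
      recruited = !is.na(first_rep),
      censored = alive
    ),
    history = hist,
    group_index = grp
  )
}

#' Simulate a heterogeneous cohort
#'
#' Draws `n` individuals from the mixture (group membership i.i.d. from the
#' mixing distribution) and simulates each life trajectory, tabulating the
#' demographic outcomes. This is the package's independent Monte Carlo
#' counterpart to the analytic Markov chain results: with the same rates,
#' empirical moments converge on [longevity()], [lifetime_output()] and
#' [first_passage()] values.
#'
#' @param mixture A [mixture_model()].
#' @param n Cohort size.
#' @param seed Optional integer seed; a given seed and `n` reproduce the
#'   table exactly.
#' @param max_years Lifespan cap (see [simulate_individual()]).
#' @return A tibble with columns `id`, `group`, `longevity`, `lro`,
#'   `age_first_reproduction`, `age_first_success` (NA when the event never
#'   occurred), `recruited`, `censored`.
#' @examples
#' sim <- simulate_cohort(southern_fulmar(), n = 1000, seed = 42)
#' mean(sim$longevity)
#' @export
simulate_cohort <- function(mixture, n, seed = NULL, max_years = 1000) {
  simulate_engine(mixture, n, seed = seed, max_years = max_years)$outcomes
}

#' Empirical summaries of simulated outcomes
#'
#' Per-group and pooled means and variances (with standard errors) of the
#' simulated demographic outcomes, using the same conventions as the
#' analytic results: ages at first reproduction/success are summarized
#' conditionally, among individuals that experienced the event.
#'
#' @param outcomes A tibble from [simulate_cohort()].
#' @return A tibble with columns `scope` (`"group"` or `"pooled"`), `group`,
#'   `outcome`, `n`, `mean`, `variance`, `se_mean`, `se_variance`.
#' @export
cohort_summaries <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) > 0)
  one <- function(x, scope, group, outcome) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0) {
      return(tibble(scope = scope, group = group, outcome = outcome,
                    n = 0L, mean = NA_real_, variance = NA_real_,
                    se_mean = NA_real_, se_variance = NA_real_))
    }
    m <- mean(x)
    v <- if (n > 1) var(x) else 0
    # SE of the sample variance from the empirical 2nd/4th central moments
    se_v <- if (n > 1) {
      m4 <- mean((x - m)^4)
      sqrt(pmax(m4 - v^2, 0) / n)
    } else NA_real_
    tibble(scope = scope, group = group, outcome = outcome, n = n,
           mean = m, variance = v,
           se_mean = if (n > 1) sqrt(v / n) else 0, se_variance = se_v)
  }
  cols <- c("longevity", "lro", "age_first_reproduction", "age_first_success")
  blocks <- list()
  for (oc in cols) {
    blocks[[length(blocks) + 1L]] <- one(outcomes[[oc]], "pooled", "all", oc)
    for (gr in sort(unique(outcomes$group))) {
      blocks[[length(blocks) + 1L]] <-
        one(outcomes[[oc]][outcomes$group == gr], "group", gr, oc)
    }
  }
  dplyr::bind_rows(blocks)
}

#' Generate synthetic capture histories
#'
#' Overlays stage-dependent detection on simulated life trajectories to
#' emulate a multistate mark-recapture data set of individuals banded as
#' fledglings. The banding occasion (year 1) is always observed; in later
#' years a living individual in stage `j` is seen with probability
#' `detection[j]` and coded by its stage, otherwise coded 0 (not seen; dead
#' individuals are never seen).
#'
#' @param mixture A [mixture_model()].
#' @param detection Per-stage detection probabilities: a numeric vector of
#'   length 4 (PB, S, F, NB) or a `g x 4` matrix for group-dependent
#'   detection.
#' @param n Number of individuals.
#' @param years Number of annual occasions (columns).
#' @param seed Optional integer seed.
#' @return A tibble with columns `id`, `group` and `y1 ... y<years>` holding
#'   codes 0 (not seen) or 1-4 (seen, stage index in PB, S, F, NB order).
#' @examples
#' ch <- simulate_captures(southern_fulmar(), detection = rep(0.9, 4),
#'                         n = 50, years = 10, seed = 7)
#' dim(ch)
#' @export
simulate_captures <- function(mixture, detection, n, years, seed = NULL) {
  stopifnot(inherits(mixture, "mixture_model"))
  years <- as.integer(years)
  if (years < 1) abort("`years` must be >= 1.")
  if (is.matrix(detection)) {
    stopifnot(nrow(detection) == mixture$g, ncol(detection) == 4)
    check_probability(as.vector(detection), "detection")
    det <- detection
  } else {
    check_probability(detection, "detection", 4)
    det <- matrix(rep(detection, each = mixture$g), mixture$g, 4)
  }
  sim <- simulate_engine(mixture, n, seed = seed, record = TRUE,
                         record_years = years)
  hist <- sim$history[, seq_len(years), drop = FALSE]
  obs <- hist
  alive_mask <- hist > 0L
  if (any(alive_mask)) {
    p <- matrix(0, nrow(hist), ncol(hist))
    p[alive_mask] <- det[cbind(
      sim$group_index[row(hist)[alive_mask]], hist[alive_mask]
    )]
    seen <- matrix(runif(length(hist)), nrow(hist)) < p
    seen[, 1L] <- TRUE # banding occasion
    obs[!seen] <- 0L
  }
  colnames(obs) <- paste0("y", seq_len(years))
  dplyr::bind_cols(
    tibble(id = seq_len(n), group = names(mixture$chains)[sim$group_index]),
    as_tibble(obs)
  )
}
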