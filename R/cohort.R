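#' Vec-permutation matrix
#'
#' The permutation matrix `K` that converts a stage-by-group population
#' vector from group-major ordering (stages contiguous within each group,
#' the package's convention for cohort vectors) to stage-major ordering
#' (groups contiguous within each stage, the ordering on which the
#' group-transition blocks act). `K` satisfies `t(K) %*% K == I`.
#'
#' Index map: group-major position of (stage `i`, group `k`) is
#' `(k - 1) * s + i`; stage-major position is `(i - 1) * g + k`.
#'
#' @param s Number of stages.
#' @param g Number of groups.
#' @return An `s g` x `s g` 0/1 permutation matrix.
#' @examples
#' vec_permutation(2, 2) # swaps the two middle coordinates
#' @export
vec_permutation <- function(s, g) {
  s <- as.integer(s); g <- as.integer(g)
  if (s < 1 || g < 1) abort("`s` and `g` must be >= 1.")
  n <- s * g
  K <- matrix(0, n, n)
  for (i in seq_len(s)) {
    for (k in seq_len(g)) {
      K[(i - 1L) * g + k, (k - 1L) * s + i] <- 1
    }
  }
  K
}

#' Block-structured projection matrix for a heterogeneous cohort
#'
#' Assembles `Utilde = t(K) %*% Dblk %*% K %*% Ublk`, where `Ublk` is the
#' block diagonal of the per-group transient matrices (acting on the
#' group-major cohort vector) and `Dblk` is the block diagonal of per-stage
#' `g x g` group-transition matrices (acting stage-major). With fixed
#' heterogeneity every `D_i` is the identity and `Utilde` reduces exactly to
#' `Ublk`.
#'
#' @param mixture A [mixture_model()].
#' @param D `NULL` (fixed heterogeneity, the default) or a list of `s`
#'   column-stochastic `g x g` matrices.
#' @return An object of class `block_projection` with elements `U_tilde`,
#'   `K`, `U_blk`, `D_blk`, `s`, `g`, `labels`.
#' @export
block_projection <- function(mixture, D = NULL) {
  stopifnot(inherits(mixture, "mixture_model"))
  s <- mixture$s; g <- mixture$g
  K <- vec_permutation(s, g)
  U_blk <- matrix(0, s * g, s * g)
  for (k in seq_len(g)) {
    idx <- (k - 1L) * s + seq_len(s)
    U_blk[idx, idx] <- mixture$chains[[k]]$U
  }
  if (is.null(D)) D <- replicate(s, diag(g), simplify = FALSE)
  if (length(D) != s) abort(sprintf("`D` must be a list of %d matrices.", s))
  D_blk <- matrix(0, s * g, s * g)
  for (i in seq_len(s)) {
    Di <- as.matrix(D[[i]])
    if (!all(dim(Di) == c(g, g))) {
      abort(sprintf("D[[%d]] must be %d x %d.", i, g, g))
    }
    if (any(Di < 0) || max(abs(colSums(Di) - 1)) > 1e-9) {
      abort(sprintf("D[[%d]] must be column-stochastic.", i))
    }
    idx <- (i - 1L) * g + seq_len(g)
    D_blk[idx, idx] <- Di
  }
  structure(
    list(U_tilde = t(K) %*% D_blk %*% K %*% U_blk,
         K = K, U_blk = U_blk, D_blk = D_blk,
         s = s, g = g, labels = names(mixture$chains)),
    class = "block_projection"
  )
}

#' Project a heterogeneous cohort through time
#'
#' Iterates `n(t + 1) = Utilde n(t)` from an initial stage-by-group
#' abundance vector. There is no reproduction: the projection is pure
#' attrition, tracking survival and stage movement of the founding cohort.
#' The default initial cohort places the mixing distribution on the
#' pre-breeder stage of each group (a fledgling cohort of total size 1).
#'
#' @param mixture A [mixture_model()] or a prebuilt [block_projection()].
#' @param n0 Optional initial cohort: either a group-major numeric vector of
#'   length `s * g`, or a `s x g` matrix (stages x groups).
#' @param horizon Number of annual steps to project (default 100).
#' @param D Optional group-transition blocks, passed to [block_projection()].
#' @return A `cohort_trajectory`: a tibble with columns `t`, `group`,
#'   `stage`, `abundance` (all `t = 0, ..., horizon`).
#' @examples
#' traj <- project_cohort(southern_fulmar(), horizon = 20)
#' dplyr::filter(cohort_composition(traj), t == 20)
#' @export
project_cohort <- function(mixture, n0 = NULL, horizon = 100, D = NULL) {
  bp <- if (inherits(mixture, "block_projection")) {
    mixture
  } else {
    block_projection(mixture, D = D)
  }
  s <- bp$s; g <- bp$g
  if (is.null(n0)) {
    if (!inherits(mixture, "mixture_model")) {
      abort("Supply `n0` when projecting from a block_projection.")
    }
    n0 <- matrix(0, s, g)
    n0[1, ] <- mixture$mixing
  }
  n0 <- if (is.matrix(n0)) as.vector(n0) else as.numeric(n0)
  if (length(n0) != s * g) {
    abort(sprintf("`n0` must have %d entries (s x g, group-major).", s * g))
  }
  if (any(n0 < 0)) abort("`n0` must be non-negative.")
  horizon <- as.integer(horizon)
  if (horizon < 0) abort("`horizon` must be >= 0.")

  states <- matrix(0, s * g, horizon + 1L)
  states[, 1L] <- n0
  for (t in seq_len(horizon)) {
    states[, t + 1L] <- bp$U_tilde %*% states[, t]
  }
  labels <- bp$labels %||% paste0("group", seq_len(g))
  out <- tibble(
    t = rep(0:horizon, each = s * g),
    group = rep(rep(labels, each = s), horizon + 1L),
    stage = rep(rep(.stages[seq_len(s)], g), horizon + 1L),
    abundance = as.vector(states)
  )
  structure(out, class = c("cohort_trajectory", class(out)),
            initial_total = sum(n0))
}

#' Composition and survivorship of a projected cohort
#'
#' Summarizes a [project_cohort()] trajectory: at each time the fraction of
#' the initial cohort still alive (`survivorship`) and the shares of the
#' survivors by group and by stage. Once the cohort is (numerically)
#' extinct, shares are reported as `NA` with `alive = FALSE` rather than
#' `NaN`.
#'
#' @param traj A `cohort_trajectory`.
#' @return A tibble with columns `t`, `unit` (`"group"` or `"stage"`),
#'   `name`, `share`, `survivorship`, `alive`.
#' @export
cohort_composition <- function(traj) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  n0_total <- attr(traj, "initial_total")
  totals <- dplyr::summarise(dplyr::group_by(as_tibble(traj), .data$t),
                             total = sum(.data$abundance), .groups = "drop")
  share_by <- function(unit_col, unit_name) {
    by <- dplyr::summarise(
      dplyr::group_by(as_tibble(traj), .data$t, .data[[unit_col]]),
      abundance = sum(.data$abundance), .groups = "drop"
    )
    by <- dplyr::left_join(by, totals, by = "t")
    dplyr::transmute(
      by,
      t = .data$t, unit = unit_name, name = .data[[unit_col]],
      alive = .data$total > n0_total * 1e-12,
      share = dplyr::if_else(.data$alive, .data$abundance / .data$total,
                             NA_real_),
      survivorship = .data$total / n0_total
    )
  }
  out <- dplyr::bind_rows(share_by("group", "group"), share_by("stage", "stage"))
  dplyr::arrange(out, .data$t, .data$unit, .data$name)
}
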