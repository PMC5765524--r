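#' Transient transition matrix of the breeding-state life cycle
#'
#' Assembles the 4 x 4 column-stochastic-oriented transient matrix `U` from
#' stage-specific vital rates. Column `j` holds the fates of a survivor of
#' stage `j`: a pre-breeder that does not breed remains a pre-breeder
#' (`U[1,1] = (1 - beta_1) sigma_1`), any stage that breeds moves to
#' successful breeder with probability `sigma_j beta_j gamma_j` or failed
#' breeder with probability `sigma_j beta_j (1 - gamma_j)`, and adults that
#' skip breeding become non-breeders (`U[4,j] = sigma_j (1 - beta_j)`,
#' `j > 1`). The pre-breeder stage is never re-entered (`U[1,j] = 0` for
#' `j > 1`).
#'
#' @param rates A [vital_rates()] object.
#' @return A 4 x 4 numeric matrix with stages as dimnames; columns are
#'   from-stages, rows are to-stages.
#' @examples
#' u <- transient_matrix(vital_rates(
#'   c(1.00, 0.93, 0.94, 0.88), c(0.10, 0.96, 0.81, 0.42),
#'   c(0.81, 0.80, 0.65, 0.66)))
#' colSums(u) # per-stage survival
#' @export
transient_matrix <- function(rates) {
  stopifnot(inherits(rates, "vital_rates"))
  sg <- rates$sigma
  be <- rates$beta
  ga <- rates$gamma
  U <- matrix(0, 4, 4, dimnames = list(.stages, .stages))
  U[1, 1] <- (1 - be[1]) * sg[1]
  U[2, ] <- sg * be * ga
  U[3, ] <- sg * be * (1 - ga)
  U[4, 2:4] <- sg[2:4] * (1 - be[2:4])
  U
}

#' Mortality (absorption) row of the life cycle
#'
#' @param rates A [vital_rates()] object.
#' @return A 1 x 4 matrix of per-stage probabilities of death,
#'   `m_j = 1 - sigma_j`, so that the columns of `rbind(U, M)` sum to 1.
#' @export
mortality_matrix <- function(rates) {
  stopifnot(inherits(rates, "vital_rates"))
  matrix(1 - rates$sigma, nrow = 1,
         dimnames = list("dead", .stages))
}

#' Absorbing Markov chain for one heterogeneity group
#'
#' Combines the transient matrix `U` and the mortality row `M` into the full
#' column-stochastic transition matrix `P = [U 0; M 1]` of the absorbing
#' chain (death absorbing). The column-stochastic orientation (from-stage =
#' column, operating on column vectors) is used throughout the package.
#'
#' @param rates A [vital_rates()] object.
#' @return An object of class `absorbing_chain` with elements `U`, `M`, `P`,
#'   `rates` and `label`.
#' @examples
#' ch <- absorbing_chain(vital_rates(
#'   c(1.00, 0.93, 0.94, 0.88), c(0.10, 0.96, 0.81, 0.42),
#'   c(0.81, 0.80, 0.65, 0.66), label = "UH-1"))
#' colSums(ch$P)
#' @export
absorbing_chain <- function(rates) {
  U <- transient_matrix(rates)
  M <- mortality_matrix(rates)
  P <- rbind(cbind(U, matrix(0, 4, 1)), cbind(M, 1))
  dimnames(P) <- list(c(.stages, "dead"), c(.stages, "dead"))
  stopifnot(max(abs(colSums(P) - 1)) < 1e-12)
  structure(
    list(U = U, M = M, P = P, rates = rates, label = rates$label),
    class = "absorbing_chain"
  )
}

#' @export
print.absorbing_chain <- function(x, ...) {
  cat(sprintf("<absorbing_chain: %s>\nU (transient):\n", x$label))
  print(round(x$U, 4))
  cat("M (mortality):\n")
  print(round(x$M, 4))
  invisible(x)
}

#' @describeIn absorbing_chain tidy the full transition matrix into a long
#'   tibble (`to`, `from`, `probability`, `group`).
#' @param x An `absorbing_chain`.
#' @param ... Unused.
#' @export
tidy.absorbing_chain <- function(x, ...) {
  out <- matrix_tidy(x$P, "probability")
  out$group <- x$label
  out
}

# Recover vital rates from an assembled chain (inverse of the construction,
# defined wherever sigma_j > 0 and beta_j > 0; degenerate entries fall back
# to 0). Used to guard against silent orientation bugs.
recover_rates <- function(chain) {
  U <- chain$U
  sigma <- colSums(U)
  breeding_mass <- U[2, ] + U[3, ]
  beta <- ifelse(sigma > 0, breeding_mass / sigma, 0)
  gamma <- ifelse(breeding_mass > 0, U[2, ] / breeding_mass, 0)
  vital_rates(sigma, pmin(beta, 1), pmin(gamma, 1), label = chain$label)
}
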