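# Canonical stage order for the breeding-state life cycle. All matrices and
# vectors in the package index stages in this order.
.stages <- c("PB", "S", "F", "NB")

# Resolve stage identifiers (names or 1-based indices) to integer indices.
stage_index <- function(stage, arg = "stage") {
  if (is.character(stage)) {
    idx <- match(stage, .stages)
    if (anyNA(idx)) {
      abort(sprintf(
        "`%s` must be one of %s (got %s).",
        arg, paste(.stages, collapse = ", "),
        paste(stage[is.na(idx)], collapse = ", ")
      ))
    }
    return(idx)
  }
  idx <- as.integer(stage)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(.stages))) {
    abort(sprintf("`%s` indices must lie in 1..%d.", arg, length(.stages)))
  }
  idx
}

check_probability <- function(x, name, n = NULL) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric with no missing values.", name))
  }
  if (!is.null(n) && length(x) != n) {
    abort(sprintf("`%s` must have length %d (one entry per stage).", name, n))
  }
  if (any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]; got %s.", name,
                  paste(signif(x[x < 0 | x > 1], 4), collapse = ", ")))
  }
  invisible(x)
}

# Linear solve of (I - U) X = B with an explicit conditioning check, so that a
# chain with no route to absorption fails loudly instead of returning garbage.
solve_survival_system <- function(U, B = NULL, label = NULL) {
  s <- nrow(U)
  A <- diag(s) - U
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-12) {
    who <- if (is.null(label)) "this chain" else sprintf("group '%s'", label)
    abort(sprintf(
      paste0("(I - U) is singular or near-singular for %s ",
             "(reciprocal condition number %.2e); the chain has no ",
             "practically reachable absorbing state, so occupancy times ",
             "are undefined."),
      who, rc
    ))
  }
  if (is.null(B)) B <- diag(s)
  solve(A, B)
}

# Matrix -> long tibble with explicit from/to stage labels.
matrix_tidy <- function(m, value_name = "value") {
  out <- tibble(
    to = rep(rownames(m) %||% as.character(seq_len(nrow(m))), ncol(m)),
    from = rep(colnames(m) %||% as.character(seq_len(ncol(m))),
               each = nrow(m)),
    value = as.vector(m)
  )
  names(out)[3] <- value_name
  out
}
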