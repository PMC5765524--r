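#' Plot a projected cohort
#'
#' Group shares among survivors over time (intra-cohort selection) with the
#' survivorship curve overlaid on a separate panel.
#'
#' @param object A `cohort_trajectory` from [project_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(project_cohort(southern_fulmar(), horizon = 50))
#' @export
autoplot.cohort_trajectory <- function(object, ...) {
  comp <- cohort_composition(object)
  shares <- dplyr::filter(comp, .data$unit == "group", .data$alive)
  ggplot2::ggplot(shares,
                  ggplot2::aes(x = .data$t, y = .data$share,
                               colour = .data$name)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "years since fledging", y = "share of survivors",
                  colour = "group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot survivorship of a projected cohort
#'
#' @param traj A `cohort_trajectory`.
#' @param log_scale Plot the y axis on log10 scale (default `TRUE`; the tail
#'   of a long-lived cohort is invisible otherwise).
#' @return A ggplot object.
#' @export
plot_survivorship <- function(traj, log_scale = TRUE) {
  comp <- dplyr::distinct(
    dplyr::filter(cohort_composition(traj), .data$unit == "group"),
    .data$t, .data$survivorship
  )
  p <- ggplot2::ggplot(comp, ggplot2::aes(x = .data$t,
                                          y = .data$survivorship)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "years since fledging",
                  y = "fraction of initial cohort alive") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot stage-occupancy proportions per group
#'
#' Stacked bars of the mean proportion of life spent in each stage, by
#' heterogeneity group.
#'
#' @param mixture A [mixture_model()].
#' @param start Starting stage or distribution, as in [stage_occupancy()];
#'   use `"adult"` for the recruitment-weighted adult-life start.
#' @return A ggplot object.
#' @examples
#' plot_occupancy(southern_fulmar())
#' @export
plot_occupancy <- function(mixture, start = "PB") {
  stopifnot(inherits(mixture, "mixture_model"))
  occ <- dplyr::bind_rows(lapply(mixture$chains, function(ch) {
    st <- if (identical(start, "adult")) recruitment_start(ch) else start
    stage_occupancy(ch, st)
  }))
  occ$stage <- factor(occ$stage, levels = .stages)
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$group, y = .data$proportion,
                                    fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of life", fill = "stage") +
    ggplot2::theme_minimal()
}

#' Plot a variance decomposition
#'
#' @param object A `variance_decomposition` from [decompose_variance()] or
#'   [decompose_outcome()].
#' @param ... Unused.
#' @return A ggplot object (stacked bar of within/between components).
#' @export
autoplot.variance_decomposition <- function(object, ...) {
  df <- tibble(
    component = factor(c("individual stochasticity (within)",
                         "heterogeneity (between)"),
                       levels = c("individual stochasticity (within)",
                                  "heterogeneity (between)")),
    variance = c(object$within, object$between),
    outcome = object$outcome
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$variance,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "variance", fill = NULL) +
    ggplot2::theme_minimal()
}
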