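#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an episode trace
#'
#' mRNA and protein time courses of one induction episode, one line per
#' gene, faceted by species.
#'
#' @param object An [simulate_episode()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot episode_trace
#' @export
autoplot.episode_trace <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("mrna_count", "protein_count"),
                        names_to = "species", values_to = "count") |>
    dplyr::mutate(
      species = dplyr::recode(.data$species,
                              mrna_count = "mRNA", protein_count = "protein"),
      gene = factor(.data$gene, levels = object$genes)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$count,
                                   colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time since PFR entry [s]", y = "copies per cell",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot compartment counts of a population trace
#'
#' @param object A [run_population()] result.
#' @param every Sampling interval of the plotted grid, seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot population_trace
#' @export
autoplot.population_trace <- function(object, every = 30, ...) {
  grid <- seq(0, object$duration, by = every)
  df <- compartment_counts(object, grid) |>
    tidyr::pivot_longer(c("n_str", "n_pfr"),
                        names_to = "compartment", values_to = "cells") |>
    dplyr::mutate(compartment = toupper(sub("n_", "", .data$compartment)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s / 60, .data$cells,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [min]", y = "tracked cells", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot population-level expression trajectories
#'
#' @param object A [population_trajectory()] result.
#' @param per_cell Plot per-capita levels (default) or population totals.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot population_expression
#' @export
autoplot.population_expression <- function(object, per_cell = TRUE, ...) {
  df <- tidyr::pivot_longer(
    object,
    if (per_cell) c("mrna_per_cell", "protein_per_cell")
    else c("mrna_total", "protein_total"),
    names_to = "species", values_to = "level"
  ) |>
    dplyr::mutate(species = ifelse(grepl("mrna", .data$species),
                                   "mRNA", "protein"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s / 3600, .data$level,
                                   colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time since PFR connection [h]",
                  y = if (per_cell) "copies per cell" else "population total",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a steady-state degradation sweep
#'
#' @param object A [steady_state_protein()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot steady_state_sweep
#' @export
autoplot.steady_state_sweep <- function(object, ...) {
  df <- object[object$k_deg_per_h > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$k_deg_per_h,
                                        .data$c_protein_ss,
                                        colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(k[deg]^Protein ~ "[" * h^-1 * "]"),
                  y = "steady-state protein [copies/cell]", colour = NULL) +
    ggplot2::theme_minimal()
  cross <- attr(object, "crossover")
  if (!is.null(cross)) {
    p <- p + ggplot2::geom_hline(
      data = cross,
      ggplot2::aes(yintercept = .data$protein_copies_per_cell,
                   colour = .data$gene),
      linetype = "dashed"
    )
  }
  p
}
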