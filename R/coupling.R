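#' Per-cell expression from flag superposition
#'
#' A cell's mRNA (protein) level at time `t` is the sum over its PFR-entry
#' flags of the single-cell episode look-up at the elapsed time
#' `t - t_flag`.  mRNA contributions vanish once the elapsed time exceeds
#' the episode length (the transcripts of that induction are fully
#' degraded); protein contributions persist at the episode's terminal value
#' because the single-cell model carries no protein decay.
#'
#' @param flags Numeric vector of the cell's PFR-entry times, seconds.
#' @param trace An [simulate_episode()] look-up table.
#' @param gene Gene name.
#' @param t Time at which to evaluate, seconds.
#' @return An integer count.
#' @examples
#' \donttest{
#' ep <- simulate_episode()
#' cell_mrna(c(100, 700), ep, "trpA", t = 800)
#' }
#' @export
cell_mrna <- function(flags, trace, gene, t) {
  stopifnot(inherits(trace, "episode_trace"))
  if (length(flags) == 0) return(0L)
  sum(episode_mrna_at(trace, t - flags, gene))
}

#' @rdname cell_mrna
#' @export
cell_protein <- function(flags, trace, gene, t) {
  stopifnot(inherits(trace, "episode_trace"))
  if (length(flags) == 0) return(0L)
  sum(episode_protein_at(trace, t - flags, gene))
}

#' Population-level expression time courses
#'
#' Superposes the single-cell episode over every live cell's flag list
#' (linearity: the population total is the exact sum of per-cell look-ups).
#' Washout removes a cell's entire contribution; division adds a
#' default daughter that contributes nothing until her own first PFR entry.
#'
#' @param pop A [run_population()] result.
#' @param trace An [simulate_episode()] look-up table built with the same
#'   simulation parameters.
#' @param grid Sample times in seconds.
#' @return An object of class `"population_expression"`: a tibble with
#'   columns `time_s`, `gene`, `mrna_total`, `protein_total`, `n_live`,
#'   `mrna_per_cell`, `protein_per_cell`.
#' @export
population_trajectory <- function(pop, trace, grid) {
  stopifnot(inherits(pop, "population_trace"), inherits(trace, "episode_trace"))
  grid <- sort(as.numeric(grid))
  fl <- pfr_flags(pop)
  removed <- ifelse(is.na(pop$cells$removed_at), Inf, pop$cells$removed_at)
  flag_removed <- removed[fl$cell_id]
  counts <- compartment_counts(pop, grid)
  genes <- trace$genes
  dt_len <- trace$episode_length
  term <- trace$final_protein

  rows <- purrr::map(seq_along(grid), function(i) {
    t <- grid[i]
    live <- fl$flag_time_s <= t & flag_removed > t
    e <- t - fl$flag_time_s[live]
    act <- e <= dt_len + 1e-9
    e_act <- e[act]
    n_past <- sum(!act)
    tibble::tibble(
      time_s = t,
      gene = genes,
      mrna_total = unname(vapply(genes, function(g)
        sum(episode_mrna_at(trace, e_act, g)), numeric(1))),
      protein_total = unname(vapply(genes, function(g)
        sum(episode_protein_at(trace, e_act, g)) + n_past * term[[g]],
        numeric(1))),
      n_live = counts$n_live[i]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$mrna_per_cell <- out$mrna_total / out$n_live
  out$protein_per_cell <- out$protein_total / out$n_live
  class(out) <- c("population_expression", class(out))
  out
}

#' Transcript profile along the PFR sampling ports
#'
#' In plug flow every cell at residence time `tau` into the PFR shares one
#' elapsed-time profile, so the transcript pattern at a sampling port is
#' the episode look-up at the port's residence time.
#'
#' @param trace An [simulate_episode()] look-up table.
#' @param ports Port residence times in seconds (defaults to the three
#'   sampling ports P1/P3/P5 at 31, 70 and 110 s).
#' @param tau_pfr Total PFR residence time, seconds; ports beyond it are
#'   rejected.
#' @return A tibble `port_s`, `gene`, `mrna_count`.
#' @examples
#' \donttest{
#' pfr_port_profile(simulate_episode())
#' }
#' @export
pfr_port_profile <- function(trace, ports = c(31, 70, 110), tau_pfr = 125) {
  stopifnot(inherits(trace, "episode_trace"))
  if (any(ports < 0 | ports > tau_pfr)) {
    stop("`ports` must lie within [0, tau_pfr] = [0, ", tau_pfr, "] s",
         call. = FALSE)
  }
  tidyr::crossing(port_s = ports, gene = trace$genes) |>
    dplyr::rowwise() |>
    dplyr::mutate(mrna_count = episode_mrna_at(trace, .data$port_s, .data$gene)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$port_s, match(.data$gene, trace$genes))
}

#' Induction-state census of the population
#'
#' A cell is currently induced if transcripts from at least one of its
#' PFR-entry flags are currently present, i.e. the flag's elapsed time
#' falls inside the episode's mRNA-positive support (`trace$mrna_span`):
#' before its lower edge transcription has not yet produced a countable
#' transcript (the observed induction delay), beyond its upper edge the
#' last mRNA of that induction has been degraded.  Cells with two or more
#' simultaneously transcript-bearing flags re-entered the PFR while still
#' induced ("multiple induction").
#'
#' @param pop A [run_population()] result.
#' @param trace An [simulate_episode()] look-up table.
#' @param times Census instants, seconds (vectorised).
#' @return A tibble `time_s`, `n_live`, `frac_not_induced`, `frac_once`,
#'   `frac_multiple` (fractions sum to 1).
#' @export
induction_census <- function(pop, trace, times) {
  stopifnot(inherits(pop, "population_trace"), inherits(trace, "episode_trace"))
  fl <- pfr_flags(pop)
  removed <- ifelse(is.na(pop$cells$removed_at), Inf, pop$cells$removed_at)
  flag_removed <- removed[fl$cell_id]
  counts <- compartment_counts(pop, times)
  span <- trace$mrna_span
  rows <- purrr::map(seq_along(times), function(i) {
    t <- times[i]
    e <- t - fl$flag_time_s
    act <- if (anyNA(span)) {
      rep(FALSE, nrow(fl))
    } else {
      e >= span[1] - 1e-9 & e <= span[2] + 1e-9 & flag_removed > t
    }
    per_cell <- tabulate(fl$cell_id[act])
    n_live <- counts$n_live[i]
    n_once <- sum(per_cell == 1L)
    n_multi <- sum(per_cell >= 2L)
    tibble::tibble(
      time_s = t,
      n_live = n_live,
      frac_not_induced = (n_live - n_once - n_multi) / n_live,
      frac_once = n_once / n_live,
      frac_multiple = n_multi / n_live
    )
  })
  dplyr::bind_rows(rows)
}

#' Time-averaged induction census
#'
#' Averages [induction_census()] over a regular grid of a post-burn-in
#' window, the long-run summary the census fractions are reported as.
#'
#' @inheritParams induction_census
#' @param from,to Averaging window in seconds; `from` should exceed about
#'   three episode lengths so that flag histories are fully populated.
#' @param every Grid spacing, seconds.
#' @return A one-row tibble `frac_not_induced`, `frac_once`,
#'   `frac_multiple`, `n_samples`.
#' @export
induction_census_average <- function(pop, trace, from, to = pop$duration,
                                     every = 30) {
  grid <- seq(from, to, by = every)
  cen <- induction_census(pop, trace, grid)
  tibble::tibble(
    frac_not_induced = mean(cen$frac_not_induced),
    frac_once = mean(cen$frac_once),
    frac_multiple = mean(cen$frac_multiple),
    n_samples = nrow(cen)
  )
}

#' Export a population expression trajectory / census as tidy TSV
#'
#' @param x A [population_trajectory()] or [induction_census()] result.
#' @param path Output file path.
#' @param normalize_by Optional reference gene; mRNA and protein totals are
#'   divided by that gene's mean total before writing (a plotting
#'   convention for comparing against intensity-scaled measurements).
#' @return Invisibly, `path`.
#' @export
export_trajectory <- function(x, path, normalize_by = NULL) {
  if (!is.null(normalize_by)) {
    stopifnot(normalize_by %in% x$gene)
    ref <- x[x$gene == normalize_by, ]
    m_ref <- mean(ref$mrna_total)
    p_ref <- mean(ref$protein_total)
    x <- dplyr::mutate(
      x,
      mrna_total = if (m_ref > 0) .data$mrna_total / m_ref else .data$mrna_total,
      protein_total = if (p_ref > 0) .data$protein_total / p_ref else .data$protein_total
    )
  }
  readr::write_tsv(x, path)
  invisible(path)
}
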