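#' Split the chemostat dilution rate into compartment growth rates
#'
#' In the STR-PFR loop the residence-time-weighted average growth rate must
#' equal the total-system dilution rate,
#' `(mu_str * tau_str + mu_pfr * tau_pfr) / (tau_str + tau_pfr) = D`.
#' Given the PFR growth rate (zero under complete starvation) this returns
#' the compensating STR growth rate.
#'
#' @param dilution_rate Total-system dilution rate D, per hour.
#' @param tau_str,tau_pfr Compartment residence times (any common unit).
#' @param mu_pfr Growth rate inside the PFR, per hour (default 0,
#'   starvation).
#' @return `mu_str` in per hour.
#' @examples
#' split_growth_rates(0.2, tau_str = 372, tau_pfr = 125) # 0.2672
#' @export
split_growth_rates <- function(dilution_rate, tau_str, tau_pfr, mu_pfr = 0) {
  if (tau_str <= 0) stop("`tau_str` must be positive", call. = FALSE)
  (dilution_rate * (tau_str + tau_pfr) - mu_pfr * tau_pfr) / tau_str
}

#' Translations-per-mRNA quota from turnover ratios
#'
#' The per-gene quota of ribosome initiations per transcript is the ratio
#' of protein turnover to mRNA turnover,
#' `(c_protein * k_deg_protein) / (c_mrna * k_deg_mrna)`, rounded to the
#' nearest integer.  With active protein degradation neglected the protein
#' degradation constant is the growth rate (dilution by division only).
#'
#' @param c_protein Protein level, copies per cell.
#' @param c_mrna mRNA level, copies per cell.
#' @param k_deg_protein Protein degradation constant, per hour.
#' @param k_deg_mrna mRNA degradation constant, per hour.
#' @return Integer quota (vectorised).
#' @examples
#' translations_per_mrna(1039.5, 1, k_deg_protein = 0.2, k_deg_mrna = 20.79)
#' @export
translations_per_mrna <- function(c_protein, c_mrna, k_deg_protein, k_deg_mrna) {
  stopifnot(all(c_protein >= 0))
  denom <- c_mrna * k_deg_mrna
  if (any(denom <= 0)) {
    stop("`c_mrna * k_deg_mrna` must be positive", call. = FALSE)
  }
  as.integer(round(c_protein * k_deg_protein / denom))
}

#' Convert a half-life to a first-order degradation constant
#'
#' @param t_half Half-life in minutes.
#' @return `k = ln(2) * 60 / t_half` in per hour.
#' @examples
#' k_from_halflife(2) # 20.79 per hour
#' @export
k_from_halflife <- function(t_half) {
  if (any(t_half <= 0)) stop("`t_half` must be positive (minutes)", call. = FALSE)
  log(2) * 60 / t_half
}

#' Per-gene translation rates realised by one episode
#'
#' Divides each gene's per-cycle protein yield by the episode (cycle)
#' length, the rate that feeds the steady-state protein analysis.
#'
#' @param trace An [simulate_episode()] result.
#' @return A tibble `gene`, `proteins_per_cycle`, `rate_per_min`,
#'   `rate_per_h`.
#' @export
episode_translation_rates <- function(trace) {
  stopifnot(inherits(trace, "episode_trace"))
  if (trace$episode_length <= 0) stop("episode produced no transcripts", call. = FALSE)
  tibble::tibble(
    gene = trace$genes,
    proteins_per_cycle = as.numeric(trace$final_protein),
    rate_per_min = .data$proteins_per_cycle / (trace$episode_length / 60),
    rate_per_h = .data$proteins_per_cycle / (trace$episode_length / 3600)
  )
}

#' Steady-state protein level versus the degradation constant
#'
#' At steady state translation balances first-order loss, so
#' `c_protein = r_translation / k_deg`.  The sweep evaluates this over a
#' grid of degradation constants; `k_deg = 0` has no analytic steady state
#' (loss is then pure growth dilution) and is reported as the optional
#' `plateau` taken from a long-run coupled simulation.  If per-gene
#' reference levels are supplied, the crossover degradation constant below
#' which the simulated steady state stays above the reference,
#' `k_cross = r_translation / c_reference`, is reported per gene.
#'
#' @param rates An [episode_translation_rates()] tibble (or any tibble with
#'   columns `gene` and `rate_per_h`, proteins per cell per hour).
#' @param k_deg_grid Degradation constants to sweep, per hour (positive).
#' @param reference Optional tibble `gene`, `protein_copies_per_cell` of
#'   reference steady-state levels.
#' @param plateau Optional named vector of `k_deg = 0` plateau levels from
#'   a coupled long-run simulation.
#' @return An object of class `"steady_state_sweep"`: a tibble `gene`,
#'   `k_deg_per_h`, `c_protein_ss`, with the crossover table (if computed)
#'   in `attr(, "crossover")` and plateau rows at `k_deg_per_h = 0` (if
#'   supplied).
#' @export
steady_state_protein <- function(rates, k_deg_grid, reference = NULL,
                                 plateau = NULL) {
  stopifnot(all(c("gene", "rate_per_h") %in% names(rates)))
  if (any(k_deg_grid < 0)) stop("`k_deg_grid` must be non-negative", call. = FALSE)
  grid_pos <- k_deg_grid[k_deg_grid > 0]
  out <- tidyr::crossing(
    rates[c("gene", "rate_per_h")],
    k_deg_per_h = grid_pos
  ) |>
    dplyr::mutate(c_protein_ss = .data$rate_per_h / .data$k_deg_per_h) |>
    dplyr::select("gene", "k_deg_per_h", "c_protein_ss")
  if (!is.null(plateau) && any(k_deg_grid == 0)) {
    out <- dplyr::bind_rows(
      tibble::tibble(gene = names(plateau), k_deg_per_h = 0,
                     c_protein_ss = as.numeric(plateau)),
      out
    )
  }
  if (!is.null(reference)) {
    stopifnot(all(c("gene", "protein_copies_per_cell") %in% names(reference)))
    cross <- dplyr::inner_join(rates[c("gene", "rate_per_h")], reference,
                               by = "gene")
    cross$k_cross_per_h <- cross$rate_per_h / cross$protein_copies_per_cell
    attr(out, "crossover") <- tibble::as_tibble(
      cross[c("gene", "protein_copies_per_cell", "k_cross_per_h")]
    )
  }
  class(out) <- c("steady_state_sweep", class(out))
  out
}

#' Read a reference protein-level table
#'
#' Tab-separated file with header columns `gene` and
#' `protein_copies_per_cell` (reference steady-state levels are an external
#' dataset and are not bundled).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_reference_levels <- function(path) {
  if (!file.exists(path)) stop("reference table not found: ", path, call. = FALSE)
  out <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene", "protein_copies_per_cell") %in% names(out)))
  out
}

#' Export a steady-state sweep as TSV
#'
#' Columns `k_deg_per_h`, `gene`, `c_protein_ss`.
#'
#' @param sweep A [steady_state_protein()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_sweep <- function(sweep, path) {
  readr::write_tsv(sweep[c("k_deg_per_h", "gene", "c_protein_ss")], path)
  invisible(path)
}
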