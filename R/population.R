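#' Event propensities of the cell-distribution model
#'
#' The three first-order events acting on the STR population: PFR entry
#' with propensity `n_str * q_pfr / v_str`, washout with propensity
#' `n_str * q_feed / v_str`, and division with the constant propensity
#' `n0 * D` (the reference cell count, not the current one -- this is what
#' makes the population self-stabilising around `n0 * D * v_str / q_feed`
#' STR cells).
#'
#' @param n_str Current number of cells in the STR.
#' @param reactor A [reactor_config()].
#' @return A tibble with columns `event`, `rate_per_s`, `rate_per_min`,
#'   `rate_per_h`.
#' @examples
#' event_rates(10000)
#' @export
event_rates <- function(n_str, reactor = reactor_config()) {
  stopifnot(inherits(reactor, "reactor_config"), n_str >= 0)
  per_s <- c(
    pfr_entry = n_str * reactor$q_pfr / 60 / reactor$v_str,
    washout = n_str * reactor$q_feed / 60 / reactor$v_str,
    division = reactor$n0 * reactor$dilution_rate / 3600
  )
  tibble::tibble(
    event = names(per_s),
    rate_per_s = unname(per_s),
    rate_per_min = unname(per_s) * 60,
    rate_per_h = unname(per_s) * 3600
  )
}

#' One Gillespie draw: waiting time and event choice
#'
#' Implements the direct-method draw used by the population engine: the
#' waiting time is `tau = ln(1/r1) / sum(rates)` and the event index is the
#' first `i` whose cumulative propensity exceeds `r2 * sum(rates)`.
#' Supplying `r1`/`r2` makes the draw deterministic (used for testing);
#' omitting them consumes R's RNG.
#'
#' @param rates Non-negative propensities, events per second.
#' @param r1,r2 Optional uniforms in (0, 1).
#' @return A list with `tau` (seconds) and `event` (index into `rates`).
#' @examples
#' gillespie_draw(c(1, 1), r1 = exp(-1), r2 = 0.9) # tau = 0.5, event 2
#' @export
gillespie_draw <- function(rates, r1 = stats::runif(1), r2 = stats::runif(1)) {
  stopifnot(all(rates >= 0), sum(rates) > 0, r1 > 0, r1 <= 1, r2 >= 0, r2 <= 1)
  total <- sum(rates)
  tau <- log(1 / r1) / total
  event <- findInterval(r2 * total, cumsum(rates), left.open = TRUE) + 1L
  event <- min(event, length(rates))
  list(tau = tau, event = event)
}

#' Simulate the STR-PFR cell population
#'
#' Gillespie simulation of the three-event cell-distribution model (PFR
#' entry, washout, division) with deterministic PFR return after
#' `reactor$tau_pfr` seconds.  All `n0` cells start uniformly in the STR.
#' Every PFR entry is logged as a time flag on the entering cell; the flag
#' lists anchor the superposition of the single-cell episode in
#' [population_trajectory()].
#'
#' @param reactor A [reactor_config()].
#' @param duration Simulated span in seconds.
#' @param seed Integer seed; identical seeds give identical event logs.
#' @return An object of class `"population_trace"`: tibbles `events`
#'   (`time_s`, `event`, `cell_id`) and `cells` (`cell_id`, `born_at`,
#'   `removed_at`, `location`, `pfr_exit_due`), plus `n0`, `duration`,
#'   `seed` and the `reactor` used.
#' @examples
#' pop <- run_population(reactor_config(n0 = 200), duration = 600, seed = 1)
#' glance(pop)
#' @export
run_population <- function(reactor = reactor_config(), duration, seed = 1L) {
  stopifnot(inherits(reactor, "reactor_config"), duration >= 0)
  set.seed(seed)
  raw <- .sim_population_cpp(
    n0 = reactor$n0,
    entry_coef = reactor$q_pfr / 60 / reactor$v_str,
    washout_coef = reactor$q_feed / 60 / reactor$v_str,
    division_rate = reactor$n0 * reactor$dilution_rate / 3600,
    tau_pfr = reactor$tau_pfr,
    duration = duration
  )
  kinds <- c("pfr_entry", "washout", "division", "pfr_return")
  events <- tibble::tibble(
    time_s = raw$ev_time,
    event = kinds[raw$ev_type],
    cell_id = raw$ev_cell
  )
  cells <- tibble::tibble(
    cell_id = seq_along(raw$born_at),
    born_at = raw$born_at,
    removed_at = ifelse(is.infinite(raw$removed_at), NA_real_, raw$removed_at),
    location = c("STR", "PFR", "removed")[raw$location + 1L],
    pfr_exit_due = raw$pfr_exit_due
  )
  structure(
    list(events = events, cells = cells, n0 = reactor$n0,
         duration = duration, seed = as.integer(seed), reactor = reactor),
    class = "population_trace"
  )
}

#' @export
print.population_trace <- function(x, ...) {
  cat("<population_trace>", x$n0, "initial cells,",
      nrow(x$events), "events over", x$duration, "s (seed", x$seed, ")\n")
  cat("  final:", sum(x$cells$location == "STR"), "STR,",
      sum(x$cells$location == "PFR"), "PFR,",
      sum(x$cells$location == "removed"), "washed out\n")
  invisible(x)
}

#' PFR-entry flags of every cell
#'
#' @param pop A [run_population()] result.
#' @return A tibble `cell_id`, `flag_time_s`, one row per PFR entry,
#'   ordered by time.
#' @export
pfr_flags <- function(pop) {
  stopifnot(inherits(pop, "population_trace"))
  ev <- pop$events[pop$events$event == "pfr_entry", ]
  tibble::tibble(cell_id = ev$cell_id, flag_time_s = ev$time_s)
}

#' Compartment counts over time
#'
#' Reconstructs `n_str` and `n_pfr` from the event log at arbitrary
#' instants (vectorised).
#'
#' @param pop A [run_population()] result.
#' @param times Query times in seconds, within `[0, duration]`.
#' @return A tibble `time_s`, `n_str`, `n_pfr`, `n_live`.
#' @export
compartment_counts <- function(pop, times) {
  stopifnot(inherits(pop, "population_trace"))
  if (any(times < 0 | times > pop$duration)) {
    stop("`times` must lie within the simulated span [0, ", pop$duration, "] s",
         call. = FALSE)
  }
  ev <- pop$events
  d_str <- c(pfr_entry = -1L, washout = -1L, division = 1L, pfr_return = 1L)
  d_pfr <- c(pfr_entry = 1L, washout = 0L, division = 0L, pfr_return = -1L)
  idx <- findInterval(times, ev$time_s)
  cum_str <- c(0L, unname(cumsum(d_str[ev$event])))
  cum_pfr <- c(0L, unname(cumsum(d_pfr[ev$event])))
  tibble::tibble(
    time_s = times,
    n_str = pop$n0 + cum_str[idx + 1L],
    n_pfr = cum_pfr[idx + 1L],
    n_live = pop$n0 + cum_str[idx + 1L] + cum_pfr[idx + 1L]
  )
}

#' Compartment census and volumetric reference
#'
#' Cell counts and fractions in the two compartments at given instants,
#' with the volumetric reference fractions `v_str / (v_str + v_pfr)` the
#' stationary census is expected to match.
#'
#' @inheritParams compartment_counts
#' @return A tibble `time_s`, `n_str`, `n_pfr`, `frac_str`, `frac_pfr`,
#'   `vol_frac_str`, `vol_frac_pfr`.
#' @export
compartment_census <- function(pop, times) {
  counts <- compartment_counts(pop, times)
  vol_str <- pop$reactor$v_str / (pop$reactor$v_str + pop$reactor$v_pfr)
  dplyr::mutate(
    counts[c("time_s", "n_str", "n_pfr")],
    frac_str = .data$n_str / (.data$n_str + .data$n_pfr),
    frac_pfr = .data$n_pfr / (.data$n_str + .data$n_pfr),
    vol_frac_str = vol_str,
    vol_frac_pfr = 1 - vol_str
  )
}

#' Export the population event log / flag list as TSV
#'
#' @param pop A [run_population()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_events <- function(pop, path) {
  readr::write_tsv(pop$events, path)
  invisible(path)
}

#' @rdname export_events
#' @export
export_flags <- function(pop, path) {
  readr::write_tsv(pfr_flags(pop), path)
  invisible(path)
}
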