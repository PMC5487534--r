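#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an episode trace
#'
#' @param x An [simulate_episode()] result.
#' @param ... Unused.
#' @return A tibble `time_s`, `gene`, `mrna_count`, `protein_count`.
#' @method tidy episode_trace
#' @export
tidy.episode_trace <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$times, times = length(x$genes)),
    gene = rep(x$genes, each = length(x$times)),
    mrna_count = as.integer(x$mrna),
    protein_count = as.integer(x$protein)
  )
}

#' @rdname tidy.episode_trace
#' @method glance episode_trace
#' @export
glance.episode_trace <- function(x, ...) {
  tibble::tibble(
    n_initiated = x$n_initiated,
    n_complete = x$n_complete,
    episode_length_s = x$episode_length,
    truncated = x$truncated,
    total_protein = sum(x$final_protein)
  )
}

#' Tidy a population trace
#'
#' @param x A [run_population()] result.
#' @param ... Unused.
#' @return The event log tibble `time_s`, `event`, `cell_id`.
#' @method tidy population_trace
#' @export
tidy.population_trace <- function(x, ...) x$events

#' @rdname tidy.population_trace
#' @method glance population_trace
#' @export
glance.population_trace <- function(x, ...) {
  ev <- table(factor(x$events$event,
                     levels = c("pfr_entry", "pfr_return", "washout", "division")))
  tibble::tibble(
    n0 = x$n0,
    duration_s = x$duration,
    seed = x$seed,
    n_events = nrow(x$events),
    n_pfr_entries = as.integer(ev[["pfr_entry"]]),
    n_washouts = as.integer(ev[["washout"]]),
    n_divisions = as.integer(ev[["division"]]),
    n_final_str = sum(x$cells$location == "STR"),
    n_final_pfr = sum(x$cells$location == "PFR")
  )
}
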