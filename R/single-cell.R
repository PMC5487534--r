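#' Simulate one starvation-induced expression episode
#'
#' Runs the deterministic single-cell lattice model for one PFR-triggered
#' induction episode: transcription initiation during the induction window,
#' coupled translation under the per-gene translations-per-mRNA quotas, and
#' 5'-to-3' gene-gated degradation, from PFR entry (t = 0) until the last
#' transcript nucleotide is degraded.  The resulting per-gene mRNA/protein
#' time series is the look-up table that the coupling layer superposes over
#' every cell's PFR-entry flags.
#'
#' The model contains no randomness: identical inputs give bit-identical
#' traces.
#'
#' @param params A [sim_params()].
#' @param operon An [operon_definition()].
#' @param horizon Maximum simulated time in seconds.  If the episode has
#'   not closed by then the trace is flagged `truncated` and a warning is
#'   emitted.
#' @param engine `"cpp"` (compiled production engine, default) or `"r"`
#'   (pure-R reference implementation; identical results, much slower).
#'
#' @return An object of class `"episode_trace"`: sampled `times` (s), a
#'   ticks-by-genes integer matrix each for `mrna` and `protein`, the gene
#'   names, `episode_length` (s, time until the last transcript nucleotide
#'   is degraded), `mrna_span` (first and last instant at which any
#'   per-gene transcript is counted -- the support used to classify a cell
#'   as currently induced), `n_initiated` / `n_complete` transcript counts,
#'   the `truncated` flag and the generating `params`/`operon`.
#' @examples
#' \donttest{
#' ep <- simulate_episode()
#' glance(ep)
#' }
#' @export
simulate_episode <- function(params = sim_params(),
                             operon = default_trp_operon(),
                             horizon = 1500,
                             engine = c("cpp", "r")) {
  stopifnot(inherits(params, "sim_params"), inherits(operon, "operon"))
  engine <- match.arg(engine)
  if (horizon <= params$t_ind[2]) {
    warning("`horizon` ends inside the induction window; the episode will be truncated")
  }
  raw <- if (engine == "cpp") {
    .sim_episode_cpp(
      op_length = operon$length,
      c_start = operon$genes$c_start,
      c_end = operon$genes$c_end,
      quota = as.integer(operon$genes$n_tl_max),
      velo_rnap = params$velo_rnap,
      velo_ribosome = params$velo_ribosome,
      velo_rnase = params$velo_rnase,
      delta_x = params$delta_x,
      delta_y = params$delta_y,
      delta_z = params$delta_z,
      t_start = params$t_ind[1],
      t_end = params$t_ind[2],
      dt = params$dt_step,
      horizon = horizon
    )
  } else {
    simulate_episode_r(params, operon, horizon)
  }
  if (raw$truncated) {
    warning("episode not finished within `horizon`; trace is truncated")
  }
  genes <- operon$genes$name
  colnames(raw$mrna) <- genes
  colnames(raw$protein) <- genes
  nz <- which(rowSums(raw$mrna) > 0)
  mrna_span <- if (length(nz) > 0) {
    c(raw$times[min(nz)], raw$times[max(nz)])
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(
      times = raw$times,
      mrna = raw$mrna,
      protein = raw$protein,
      genes = genes,
      episode_length = raw$episode_length,
      mrna_span = mrna_span,
      n_initiated = raw$n_initiated,
      n_complete = raw$n_complete,
      truncated = raw$truncated,
      final_protein = stats::setNames(raw$final_protein, genes),
      dt = params$dt_step,
      params = params,
      operon = operon
    ),
    class = "episode_trace"
  )
}

#' @export
print.episode_trace <- function(x, ...) {
  cat("<episode_trace>", x$n_initiated, "transcripts initiated,",
      x$n_complete, "completed\n")
  cat("  episode length:", round(x$episode_length, 1), "s",
      if (x$truncated) "(truncated)" else "", "\n")
  cat("  final proteins:",
      paste(x$genes, x$final_protein, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# nearest-grid-point lookup of the episode trace at elapsed times (s);
# counts are integers, so no fractional interpolation is used.
episode_index <- function(trace, elapsed) {
  idx <- as.integer(round(elapsed / trace$dt)) + 1L
  pmin(pmax(idx, 1L), length(trace$times))
}

#' Look up per-gene episode levels at an elapsed time
#'
#' @param trace An [simulate_episode()] result.
#' @param elapsed Seconds since the inducing PFR entry (vectorised).
#' @param gene Gene name.
#' @return Integer vector of counts, one per elapsed time.  mRNA is zero
#'   beyond the episode length; protein holds its terminal value.
#' @export
episode_mrna_at <- function(trace, elapsed, gene) {
  stopifnot(gene %in% trace$genes)
  out <- integer(length(elapsed))
  inside <- elapsed >= 0 & elapsed <= trace$episode_length + 1e-9
  out[inside] <- trace$mrna[episode_index(trace, elapsed[inside]), gene]
  out
}

#' @rdname episode_mrna_at
#' @export
episode_protein_at <- function(trace, elapsed, gene) {
  stopifnot(gene %in% trace$genes)
  out <- integer(length(elapsed))
  past <- elapsed > trace$episode_length + 1e-9
  inside <- elapsed >= 0 & !past
  out[inside] <- trace$protein[episode_index(trace, elapsed[inside]), gene]
  out[past] <- trace$final_protein[[gene]]
  out
}

#' Write an episode trace as tidy TSV
#'
#' Columns `time_s`, `gene`, `mrna_count`, `protein_count`.
#'
#' @param trace An [simulate_episode()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_episode <- function(trace, path) {
  readr::write_tsv(tidy(trace), path)
  invisible(path)
}
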