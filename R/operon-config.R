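#' Lattice simulation parameters
#'
#' Bundles the kinetic parameters of the single-cell lattice model: the
#' elongation rates of the three tracked species (RNA polymerase, ribosome,
#' RNase), their minimum head-to-tail spacings on the template, and the
#' induction window during which transcription initiation is permitted after
#' a cell enters the starvation (PFR) zone.
#'
#' Defaults are the literature-derived values used throughout the model:
#' all three species elongate at 21 nucleotides per second, all spacings are
#' 100 nucleotides, and initiation is allowed between 30 s (the observed
#' induction delay) and 125 s (the PFR residence time) after PFR entry.
#'
#' @param velo_rnap RNA polymerase elongation rate, nucleotides per second.
#' @param velo_ribosome Ribosome elongation rate, nucleotides per second.
#' @param velo_rnase RNase (degradosome) elongation rate, nucleotides per
#'   second.
#' @param delta_x Minimum spacing between consecutive RNAPs, nucleotides.
#' @param delta_y Minimum spacing between consecutive ribosomes (and the
#'   template lookahead a ribosome requires), nucleotides.
#' @param delta_z Minimum distance the RNase keeps behind the hindmost
#'   ribosome still on the strand, nucleotides.
#' @param t_ind Closed induction interval `c(start, end)` in seconds
#'   relative to PFR entry.
#' @param dt_step Lattice integration time step in seconds.  The default
#'   `NULL` resolves to `1 / velo_rnap`, i.e. one nucleotide hop per step,
#'   which makes all default motions exact integer hops.
#' @param rng_seed Integer seed recorded for runs that consume randomness
#'   (the lattice model itself is deterministic).
#'
#' @return A list of class `"sim_params"`.
#' @examples
#' sim_params()
#' sim_params(t_ind = c(30, 30)) # single-initiation window
#' @export
sim_params <- function(velo_rnap = 21,
                       velo_ribosome = 21,
                       velo_rnase = 21,
                       delta_x = 100,
                       delta_y = 100,
                       delta_z = 100,
                       t_ind = c(30, 125),
                       dt_step = NULL,
                       rng_seed = 1L) {
  p <- list(
    velo_rnap = as.numeric(velo_rnap),
    velo_ribosome = as.numeric(velo_ribosome),
    velo_rnase = as.numeric(velo_rnase),
    delta_x = as.numeric(delta_x),
    delta_y = as.numeric(delta_y),
    delta_z = as.numeric(delta_z),
    t_ind = as.numeric(t_ind),
    dt_step = if (is.null(dt_step)) 1 / as.numeric(velo_rnap) else as.numeric(dt_step),
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  for (f in c("velo_rnap", "velo_ribosome", "velo_rnase")) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      stop("`", f, "` must be a positive elongation rate (nt/s)", call. = FALSE)
    }
  }
  for (f in c("delta_x", "delta_y", "delta_z")) {
    if (!is.finite(p[[f]]) || p[[f]] < 1) {
      stop("`", f, "` must be a spacing of at least 1 nt", call. = FALSE)
    }
  }
  if (length(p$t_ind) != 2 || any(!is.finite(p$t_ind)) || p$t_ind[1] > p$t_ind[2]) {
    stop("`t_ind` must be c(start, end) with start <= end (seconds)", call. = FALSE)
  }
  if (p$t_ind[1] < 0) stop("`t_ind` start must be >= 0 s", call. = FALSE)
  if (!is.finite(p$dt_step) || p$dt_step <= 0) {
    stop("`dt_step` must be a positive time step (s)", call. = FALSE)
  }
  invisible(p)
}

#' Reactor configuration of the STR-PFR scale-down system
#'
#' Geometry and flow parameters of the stirred-tank (STR) / plug-flow (PFR)
#' loop.  Defaults reproduce the laboratory scale-down setup: 1120 mL STR,
#' 380 mL PFR, 180 mL/min circulation through the PFR, 5 mL/min feed and
#' harvest, total dilution rate 0.2 per hour and 10,000 tracked cells.
#'
#' The PFR residence time used by the population engine defaults to the
#' operational value of 125 s (the sampling ports and the induction window
#' are tied to it) rather than the recomputed `v_pfr / q_pfr` = 126.7 s;
#' [residence_times()] reports both.
#'
#' @param v_str STR liquid volume, mL.
#' @param v_pfr PFR liquid volume, mL.
#' @param q_pfr Biosuspension flow through the PFR, mL per minute.
#' @param q_feed Feed/harvest flow, mL per minute.
#' @param dilution_rate Total-system dilution rate D, per hour.
#' @param n0 Initial number of tracked cells in the STR.
#' @param tau_pfr PFR transit time used for scheduled returns, seconds.
#'
#' @return A list of class `"reactor_config"`.
#' @examples
#' reactor_config()
#' residence_times(reactor_config())
#' @export
reactor_config <- function(v_str = 1120,
                           v_pfr = 380,
                           q_pfr = 180,
                           q_feed = 5,
                           dilution_rate = 0.2,
                           n0 = 10000,
                           tau_pfr = 125) {
  r <- list(
    v_str = as.numeric(v_str),
    v_pfr = as.numeric(v_pfr),
    q_pfr = as.numeric(q_pfr),
    q_feed = as.numeric(q_feed),
    dilution_rate = as.numeric(dilution_rate),
    n0 = as.integer(n0),
    tau_pfr = as.numeric(tau_pfr)
  )
  validate_reactor_config(r)
  structure(r, class = "reactor_config")
}

validate_reactor_config <- function(r) {
  for (f in c("v_str", "v_pfr", "q_pfr", "q_feed", "dilution_rate", "tau_pfr")) {
    if (!is.finite(r[[f]]) || r[[f]] < 0) {
      stop("`", f, "` must be a non-negative number", call. = FALSE)
    }
  }
  if (r$v_str <= 0) stop("`v_str` must be positive (mL)", call. = FALSE)
  if (is.na(r$n0) || r$n0 < 1) stop("`n0` must be at least 1 cell", call. = FALSE)
  invisible(r)
}

#' Residence times of the two compartments
#'
#' Computes the hydraulic residence times `tau = V / q_pfr` of both
#' compartments from the configured volumes and circulation flow, alongside
#' the operational PFR transit time actually used for scheduled returns.
#'
#' @param reactor A [reactor_config()].
#' @return A tibble with columns `compartment`, `volume_ml`, `tau_s`
#'   (hydraulic) and `tau_used_s` (the value the simulator uses).
#' @export
residence_times <- function(reactor = reactor_config()) {
  stopifnot(inherits(reactor, "reactor_config"))
  q_s <- reactor$q_pfr / 60 # mL/s
  tibble::tibble(
    compartment = c("STR", "PFR"),
    volume_ml = c(reactor$v_str, reactor$v_pfr),
    tau_s = c(reactor$v_str / q_s, reactor$v_pfr / q_s),
    tau_used_s = c(reactor$v_str / q_s, reactor$tau_pfr)
  )
}

#' Operon annotation
#'
#' An operon is described by its total transcript length and an ordered set
#' of gene regions on the transcript coordinate system (1-based, closed
#' intervals, position 1 = first transcribed nucleotide; position 0 is the
#' reserved not-yet-initiated agent state).  Each gene carries its
#' translations-per-mRNA quota `n_tl_max`, the number of ribosome
#' initiations a transcript receives on that gene before the degradation
#' machinery may sweep through it.  A quota of 0 (the untranslated leader)
#' means the region is degradable without any translation gate.
#'
#' @param genes A data frame with columns `name`, `c_start`, `c_end`,
#'   `n_tl_max`; rows must be ordered 5' to 3' and non-overlapping.
#' @param length Total transcript length in nucleotides; defaults to the
#'   last gene's `c_end`.
#' @return A list of class `"operon"` with elements `genes` (tibble) and
#'   `length`.
#' @examples
#' operon_definition(
#'   data.frame(name = c("a", "b"), c_start = c(1, 61),
#'              c_end = c(60, 200), n_tl_max = c(2, 3))
#' )
#' @export
operon_definition <- function(genes, length = NULL) {
  genes <- tibble::as_tibble(genes)
  required <- c("name", "c_start", "c_end", "n_tl_max")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    stop("operon annotation lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  genes <- genes[required]
  genes$name <- as.character(genes$name)
  genes$c_start <- as.numeric(genes$c_start)
  genes$c_end <- as.numeric(genes$c_end)
  genes$n_tl_max <- as.integer(genes$n_tl_max)
  total <- if (is.null(length)) max(genes$c_end) else as.numeric(length)
  op <- structure(list(genes = genes, length = total), class = "operon")
  validate_operon(op)
  op
}

validate_operon <- function(op) {
  g <- op$genes
  if (nrow(g) == 0) stop("operon must contain at least one gene", call. = FALSE)
  if (any(g$c_start >= g$c_end)) {
    bad <- g$name[g$c_start >= g$c_end][1]
    stop("gene `", bad, "` has c_start >= c_end", call. = FALSE)
  }
  if (any(g$c_start < 1) || any(g$c_end > op$length)) {
    stop("gene regions must lie within [1, operon length]", call. = FALSE)
  }
  if (nrow(g) > 1) {
    if (any(diff(g$c_start) <= 0) || any(utils::head(g$c_end, -1) >= g$c_start[-1])) {
      stop("gene regions must be ordered 5'->3' and non-overlapping", call. = FALSE)
    }
  }
  if (any(is.na(g$n_tl_max)) || any(g$n_tl_max < 0)) {
    stop("`n_tl_max` must be a non-negative integer for every gene", call. = FALSE)
  }
  invisible(op)
}

#' @export
print.operon <- function(x, ...) {
  cat("<operon> length", x$length, "nt,", nrow(x$genes), "genes\n")
  print(x$genes, ...)
  invisible(x)
}

#' Default trp operon annotation
#'
#' The packaged annotation of the *E. coli* trp operon transcript: 6726 nt
#' total, leader region `trpL` followed by the structural genes `trpE`,
#' `trpD`, `trpC`, `trpB`, `trpA` with translations-per-mRNA quotas
#' 0/4/4/5/10/10 (the `trpA` quota is extrapolated from `trpB` because the
#' two form a 2:2 complex; the leader peptide is excluded from protein
#' accounting).  Only the total length and gene order are constrained by the
#' modelled system; the per-gene boundaries are a synthetic reconstruction
#' from K-12 MG1655 gene lengths, shifted so the operon ends at 6726 nt, and
#' can be replaced by supplying your own annotation file to
#' [read_operon()].
#'
#' @return An [operon_definition()] object.
#' @examples
#' default_trp_operon()
#' @export
default_trp_operon <- function() {
  path <- system.file("extdata", "trp_operon.tsv", package = "strpfr")
  read_operon(path)
}

#' Read / write an operon annotation file
#'
#' The annotation format is a tab-separated file with a header line and
#' columns `name`, `c_start`, `c_end`, `n_tl_max`.
#'
#' @param path File path.
#' @param length Optional total transcript length; defaults to the last
#'   gene's `c_end`.
#' @return [read_operon()] returns an [operon_definition()];
#'   [write_operon()] invisibly returns `path`.
#' @export
read_operon <- function(path, length = NULL) {
  if (!file.exists(path)) stop("operon annotation file not found: ", path, call. = FALSE)
  genes <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  operon_definition(genes, length = length)
}

#' @param operon An [operon_definition()].
#' @rdname read_operon
#' @export
write_operon <- function(operon, path) {
  stopifnot(inherits(operon, "operon"))
  utils::write.table(operon$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load or write a full model configuration
#'
#' Configurations are flat YAML files with up to three sections:
#' `simulation` (fields of [sim_params()]), `reactor` (fields of
#' [reactor_config()]) and `operon` (either `annotation: <path>` pointing at
#' a tab-separated annotation, optionally with `length`, or an inline
#' `genes:` list).  Every omitted field takes its packaged default, so an
#' empty file yields the full default model.
#'
#' @param path File path of the YAML configuration.
#' @return A list of class `"strpfr_config"` with elements `simulation`,
#'   `reactor`, `operon`.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines("reactor:\n  dilution_rate: 0.1", cfg_file)
#' cfg <- load_config(cfg_file)
#' cfg$reactor$dilution_rate
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("simulation", "reactor", "operon")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sim <- build_from_fields(sim_params, raw$simulation, "simulation")
  reac <- build_from_fields(reactor_config, raw$reactor, "reactor")
  op <- raw$operon
  operon <-
    if (is.null(op)) {
      default_trp_operon()
    } else if (!is.null(op$annotation)) {
      anno <- op$annotation
      if (!file.exists(anno)) {
        anno2 <- file.path(dirname(path), anno)
        if (file.exists(anno2)) anno <- anno2
      }
      read_operon(anno, length = op$length)
    } else if (!is.null(op$genes)) {
      genes <- dplyr::bind_rows(lapply(op$genes, tibble::as_tibble))
      operon_definition(genes, length = op$length)
    } else {
      default_trp_operon()
    }
  structure(list(simulation = sim, reactor = reac, operon = operon),
            class = "strpfr_config")
}

build_from_fields <- function(constructor, fields, section) {
  if (is.null(fields)) return(constructor())
  formal_names <- names(formals(constructor))
  unknown <- setdiff(names(fields), formal_names)
  if (length(unknown) > 0) {
    stop("unknown field(s) in [", section, "]: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(fields$t_ind)) fields$t_ind <- as.numeric(unlist(fields$t_ind))
  do.call(constructor, fields)
}

#' @param config A `"strpfr_config"` list as returned by [load_config()] or
#'   [default_config()].
#' @rdname load_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "strpfr_config"))
  out <- list(
    simulation = unclass(config$simulation),
    reactor = unclass(config$reactor),
    operon = list(
      length = config$operon$length,
      genes = lapply(seq_len(nrow(config$operon$genes)), function(i) {
        as.list(config$operon$genes[i, ])
      })
    )
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Default configuration triple
#'
#' @return A `"strpfr_config"` list with default [sim_params()],
#'   [reactor_config()] and [default_trp_operon()].
#' @export
default_config <- function() {
  structure(
    list(simulation = sim_params(), reactor = reactor_config(),
         operon = default_trp_operon()),
    class = "strpfr_config"
  )
}
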