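#' Create an empty lattice state
#'
#' The lattice state holds every agent of the single-cell model at one
#' instant: RNAP positions on the DNA, ribosome positions and per-gene
#' translation counters on each nascent transcript, and one RNase position
#' per transcript.  These pure-R operations implement the model one tick at
#' a time and serve as the readable reference for the compiled episode
#' engine (the two are asserted identical in the test suite).
#'
#' @param params A [sim_params()].
#' @param operon An [operon_definition()].
#' @return A list of class `"lattice_state"`: simulation clock `t`, tick
#'   counter, a list of strands, cumulative per-gene `protein` counts and
#'   bookkeeping counters.
#' @export
new_lattice_state <- function(params = sim_params(), operon = default_trp_operon()) {
  stopifnot(inherits(params, "sim_params"), inherits(operon, "operon"))
  structure(
    list(
      t = 0, tick = 0L,
      strands = list(),
      protein = stats::setNames(integer(nrow(operon$genes)), operon$genes$name),
      n_initiated = 0L, n_complete = 0L,
      last_degraded_at = 0,
      params = params, operon = operon
    ),
    class = "lattice_state"
  )
}

new_strand <- function(operon) {
  ng <- nrow(operon$genes)
  list(
    x = 0, complete = FALSE,
    y = numeric(0), gene = integer(0),
    init_cnt = integer(ng), comp_cnt = integer(ng),
    z = 0, degraded = FALSE
  )
}

strand_len <- function(s, operon) if (s$complete) operon$length else s$x

#' Attempt one transcription initiation
#'
#' A new RNAP is appended at the reserved position 0 if and only if the
#' clock lies inside the induction window and the trailing-most RNAP still
#' on the DNA has cleared the minimum spacing `delta_x` (a detached RNAP
#' imposes no constraint).  The first elongation step -- the initiation
#' step proper -- is taken on the following tick, so successive
#' initiations on an unblocked track are spaced exactly
#' `delta_x / velo_rnap` seconds apart.  Once appended, the RNAP is
#' committed: it elongates to the terminator even after the induction
#' window closes.
#'
#' @param state A [new_lattice_state()].
#' @param t Time used for the induction-window test; defaults to the state
#'   clock.
#' @return The updated state.
#' @export
try_initiate_rnap <- function(state, t = state$t) {
  p <- state$params
  op <- state$operon
  if (t < p$t_ind[1] - 1e-9 || t > p$t_ind[2] + 1e-9) return(state)
  n <- length(state$strands)
  if (n > 0) {
    tail <- state$strands[[n]]
    if (!tail$complete && tail$x < p$delta_x - 1e-9) return(state)
  }
  state$strands[[n + 1L]] <- new_strand(op)
  state$n_initiated <- state$n_initiated + 1L
  state
}

#' Advance all RNA polymerases by one step
#'
#' Each RNAP still on the DNA advances `velo_rnap * dt` nucleotides unless
#' its leader (the nearest active RNAP downstream) is closer than
#' `delta_x`.  An RNAP reaching the transcript end terminates and detaches;
#' the strand is then complete and its length is frozen at the operon
#' length.  Leaders move before followers, so spacing is evaluated against
#' current-tick leader positions.
#'
#' @inheritParams try_initiate_rnap
#' @param dt Time step in seconds; defaults to `params$dt_step`.
#' @return The updated state.
#' @export
step_rnaps <- function(state, dt = state$params$dt_step) {
  p <- state$params
  op <- state$operon
  step <- p$velo_rnap * dt
  have_prev <- FALSE
  prev_x <- 0
  for (i in seq_along(state$strands)) {
    s <- state$strands[[i]]
    if (s$complete) {
      have_prev <- FALSE
      next
    }
    if (!have_prev || prev_x - s$x >= p$delta_x - 1e-9) {
      s$x <- s$x + step
      if (s$x >= op$length - 1e-9) {
        s$x <- op$length
        s$complete <- TRUE
        state$n_complete <- state$n_complete + 1L
      }
    }
    if (s$complete) {
      have_prev <- FALSE
    } else {
      have_prev <- TRUE
      prev_x <- s$x
    }
    state$strands[[i]] <- s
  }
  state
}

#' Advance all ribosomes by one step and initiate new ones
#'
#' Per strand, leader first: a ribosome advances `velo_ribosome * dt`
#' nucleotides unless (i) the strand is still being transcribed and fewer
#' than `delta_y` nucleotides of template lie ahead, or (ii) its leading
#' ribosome is closer than `delta_y`.  A ribosome passing the last
#' nucleotide of its gene detaches and increments that gene's protein
#' count.  Afterwards at most one ribosome per gene initiates at the gene
#' start if at least `delta_y` nucleotides downstream are synthesized, the
#' nearest downstream ribosome has cleared `delta_y`, and the gene's
#' translations-per-mRNA quota is not yet exhausted.
#'
#' @inheritParams step_rnaps
#' @return The updated state.
#' @export
step_ribosomes <- function(state, dt = state$params$dt_step) {
  p <- state$params
  op <- state$operon
  step <- p$velo_ribosome * dt
  g_start <- op$genes$c_start
  g_end <- op$genes$c_end
  quota <- op$genes$n_tl_max
  for (i in seq_along(state$strands)) {
    s <- state$strands[[i]]
    if (s$degraded) next
    L <- strand_len(s, op)
    if (length(s$y) > 0) {
      keep_y <- numeric(0)
      keep_g <- integer(0)
      have_lead <- FALSE
      lead_y <- 0
      for (j in seq_along(s$y)) {
        yj <- s$y[j]
        gj <- s$gene[j]
        template_halt <- !s$complete && (L - yj <= p$delta_y + 1e-9)
        lead_halt <- have_lead && (lead_y - yj < p$delta_y - 1e-9)
        if (!template_halt && !lead_halt) yj <- yj + step
        if (yj > g_end[gj] + 1e-9) {
          s$comp_cnt[gj] <- s$comp_cnt[gj] + 1L
          state$protein[gj] <- state$protein[gj] + 1L
        } else {
          keep_y <- c(keep_y, yj)
          keep_g <- c(keep_g, gj)
          have_lead <- TRUE
          lead_y <- yj
        }
      }
      s$y <- keep_y
      s$gene <- keep_g
    }
    for (g in seq_along(quota)) {
      if (s$init_cnt[g] >= quota[g]) next
      if (!(s$complete || L - g_start[g] >= p$delta_y - 1e-9)) next
      down <- which(s$y >= g_start[g] - 1e-9)
      if (length(down) > 0) {
        y_near <- s$y[max(down)] # descending order: last is nearest
        if (y_near - g_start[g] < p$delta_y - 1e-9) next
        ins <- max(down)
      } else {
        ins <- 0L
      }
      s$y <- append(s$y, g_start[g], after = ins)
      s$gene <- append(s$gene, g, after = ins)
      s$init_cnt[g] <- s$init_cnt[g] + 1L
    }
    state$strands[[i]] <- s
  }
  state
}

#' Advance all RNases by one step
#'
#' One RNase per strand starts at the 5' end at strand birth and sweeps 3'
#' at `velo_rnase * dt` nucleotides per step.  It halts while the hindmost
#' ribosome still on the strand is within `delta_z`, may not advance into a
#' gene until that gene has received its full quota of translation
#' initiations, and never passes the synthesized front of the transcript.
#' Once the RNase reaches the transcript end the strand is fully degraded
#' and retires.
#'
#' @inheritParams step_rnaps
#' @return The updated state.
#' @export
step_rnases <- function(state, dt = state$params$dt_step) {
  p <- state$params
  op <- state$operon
  step <- p$velo_rnase * dt
  g_start <- op$genes$c_start
  quota <- op$genes$n_tl_max
  for (i in seq_along(state$strands)) {
    s <- state$strands[[i]]
    if (s$degraded) next
    L <- strand_len(s, op)
    if (length(s$y) > 0 && s$y[length(s$y)] - s$z <= p$delta_z + 1e-9) next
    cap <- L
    open <- which(s$init_cnt < quota)
    if (length(open) > 0) cap <- min(cap, g_start[min(open)] - 1)
    zn <- min(s$z + step, cap)
    if (zn > s$z) s$z <- zn
    if (s$complete && s$z >= op$length - 1e-9) {
      s$z <- op$length
      s$degraded <- TRUE
      state$last_degraded_at <- state$t
    }
    state$strands[[i]] <- s
  }
  state
}

#' Per-gene mRNA and protein counts of a lattice state
#'
#' The per-gene mRNA level is the difference between synthesized and
#' degraded copies: a strand counts toward gene `g` while transcription
#' has reached the gene's first nucleotide and the RNase has not yet
#' passed it (so a partially transcribed strand already counts for the
#' genes it has entered, and the quota-0 leader is degraded essentially as
#' fast as it is made).  Protein counts are the cumulative completed
#' translations.
#'
#' @inheritParams try_initiate_rnap
#' @return A tibble with columns `gene`, `mrna`, `protein`.
#' @export
count_levels <- function(state) {
  op <- state$operon
  g_start <- op$genes$c_start
  mrna <- integer(nrow(op$genes))
  for (s in state$strands) {
    L <- strand_len(s, op)
    syn <- (L >= g_start - 1e-9)
    deg <- (s$z >= g_start - 1e-9)
    mrna <- mrna + pmax(0L, as.integer(syn) - as.integer(deg))
  }
  tibble::tibble(gene = op$genes$name, mrna = mrna,
                 protein = as.integer(state$protein))
}

#' Advance the lattice by one full tick
#'
#' Applies, in order, RNAP movement, ribosome movement and initiation,
#' RNase movement and finally transcription initiation, then advances the
#' clock by `dt_step`.  Downstream species move first so that spacing rules
#' are evaluated against current-tick leader positions and no same-tick
#' collision can occur.
#'
#' @inheritParams try_initiate_rnap
#' @return The updated state.
#' @export
lattice_tick <- function(state) {
  state$tick <- state$tick + 1L
  state$t <- state$tick * state$params$dt_step
  state <- step_rnaps(state)
  state <- step_ribosomes(state)
  state <- step_rnases(state)
  try_initiate_rnap(state)
}

all_degraded <- function(state) {
  all(vapply(state$strands, function(s) s$degraded, logical(1)))
}

# Pure-R episode driver; reference implementation for the compiled engine.
simulate_episode_r <- function(params, operon, horizon) {
  state <- new_lattice_state(params, operon)
  state <- try_initiate_rnap(state, t = 0) # closed window may open at 0
  ng <- nrow(operon$genes)
  k_max <- floor(horizon / params$dt_step + 1e-9)
  times <- numeric(k_max + 1)
  mrna <- matrix(0L, nrow = k_max + 1, ncol = ng)
  protein <- matrix(0L, nrow = k_max + 1, ncol = ng)
  n_rec <- 1L
  truncated <- FALSE
  repeat {
    if (state$tick >= k_max) {
      truncated <- !(state$t > params$t_ind[2] + 1e-9 && all_degraded(state))
      break
    }
    state <- lattice_tick(state)
    lv <- count_levels(state)
    n_rec <- n_rec + 1L
    times[n_rec] <- state$t
    mrna[n_rec, ] <- lv$mrna
    protein[n_rec, ] <- lv$protein
    if (state$t > params$t_ind[2] + 1e-9 && all_degraded(state)) break
  }
  list(
    times = times[seq_len(n_rec)],
    mrna = mrna[seq_len(n_rec), , drop = FALSE],
    protein = protein[seq_len(n_rec), , drop = FALSE],
    episode_length = state$last_degraded_at,
    n_initiated = state$n_initiated,
    n_complete = state$n_complete,
    truncated = truncated,
    final_protein = as.integer(state$protein)
  )
}
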