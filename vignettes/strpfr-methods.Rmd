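---
title: "The strpfr model: single-cell operon dynamics in a scale-down reactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The strpfr model: single-cell operon dynamics in a scale-down reactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpfr)
```

## The system being modelled

Industrial bioreactors mix poorly: a cell circulating through a 100 m³
tank repeatedly crosses zones where the limiting nutrient has run out.
The laboratory scale-down analogue couples a nitrogen-limited chemostat
(a stirred tank reactor, STR, 1120 mL) to a plug-flow loop (PFR, 380 mL)
through which biosuspension is pumped at 180 mL/min.  No feed enters the
loop, so every passage is a ~125 s starvation pulse.  Each pulse
transiently induces starvation-responsive transcription; the tryptophan
operon (`trpL` leader + `trpEDCBA`, one 6726 nt polycistronic mRNA) is
the tracked example because attenuation control couples its transcription
to translation: detecting `trpE` transcripts implies ribosomes were
running.

`strpfr` implements the resulting hybrid model in three layers:

1. **Single-cell lattice model** (`simulate_episode()`): a deterministic
   agent model of one induction episode -- RNA polymerases, ribosomes and
   RNases hopping along a 1D nucleotide lattice.
2. **Cell-distribution model** (`run_population()`): a Gillespie
   simulation of every tracked cell's traffic between STR and PFR, with
   washout and division.
3. **Coupling** (`population_trajectory()`, `induction_census()`): the
   episode is computed once, stored as a look-up table, and superposed
   over every cell's logged PFR-entry times ("flags").

## Single-cell lattice model

The transcript coordinate system is 1-based and closed; position 0 is the
reserved pre-initiation state.  Three species move at fixed elongation
rates (all 21 nt/s by default) subject to minimum spacings (all 100 nt):

* **RNAP**: a new polymerase is appended at position 0 whenever the clock
  is inside the induction window `t_ind = [30, 125]` s after PFR entry
  (30 s is the experimentally observed induction delay; 125 s the PFR
  transit time) and the trailing polymerase has cleared `delta_x`.  Once
  appended it is committed: attenuation is reduced to its starvation-side
  outcome, so elongation continues to the terminator at 6726 nt even
  after the window closes.  The nascent strand length equals the RNAP
  position.
* **Ribosomes**: initiation at a gene's first coding nucleotide requires
  `delta_y` nucleotides of synthesized template ahead, a clear `delta_y`
  gap to the nearest downstream ribosome, and an unexhausted
  translations-per-mRNA quota for that gene.  Movement halts when the
  template lookahead or the gap to the leading ribosome falls below
  `delta_y`; a ribosome passing the gene's last nucleotide detaches and
  counts one protein.  The per-gene quotas (trpE 4, trpD 4, trpC 5,
  trpB 10, trpA 10; trpA extrapolated from trpB because the synthase is
  an alpha2-beta2 complex) are protein/mRNA turnover ratios, computable
  with `translations_per_mrna()`.
* **RNase**: one degradosome per strand starts at the 5' end immediately
  at strand birth, may not advance into a gene until that gene has
  received its full quota of translation *initiations*, and trails the
  hindmost ribosome still on the strand by at least `delta_z`.  A strand
  retires when the RNase reaches the transcript end.

The per-gene mRNA level is "synthesized minus degraded": a strand counts
toward gene *g* while transcription has reached the gene's first
nucleotide and the RNase has not yet passed it.  Two consequences are
worth spelling out, because the counting convention was a genuinely open
design choice:

* Partially transcribed strands already count for the genes they have
  entered.  This is what makes `trpE` transcripts visible at the PFR
  sampling ports (31/70/110 s) while `trpDCBA` remain absent -- the
  behaviour the microarray comparison hinges on.  Counting only fully
  transcribed genes would render every pulse invisible, because under the
  initiation-gated degradation rule the RNase enters a gene region
  roughly `quota * delta_y / velo` seconds after initiation starts there,
  which is well before a long gene finishes transcribing.
* The quota-0 leader `trpL` is degraded essentially as fast as it is
  made: the RNase crosses it unhindered, so its count hovers at zero --
  consistent with the leader being barely detectable in the PFR.

Two episode-length notions coexist and both are stored on the trace:
`episode_length` is the instant the last transcript *nucleotide* is
degraded (~493 s with defaults), while `mrna_span` is the support on
which any per-gene transcript count is positive (~38-455 s).  The
superposition formulas are numerically identical under either (the
look-up is zero in between); the induction census uses `mrna_span`
because "currently induced" means "transcripts from that passage
currently present".

### Numerical scheme

The equations of motion are simple switched ODEs, but every observable is
an integer count, so the engine uses a fixed time step
`dt_step = 1/velo_rnap` (~0.0476 s): each unblocked agent hops exactly
one nucleotide per tick and no floating-point drift can accumulate
(comparisons still carry a 1e-9 guard).  Within a tick the update order
is downstream-first -- RNAPs, then ribosomes (movement before
initiation), then RNases, then transcription initiation -- so spacing
rules are evaluated against current-tick leader positions and same-tick
collisions are impossible.  The template-lookahead halt applies only
while a strand is still being transcribed; a completed strand imposes
none (otherwise every ribosome would deadlock 100 nt before the 3' end).
Degenerate inputs behave sensibly: a zero-width window yields exactly one
transcript whose proteins equal the quotas; an all-quota-zero operon is
transcribed and degraded without translation; a closed interval that
includes t = 0 initiates at t = 0.

With these rules the strand count of an unblocked track obeys the closed
form `1 + floor((t_end - t_start) * velo / delta_x)` exactly, and every
initiated strand eventually delivers its full quota, so final protein
counts are `n_strands * quota` -- both are asserted as properties in the
test suite against the lattice simulation.  The engine is compiled
(Rcpp); a pure-R implementation of each step rule
(`step_rnaps()`, `step_ribosomes()`, `step_rnases()`,
`try_initiate_rnap()`, `count_levels()`) doubles as readable
specification and independent reference, and the suite asserts the two
engines produce bit-identical traces.

## Cell-distribution model

Three first-order events act on the STR population of tracked cells
(volumes in mL, flows in mL/min, D in 1/h; everything is converted to
seconds internally):

| event | propensity | effect |
|---|---|---|
| PFR entry | `n_str * q_pfr / v_str` | uniformly chosen STR cell enters the loop; its entry time is logged as a flag |
| washout | `n_str * q_feed / v_str` | uniformly chosen STR cell leaves the system |
| division | `n0 * D` (constant) | a default daughter cell (no flags, no expression programme) joins the STR |

The division propensity deliberately uses the constant reference count
`n0`, not the current population: washout then balances division at
`n_str* = n0 * D * v_str / q_feed` (7467 cells with defaults) and the
population self-stabilises.  PFR transit is not stochastic: a cell
re-enters the STR exactly `tau_pfr = 125 s` after entry.  The engine
interleaves these scheduled returns with the Gillespie draws and redraws
the exponential waiting time after each executed return, which is exact
because the exponential clock is memoryless.  `tau_pfr` binds to the
operational 125 s (to which the sampling ports and the induction window
are calibrated) rather than the recomputed 380/3 = 126.7 s;
`residence_times()` reports both.

The stationary compartment split follows from a Little's-law balance:
`n_pfr / n_str = (q_pfr / v_str) * tau_pfr = 0.335`, i.e. 74.9 % of
tracked cells in the STR -- matching the volumetric split 1120/1500 =
74.7 vol%.  Both are asserted (the former across ten seeds, within three
standard errors).

All randomness flows through R's RNG: `run_population(seed = )` seeds it,
the compiled loop consumes it, and identical seeds give identical event
logs.  The single-cell model is RNG-free.

## Coupling

Cells are assumed to travel through a "frozen" bioreactor background:
they do not alter their environment, so one episode look-up table serves
the entire population.  A cell's expression level at time *t* is the sum
over its flags of the look-up at the elapsed time; mRNA contributions
vanish beyond the episode, protein contributions persist at the episode's
terminal value (the single-cell model has no protein decay).  Washout
deletes a cell's contribution; division adds a contribution-free
daughter.  Look-ups use nearest-grid-point indexing on the `dt_step` grid
-- counts are integers, fractional interpolation would be meaningless.

Per-capita protein dilution therefore *emerges* from daughter influx and
washout rather than being imposed: the population turns over at rate `D`,
so neglected protein degradation is exactly replaced by growth dilution
with `k_deg = D`.  The long-run per-capita plateau consequently matches
the steady-state balance `c = r_translation / k_deg` evaluated at
`k_deg = D`, which the acceptance suite checks within 5 %.  The same
balance, swept over a grid of degradation constants with
`steady_state_protein()`, reproduces the protein-level-versus-`k_deg`
analysis; supplying external reference levels yields the crossover
constant `k_cross = r_translation / c_reference` per gene (the reference
proteome table is an external dataset and is deliberately not bundled).

Two population time scales separate by two orders of magnitude: per-capita
mRNA settles once flag histories cover one episode (~8 min), while
per-capita protein approaches its plateau at rate `D` (95 % at
`3/D` = 15 h).  The census classifies each live cell by the number of
flags whose elapsed time lies inside `mrna_span`: none (not induced),
one, or two and more ("multiple induction": the cell re-entered the PFR
while transcripts from a previous passage were still present).

## What the generator emulates -- and what it does not

The population simulator plus the packaged operon annotation *are* the
study conditions: 10,000 initial cells, the Table of defaults above, and
a 2 h span with a 30 min burn-in for stationary summaries.  Features of
real scale-down data deliberately outside the model: residence-time
distribution inside the PFR (plug flow is ideal; sampling-port profiles
are single look-ups), metabolic feedback of cells on their environment,
single-cell stochasticity in initiation and elongation (the lattice model
is deterministic by design), thermodynamics of the attenuator hairpin,
and microarray intensity scaling (only an optional normalise-by-reference
-gene export flag).  Passing tests therefore demonstrate internal
consistency with the model's mechanism, not agreement with any particular
transcriptome dataset.

The per-gene boundaries of the default annotation are a synthetic
reconstruction: the modelled system fixes only the total length (6726 nt)
and the gene order, so the package derives boundaries from K-12 MG1655
gene lengths (trpE 1563, trpD 1596, trpC 1359, trpB 1194, trpA 807 nt;
leader region 1-162; one 45 nt trpC-trpB spacer), shifted so `trpA` ends
at 6726.  Boundary shifts of this size move protein appearance times by
seconds and leave all integer yields unchanged; users can supply their
own annotation file (`read_operon()`).

## Problem sizes

The deterministic episode runs in well under a second.  Stationary
population summaries use the full 10,000 cells over 2 simulated hours
(about 300,000 events).  The transcript-versus-protein adaptation
analysis runs 2,000 cells over 24 simulated hours -- per-capita fractions
and percentages are invariant to the tracked-cell count (both compartment
counts scale with `n_str`), so the smaller ensemble changes only the
noise floor, and 24 h comfortably brackets the 15 h protein settling
time.  Ten-seed replication is used wherever a stochastic ratio is
asserted against a closed form.

## Known limitations

* The census percentages depend mildly on the operational definition of
  "currently induced"; the package defines it as transcript presence
  (`mrna_span`), which is the only reading consistent with all the
  model's own outputs, and documents the alternative (flag age below
  `episode_length`) as giving a few points more "multiple" and fewer
  "not induced".
* Event selection among STR cells is uniform; there is no cell-age or
  position bias, and the PFR has no internal structure.
* The deterministic 125 s return makes the PFR a pure delay line; do not
  use `compartment_census()` port-style readouts for loops with
  significant dispersion.
* With non-default velocity ratios (`velo_ribosome != velo_rnap`) hops
  are no longer integer multiples of the grid; the engine remains correct
  but the closed-form strand count and the quota identity are only exact
  when the initiation cadence divides the tick grid.
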