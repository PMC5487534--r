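# strpfr

Hybrid single-cell / population simulation of gene expression in
scale-down STR-PFR bioreactors.

## The problem

Large industrial bioreactors mix slowly, so circulating cells repeatedly
cross nutrient-depleted zones. The standard laboratory mimic couples a
nitrogen-limited chemostat (stirred tank reactor, **STR**, 1120 mL,
dilution rate D = 0.2 h⁻¹) to a feed-free plug-flow loop (**PFR**,
380 mL, 180 mL min⁻¹): every passage is a ~125 s starvation pulse that
transiently switches on starvation genes. The tryptophan operon
(`trpL‑trpEDCBA`, one 6726 nt polycistronic mRNA under attenuation
control) is the tracked example — seeing `trpE` mRNA implies ribosomes
were translating the leader.

`strpfr` is for bioprocess and systems-biology modellers who want to
predict, from literature parameters alone, how such repeated short
pulses propagate into short-term transcript dynamics along the loop,
long-term population-level adaptation, and the much slower protein
response. It couples:

* a **deterministic 1D-lattice single-cell model** of one induction
  episode — RNA polymerases, ribosomes and RNases hopping at
  `velo = 21 nt s⁻¹` with 100 nt minimum spacings; transcription
  initiation only inside the induction window `t_ind = [30, 125] s`
  after PFR entry; per-gene translations-per-mRNA quotas
  `N_g^TL,max = (c_g^Prot · k_deg^Prot) / (c_g^mRNA · k_deg^mRNA)`
  (4/4/5/10/10 for trpE/D/C/B/A) gating both translation and 5′→3′
  degradation;
* a **Gillespie cell-distribution model**: PFR entry
  (α₁ = N_STR·q_PFR/V_STR), washout (α₂ = N_STR·q_feed/V_STR) and
  division at the constant propensity α₃ = N⁰_STR·D, with deterministic
  return 125 s after each PFR entry;
* a **superposition layer**: the episode is computed once and summed
  over every cell's logged PFR-entry flags,
  `N_g(t) = Σ_i N_g,SC(t − t_i^flag)`, yielding population mRNA/protein
  time courses, sampling-port profiles and the induction-state census.

The methods vignette (`vignettes/strpfr-methods.Rmd`) derives every rule
and documents the design choices.

## Worked example

```r
library(strpfr)

ep <- simulate_episode()           # one induction episode, deterministic
ep
#> <episode_trace> 20 transcripts initiated, 20 completed
#>   episode length: 493.1 s
#>   final proteins: trpL=0, trpE=80, trpD=80, trpC=100, trpB=200, trpA=200
```

One PFR–STR cycle produces 20 complete operon transcripts; the quotas
turn them into 80 TrpE/TrpD, 100 TrpC and 200 TrpB/TrpA copies —
9.7 / 12.2 / 24.3 proteins cell⁻¹ min⁻¹ over the 493 s cycle
(`episode_translation_rates(ep)`).

```r
run <- run_full(default_config(), duration = 7200, seed = 1)
run
#> <strpfr_run> seed 1 , 7200 s simulated
#>   episode: 20 transcripts, 493.1 s, proteins trpL=0 trpE=80 trpD=80 trpC=100 trpB=200 trpA=200
#>   compartments: 74.9% STR / 25.1% PFR (volumetric 74.7/25.3)
#>   induction census: 35% none / 48% once / 17% multiple
```

The 10,000 tracked cells settle at 74.9 % in the STR against the
74.7 vol% reference, and the stationary population is heterogeneous:
roughly a third of the cells carry no transcripts from any recent PFR
passage, half carry transcripts from exactly one, and a sixth re-entered
the loop while still induced. `pfr_port_profile(ep)` gives the
along-the-loop transcript pattern (only `trpL`/`trpE` regions active at
the 31/70/110 s ports), `population_trajectory()` the long-term
adaptation — per-capita mRNA plateaus within minutes, protein keeps
rising for ~15 h. Every result type has `tidy()`/`glance()` and
`autoplot()` methods; `steady_state_protein()` sweeps steady-state
protein levels against the protein degradation constant.

A thin command-line wrapper ships in `inst/cli/strpfr.R`
(`simulate-cell`, `simulate-population`, `full-run`, `steady-state`),
writing tidy TSVs plus a reproducibility manifest.

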