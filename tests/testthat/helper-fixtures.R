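# Shared fixtures.  The default episode and the full-scale population run
# are deterministic (or seeded) and reused across test files, so they are
# computed once per session and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_episode <- function() {
  cached("default_episode", simulate_episode())
}

default_population <- function(seed = 1L, duration = 7200) {
  cached(paste0("pop_", seed, "_", duration),
         run_population(reactor_config(), duration = duration, seed = seed))
}

# small operon: quota-0 leader plus two translated genes; short enough for
# the pure-R reference engine
small_operon <- function() {
  operon_definition(data.frame(
    name = c("ldr", "gA", "gB"),
    c_start = c(1, 51, 261),
    c_end = c(50, 260, 500),
    n_tl_max = c(0L, 2L, 3L)
  ), length = 500)
}

small_params <- function(t_ind = c(10, 40), spacing = 50) {
  sim_params(t_ind = t_ind, delta_x = spacing, delta_y = spacing,
             delta_z = spacing)
}

# random operon generator for property tests
random_operon <- function(seed) {
  set.seed(seed)
  n_genes <- sample(2:4, 1)
  lens <- sample(80:300, n_genes, replace = TRUE)
  gaps <- sample(0:30, n_genes, replace = TRUE)
  starts <- cumsum(c(1, utils::head(lens + gaps, -1)))
  ends <- starts + lens - 1
  operon_definition(data.frame(
    name = paste0("g", seq_len(n_genes)),
    c_start = starts,
    c_end = ends,
    n_tl_max = sample(1:5, n_genes, replace = TRUE)
  ), length = max(ends) + sample(0:40, 1))
}

# build a lattice state with hand-placed agents (unit tests of single ops)
state_with_strand <- function(params, operon, x = NULL, complete = FALSE,
                              y = numeric(0), gene = integer(0),
                              init_cnt = NULL, comp_cnt = NULL, z = 0,
                              t = 0) {
  st <- new_lattice_state(params, operon)
  st$t <- t
  ng <- nrow(operon$genes)
  if (!is.null(x) || complete) {
    st$strands[[1]] <- list(
      x = if (complete) operon$length else x,
      complete = complete,
      y = y, gene = gene,
      init_cnt = if (is.null(init_cnt)) integer(ng) else as.integer(init_cnt),
      comp_cnt = if (is.null(comp_cnt)) integer(ng) else as.integer(comp_cnt),
      z = z, degraded = FALSE
    )
  }
  st
}
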