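test_that("RNAP elongation advances, blocks on spacing, terminates", {
  p <- sim_params()
  op <- default_trp_operon()

  # lone polymerase advances at the elongation rate
  st <- state_with_strand(p, op, x = 500)
  st1 <- step_rnaps(st, dt = 1)
  expect_equal(st1$strands[[1]]$x, 521)

  # follower halts when the gap to its leader is below delta_x
  st <- state_with_strand(p, op, x = 380)
  st$strands[[2]] <- st$strands[[1]]
  st$strands[[2]]$x <- 300
  st1 <- step_rnaps(st)
  expect_equal(st1$strands[[1]]$x, 381, tolerance = 1e-9)
  expect_equal(st1$strands[[2]]$x, 300) # gap 81 < 100, halted

  # reaching the terminator completes the strand and detaches the RNAP
  st <- state_with_strand(p, op, x = op$length - 0.5)
  st1 <- step_rnaps(st)
  expect_true(st1$strands[[1]]$complete)
  expect_equal(st1$strands[[1]]$x, op$length)
  expect_equal(st1$n_complete, 1L)
})

test_that("transcription initiation obeys the induction window and spacing", {
  p <- sim_params()
  op <- default_trp_operon()
  st <- new_lattice_state(p, op)

  # before the 30 s induction delay
  expect_length(try_initiate_rnap(st, t = 20)$strands, 0)
  # after the window closes
  expect_length(try_initiate_rnap(st, t = 126)$strands, 0)
  # inside the window, clear track
  st1 <- try_initiate_rnap(st, t = 40)
  expect_length(st1$strands, 1)
  expect_equal(st1$strands[[1]]$x, 0) # reserved pre-initiation position
  # blocked by a trailing RNAP at 50 < delta_x
  st2 <- state_with_strand(p, op, x = 50)
  expect_length(try_initiate_rnap(st2, t = 40)$strands, 1)
})

test_that("ribosomes respect template lookahead, spacing, quota and detach", {
  p <- small_params()
  op <- small_operon()

  # template halt: fewer than delta_y nucleotides synthesized ahead
  st <- state_with_strand(p, op, x = 120, y = 80, gene = 2L,
                          init_cnt = c(0L, 1L, 0L))
  st1 <- step_ribosomes(st)
  expect_equal(st1$strands[[1]]$y, 80) # L - y = 40 <= 50

  # exhausted quota blocks further initiation; open genes initiate
  st <- state_with_strand(p, op, complete = TRUE, init_cnt = c(0L, 2L, 0L))
  st1 <- step_ribosomes(st)
  expect_equal(st1$strands[[1]]$gene, 3L) # only gB initiated
  expect_equal(st1$strands[[1]]$y, op$genes$c_start[3])
  expect_equal(st1$strands[[1]]$init_cnt, c(0L, 2L, 1L))

  # crossing the stop codon detaches the ribosome and counts one protein
  st <- state_with_strand(p, op, complete = TRUE, y = 259.5, gene = 2L,
                          init_cnt = c(0L, 2L, 3L), comp_cnt = c(0L, 1L, 0L))
  st1 <- step_ribosomes(st)
  expect_length(st1$strands[[1]]$y, 0)
  expect_equal(unname(st1$protein[2]), 1L)
  expect_equal(st1$strands[[1]]$comp_cnt[2], 2L)
})

test_that("RNase is quota-gated, trails the hindmost ribosome, retires strands", {
  p <- small_params()
  op <- small_operon()

  # parked at the boundary of a gene whose quota is not yet initiated
  st <- state_with_strand(p, op, complete = TRUE, z = 50,
                          init_cnt = c(0L, 1L, 0L))
  expect_equal(step_rnases(st)$strands[[1]]$z, 50)

  # halted within delta_z of the hindmost ribosome still on the strand
  st <- state_with_strand(p, op, complete = TRUE, y = 90, gene = 2L,
                          init_cnt = c(0L, 2L, 3L), z = 45)
  expect_equal(step_rnases(st)$strands[[1]]$z, 45)

  # free once all quotas are initiated and no ribosome remains
  st <- state_with_strand(p, op, complete = TRUE, z = 499.5,
                          init_cnt = c(0L, 2L, 3L), comp_cnt = c(0L, 2L, 3L))
  st1 <- step_rnases(st)
  expect_true(st1$strands[[1]]$degraded)
  expect_equal(st1$strands[[1]]$z, op$length)

  # never beyond the synthesized front of an incomplete strand
  st <- state_with_strand(p, op, x = 30, z = 29.5)
  expect_equal(step_rnases(st)$strands[[1]]$z, 30)
})

test_that("count_levels is synthesized-minus-degraded per gene", {
  p <- small_params()
  op <- small_operon()

  st <- new_lattice_state(p, op)
  expect_equal(count_levels(st)$mrna, c(0L, 0L, 0L))

  # one complete, undegraded strand counts once for every gene
  st <- state_with_strand(p, op, complete = TRUE)
  expect_equal(count_levels(st)$mrna, c(1L, 1L, 1L))

  # RNase past the leader start only: leader no longer counted
  st <- state_with_strand(p, op, complete = TRUE, z = 1)
  expect_equal(count_levels(st)$mrna, c(0L, 1L, 1L))

  # partially transcribed strand already counts for the genes it entered
  st <- state_with_strand(p, op, x = 60)
  expect_equal(count_levels(st)$mrna, c(1L, 1L, 0L))
})

test_that("compiled and pure-R engines produce identical traces", {
  p <- small_params()
  op <- small_operon()
  a <- simulate_episode(p, op, horizon = 400, engine = "cpp")
  b <- simulate_episode(p, op, horizon = 400, engine = "r")
  expect_equal(a$times, b$times)
  expect_equal(a$mrna, b$mrna)
  expect_equal(a$protein, b$protein)
  expect_equal(a$episode_length, b$episode_length)
  expect_equal(a$n_initiated, b$n_initiated)
  expect_equal(a$n_complete, b$n_complete)
})

test_that("the default episode reproduces per-cycle transcript and protein yields", {
  ep <- default_episode()
  expect_equal(ep$n_initiated, 20L)
  expect_equal(ep$n_complete, 20L)
  expect_equal(unname(ep$final_protein),
               c(0L, 80L, 80L, 100L, 200L, 200L))
  expect_false(ep$truncated)
  # the mRNA-positive support opens after the 30 s induction delay and
  # closes before the final nucleotide is degraded
  expect_gt(ep$mrna_span[1], 30)
  expect_lt(ep$mrna_span[2], ep$episode_length)
  # mRNA is zero at and beyond the episode length
  expect_true(all(ep$mrna[ep$times >= ep$mrna_span[2] + 1, ] == 0))
})

test_that("a zero-width induction window yields exactly one transcript", {
  ep <- simulate_episode(sim_params(t_ind = c(30, 30)), default_trp_operon())
  expect_equal(ep$n_initiated, 1L)
  quotas <- default_trp_operon()$genes$n_tl_max
  expect_equal(unname(ep$final_protein), quotas)
})

test_that("episodes are deterministic and truncation is flagged", {
  a <- simulate_episode(small_params(), small_operon())
  b <- simulate_episode(small_params(), small_operon())
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$protein, b$protein)

  expect_warning(
    tr <- simulate_episode(small_params(), small_operon(), horizon = 60),
    "truncated"
  )
  expect_true(tr$truncated)
})

test_that("episode look-ups clamp correctly and export is tidy", {
  ep <- default_episode()
  expect_equal(episode_mrna_at(ep, -5, "trpA"), 0L)
  expect_equal(episode_mrna_at(ep, ep$episode_length + 10, "trpA"), 0L)
  expect_equal(episode_protein_at(ep, ep$episode_length + 1000, "trpA"), 200L)
  e <- 200
  idx <- as.integer(round(e / ep$dt)) + 1L
  expect_equal(episode_mrna_at(ep, e, "trpB"), unname(ep$mrna[idx, "trpB"]))

  f <- withr::local_tempfile(fileext = ".tsv")
  export_episode(ep, f)
  df <- readr::read_tsv(f, show_col_types = FALSE)
  expect_named(df, c("time_s", "gene", "mrna_count", "protein_count"))
  expect_equal(nrow(df), length(ep$times) * 6)
})
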