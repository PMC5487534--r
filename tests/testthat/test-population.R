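test_that("event propensities follow the three rate laws", {
  r <- reactor_config()
  # empty STR: only the constant division propensity remains
  e0 <- event_rates(0, r)
  expect_equal(e0$rate_per_s[e0$event == "pfr_entry"], 0)
  expect_equal(e0$rate_per_s[e0$event == "washout"], 0)
  expect_equal(e0$rate_per_h[e0$event == "division"], 10000 * 0.2)

  e <- event_rates(10000, r)
  expect_equal(e$rate_per_min[e$event == "pfr_entry"], 10000 * 180 / 1120,
               tolerance = 1e-12) # 1607.14 per min
  expect_equal(e$rate_per_min[e$event == "washout"], 10000 * 5 / 1120)
  expect_equal(e$rate_per_h[e$event == "division"], 2000)
})

test_that("the Gillespie draw solves the direct-method formulas", {
  d <- gillespie_draw(c(1, 1), r1 = exp(-1), r2 = 0.9)
  expect_equal(d$tau, 0.5)
  expect_equal(d$event, 2L)
  # r2 -> 0+ selects the first feasible reaction
  expect_equal(gillespie_draw(c(2, 1, 1), r1 = 0.5, r2 = 1e-12)$event, 1L)
  # zero-propensity reactions are never selected
  expect_equal(gillespie_draw(c(0, 3), r1 = 0.5, r2 = 1e-12)$event, 2L)
  expect_equal(gillespie_draw(c(0, 3), r1 = 0.5, r2 = 1)$event, 2L)
  expect_error(gillespie_draw(c(0, 0)), "sum")
})

test_that("identical seeds give identical event logs", {
  a <- run_population(reactor_config(n0 = 300), duration = 1200, seed = 42)
  b <- run_population(reactor_config(n0 = 300), duration = 1200, seed = 42)
  expect_identical(a$events, b$events)
  expect_identical(a$cells, b$cells)
  c2 <- run_population(reactor_config(n0 = 300), duration = 1200, seed = 43)
  expect_false(identical(a$events, c2$events))
})

test_that("a disconnected PFR leaves every flag list empty", {
  pop <- run_population(reactor_config(n0 = 200, q_pfr = 0),
                        duration = 3600, seed = 1)
  expect_equal(nrow(pfr_flags(pop)), 0)
  expect_false(any(pop$events$event %in% c("pfr_entry", "pfr_return")))
  cc <- compartment_counts(pop, c(0, 1800, 3600))
  expect_equal(cc$n_pfr, c(0L, 0L, 0L))
})

test_that("zero duration produces an empty event log", {
  pop <- run_population(reactor_config(n0 = 100), duration = 0, seed = 1)
  expect_equal(nrow(pop$events), 0)
  expect_equal(compartment_counts(pop, 0)$n_str, 100L)
})

test_that("PFR returns are deterministic delays and daughters start flagless", {
  pop <- run_population(reactor_config(n0 = 500), duration = 3600, seed = 7)
  ev <- pop$events
  # every return happens exactly tau_pfr after a matching entry
  entries <- ev[ev$event == "pfr_entry", ]
  returns <- ev[ev$event == "pfr_return", ]
  # each return must sit exactly tau_pfr after one of that cell's entries
  expect_true(all(vapply(seq_len(nrow(returns)), function(i) {
    any(abs(entries$time_s[entries$cell_id == returns$cell_id[i]] -
              (returns$time_s[i] - pop$reactor$tau_pfr)) < 1e-9)
  }, logical(1))))
  # daughters are default cells: no flags before their birth
  divisions <- ev[ev$event == "division", ]
  fl <- pfr_flags(pop)
  born <- pop$cells$born_at[divisions$cell_id]
  first_flag <- vapply(divisions$cell_id, function(id) {
    ft <- fl$flag_time_s[fl$cell_id == id]
    if (length(ft) == 0) Inf else min(ft)
  }, numeric(1))
  expect_true(all(first_flag >= born))
})

test_that("cell bookkeeping balances at every sampled instant", {
  pop <- run_population(reactor_config(n0 = 400), duration = 5400, seed = 3)
  grid <- seq(0, 5400, by = 90)
  cc <- compartment_counts(pop, grid)
  ev <- pop$events
  for (i in seq_along(grid)) {
    t <- grid[i]
    divs <- sum(ev$event == "division" & ev$time_s <= t)
    wash <- sum(ev$event == "washout" & ev$time_s <= t)
    expect_equal(cc$n_str[i] + cc$n_pfr[i], 400 + divs - wash)
  }
  # counts also match the per-cell location fields at the end
  end <- compartment_counts(pop, 5400)
  expect_equal(end$n_str, sum(pop$cells$location == "STR"))
  expect_equal(end$n_pfr, sum(pop$cells$location == "PFR"))
})

test_that("the population self-stabilises at the washout-division balance", {
  # stationary STR count solves n0 * D = n_str * q_feed / v_str
  r <- reactor_config()
  pop <- run_population(r, duration = 86400, seed = 5)
  grid <- seq(57600, 86400, by = 120)
  cc <- compartment_counts(pop, grid)
  n_star <- r$n0 * r$dilution_rate / 3600 * r$v_str / (r$q_feed / 60)
  expect_equal(n_star, 7466.667, tolerance = 1e-6)
  expect_lt(abs(mean(cc$n_str) - n_star) / n_star, 0.03)
})

test_that("the PFR/STR ratio obeys the residence-time balance across seeds", {
  # little's law: n_pfr / n_str = (q_pfr / v_str) * tau_pfr
  r <- reactor_config(n0 = 1000)
  target <- (r$q_pfr / 60 / r$v_str) * r$tau_pfr
  ratios <- vapply(1:10, function(seed) {
    pop <- run_population(r, duration = 7200, seed = seed)
    cc <- compartment_counts(pop, seq(1800, 7200, by = 60))
    mean(cc$n_pfr / cc$n_str)
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - target), 3 * se + 1e-6)
})

test_that("inter-event waiting times are exponential at fixed propensity", {
  # with entries and washouts switched off only the constant division
  # propensity remains, so waiting times are iid exponential
  r <- reactor_config(n0 = 500, q_pfr = 0, q_feed = 0)
  pop <- run_population(r, duration = 36000, seed = 9)
  waits <- diff(c(0, pop$events$time_s))
  rate <- r$n0 * r$dilution_rate / 3600
  expect_gt(length(waits), 500)
  ks <- suppressWarnings(stats::ks.test(waits, "pexp", rate = rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("census reports counts, fractions and the volumetric reference", {
  pop <- default_population()
  cen <- compartment_census(pop, c(0, 3600))
  expect_equal(cen$frac_str[1], 1) # initial condition: everyone in the STR
  expect_equal(cen$vol_frac_str[1], 1120 / 1500)
  expect_equal(cen$frac_str + cen$frac_pfr, c(1, 1))
  expect_error(compartment_census(pop, 7201), "span")
})

test_that("event log and flag exports are tidy TSV", {
  pop <- run_population(reactor_config(n0 = 100), duration = 600, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_events(pop, f1)
  export_flags(pop, f2)
  ev <- readr::read_tsv(f1, show_col_types = FALSE)
  fl <- readr::read_tsv(f2, show_col_types = FALSE)
  expect_named(ev, c("time_s", "event", "cell_id"))
  expect_named(fl, c("cell_id", "flag_time_s"))
  expect_true(all(fl$flag_time_s %in% ev$time_s))
})
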