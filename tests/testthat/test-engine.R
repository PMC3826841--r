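test_that("a synchronous step follows the rules", {
  tg <- make_toy_model("toggle")
  st <- active_start_state(tg)   # (T1, T2) = (1, 0)
  nxt <- step_model(st, tg)
  expect_equal(nxt[c("T1", "T2")], c(T1 = 0L, T2 = 1L))
  expect_equal(step_model(nxt, tg)[c("T1", "T2")], c(T1 = 1L, T2 = 0L))
  ## with all dosages at 1 the step is deterministic
  m <- yeast_model()
  s0 <- active_start_state(m)
  expect_identical(step_model(s0, m, seed = 1), step_model(s0, m, seed = 999))
})

test_that("wild-type simulation is deterministic regardless of seed", {
  m <- yeast_model()
  a <- simulate_model(m, config = sim_config(100, 3, seed = 1))
  b <- simulate_model(m, config = sim_config(100, 3, seed = 12345))
  expect_identical(a$replicates, b$replicates)
  expect_true(all(a$replicates$period_sum / a$replicates$period_count == 31))
})

test_that("identical seeds give byte-identical summaries, distinct seeds differ", {
  m <- gated_ring_toy(6, gated = 4L)
  cfg <- sim_config(300, 40, seed = 99)
  a <- simulate_model(m, dosage_spec(c(G = 0.5)), cfg)
  b <- simulate_model(m, dosage_spec(c(G = 0.5)), cfg)
  expect_identical(serialize(a$replicates, NULL), serialize(b$replicates, NULL))
  c2 <- simulate_model(m, dosage_spec(c(G = 0.5)), sim_config(300, 40, seed = 100))
  expect_false(identical(a$replicates, c2$replicates))
})

test_that("replicate blocks pool to the same summaries (replicate additivity)", {
  m <- gated_ring_toy(6, gated = 4L)
  whole <- simulate_model(m, dosage_spec(c(G = 0.5)),
                          sim_config(200, 30, seed = 3))
  first <- simulate_model(m, dosage_spec(c(G = 0.5)),
                          sim_config(200, 18, seed = 3))
  rest <- simulate_model(m, dosage_spec(c(G = 0.5)),
                         sim_config(200, 12, seed = 3),
                         replicate_offset = 18L)
  expect_equal(rbind(first$replicates, rest$replicates), whole$replicates,
               ignore_attr = TRUE)
})

test_that("cycle events need a run longer than two steps and a mass return", {
  tg <- make_toy_model("toggle")  # supplies the event-node designation
  mk_traj <- function(cyt, mass) {
    tr <- cbind(T1 = 0L, T2 = 0L, CYT = as.integer(cyt),
                MASS = as.integer(mass))
    tr
  }
  ## 2-step run: not an event
  ev <- detect_cycles(mk_traj(c(0, 0, 2, 2, 0, 0), c(2, 2, 2, 2, 1, 1)), tg)
  expect_equal(nrow(ev), 0L)
  ## 3-step run followed by a mass return: one event
  ev <- detect_cycles(mk_traj(c(0, 2, 2, 2, 0, 0), c(2, 2, 2, 2, 2, 1)), tg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$run_length, 3L)
  expect_equal(ev$end_step, 5L)
  ## without the mass return the event stays pending and is discarded...
  ev <- detect_cycles(mk_traj(c(0, 2, 2, 2, 0, 0), c(2, 2, 2, 2, 2, 2)), tg)
  expect_equal(nrow(ev), 0L)
  ## ...unless the mass-return requirement is switched off
  ev <- detect_cycles(mk_traj(c(0, 2, 2, 2, 0, 0), c(2, 2, 2, 2, 2, 2)), tg,
                      require_mass_return = FALSE)
  expect_equal(nrow(ev), 1L)
  ## a run truncated by the trajectory end is discarded
  ev <- detect_cycles(mk_traj(c(0, 0, 2, 2, 2), c(2, 2, 2, 2, 2)), tg)
  expect_equal(nrow(ev), 0L)
  ## constant-zero trajectory: no events
  ev <- detect_cycles(mk_traj(rep(0, 6), rep(1, 6)), tg)
  expect_equal(nrow(ev), 0L)
})

test_that("the engine's streaming event counts match detect_cycles", {
  m <- gated_ring_toy(8, gated = 5L)
  cfg <- sim_config(400, 1, seed = 21, record_trajectory = TRUE)
  sim <- simulate_model(m, dosage_spec(c(G = 0.6)), cfg)
  ev <- detect_cycles(sim$trajectory, m)
  expect_equal(sim$replicates$events[1], nrow(ev))
  expect_equal(sim$replicates$period_sum[1], sum(ev$period))
})

test_that("a ring oscillator completes floor(n/p) events", {
  for (k in c(6L, 8L)) {
    r <- make_toy_model("ring-oscillator", k)
    for (n in c(5L * k, 5L * k + k - 1L)) {
      sim <- simulate_model(r, config = sim_config(n, 1, 1))
      expect_equal(sim$replicates$events, floor(n / k))
    }
  }
})

test_that("growth rates recover the analytic periods of the toys", {
  ## arrester: no reachable cytokinesis event
  a <- growth_rate(make_toy_model("arrester", 6),
                   config = sim_config(400, 2, 1), wt_period = 6)
  expect_true(a$arrested)
  expect_equal(a$relative_growth_rate, 0)
  ## paced ring: knocking out the pacing gene doubles the period
  p <- make_toy_model("paced", 6)
  g0 <- growth_rate(p, dosage_spec(c(PACE = 0)), sim_config(3000, 4, 2))
  expect_close(g0$relative_growth_rate, 0.5, 0.01)
  g1 <- growth_rate(p, config = sim_config(3000, 1, 2))
  expect_close(g1$relative_growth_rate, 1, 0.01)
})
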