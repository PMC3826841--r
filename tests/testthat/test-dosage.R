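test_that("dosage specifications validate their inputs", {
  d <- dosage_spec(c(HSL1 = 0.25, CDC28 = 1))
  expect_equal(unname(reset_probability(d)["HSL1"] + d$fractions[["HSL1"]]), 1)
  expect_error(dosage_spec(c(A = 1.2)), "\\[0, 1\\]")
  expect_error(dosage_spec(c(A = -0.1)), "\\[0, 1\\]")
  expect_error(dosage_spec(c(0.5)), "named")
  expect_error(inhibitor_spec("CDC28", 2), "\\[0, 1\\]")
})

test_that("occurrence and outcome sampling follow the reset rubric", {
  ## d = 1: the true value is always read; d = 0: always zero
  expect_equal(sample_occurrence(2L, 1), 2L)
  expect_equal(sample_occurrence(2L, 0, u = 0.99), 0L)
  expect_equal(sample_occurrence(0L, 0.5, u = 0.01), 0L)
  expect_equal(sample_occurrence(2L, 0.5, u = 0.49), 2L)
  expect_equal(sample_occurrence(2L, 0.5, u = 0.51), 0L)
  ## unsatisfied requirements give 0 at any dosage; satisfied multi-valued
  ## requirements keep their level with probability d
  expect_equal(apply_target_reset(0L, 0.25), 0L)
  expect_equal(apply_target_reset(2L, 1), 2L)
  expect_equal(apply_target_reset(2L, 0.75, u = 0.74), 2L)
  expect_equal(apply_target_reset(2L, 0.75, u = 0.76), 0L)
})

test_that("d = 1 reproduces the deterministic model and d = 0 the hard knockout", {
  m <- gated_ring_toy(6, gated = 4L)
  cfg <- sim_config(n_steps = 60, n_replicates = 2, seed = 11,
                    record_trajectory = TRUE)
  wt <- simulate_model(m, dosage_spec(c(G = 1)), cfg)
  det <- simulate_model(m, config = cfg)
  expect_identical(wt$trajectory, det$trajectory)
  expect_identical(wt$replicates[, -1], det$replicates[, -1])

  ## knockout: trajectories equal those of a model with the gene clamped
  ko <- simulate_model(m, dosage_spec(c(G = 0)), cfg)
  m_clamped <- m
  m_clamped$rules <- Filter(function(r) r$target != "G", m_clamped$rules)
  m_clamped$start_state["G"] <- 0L
  clamped <- simulate_model(m_clamped, config = cfg)
  ## identical dynamics from the first update on (the declared START states
  ## differ only in the clamped gene's own entry)
  expect_identical(ko$trajectory[-1, ], clamped$trajectory[-1, ])
  expect_identical(ko$replicates[, -1], clamped$replicates[, -1])
  ## the gate never opens: the token is absorbed before the gated stage
  expect_true(all(ko$replicates$events == 0))
})

test_that("inhibitor activity is the same mechanism as fractional dosage", {
  m <- gated_ring_toy(6, gated = 4L)
  expect_equal(inhibitor_spec("G", 0.25)$fractions,
               dosage_spec(c(G = 0.25))$fractions)
  cfg <- sim_config(n_steps = 300, n_replicates = 50, seed = 5)
  a <- simulate_model(m, inhibitor_spec("G", 0.4), cfg)
  b <- simulate_model(m, dosage_spec(c(G = 0.4)), cfg)
  expect_identical(a$replicates, b$replicates)
  ## activity 1 is wild type; activity 0 is the knockout
  expect_equal(inhibitor_spec("G", 1)$fractions[["G"]], 1)
  expect_equal(inhibitor_spec("G", 0)$fractions[["G"]], 0)
})

test_that("per-occurrence draws are independent within one expression", {
  ## same gene twice under OR at d = 0.5: given the gene active, the
  ## expression reads true with probability 1 - 0.25 = 0.75 (exact oracle)
  m <- occurrence_toy(expr_or(expr_ge("G"), expr_ge("G")))
  ch <- build_chain(m, dosage_spec(c(G = 0.5)))
  from <- chain_state_index(ch, c(G = 1L, T = 0L, CYT = 0L, MASS = 1L))
  row <- ch$P[from, ]
  t_on <- ch$states[, "T"] == 1L
  expect_equal(sum(row[t_on]), 0.75)
  ## single occurrence for comparison: probability d = 0.5
  m1 <- occurrence_toy(expr_ge("G"))
  ch1 <- build_chain(m1, dosage_spec(c(G = 0.5)))
  row1 <- ch1$P[chain_state_index(ch1, c(G = 1L, T = 0L, CYT = 0L, MASS = 1L)), ]
  expect_equal(sum(row1[ch1$states[, "T"] == 1L]), 0.5)
})

test_that("dosing a gene absent from the model is an error", {
  m <- gated_ring_toy(6)
  expect_error(simulate_model(m, dosage_spec(c(NOPE = 0.5))), "NOPE")
  expect_error(run_dose_series(m, "NOPE", c(1, 0.5)), "NOPE")
})
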