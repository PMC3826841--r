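test_that("transition matrices are row-stochastic and deterministic at d = 1", {
  for (m in list(make_toy_model("toggle"), gated_ring_toy(6, gated = 4L))) {
    ch <- build_chain(m)
    expect_close(max(abs(Matrix::rowSums(ch$P) - 1)), 0, 1e-12)
    ## every row is a single unit entry equal to the synchronous step map
    expect_true(all(ch$P@x == 1))
    rbt <- rules_by_target(active_rules(m))
    for (s in sample.int(nrow(ch$states), 20, replace = TRUE)) {
      st <- stats::setNames(as.integer(ch$states[s, ]), ch$node_names)
      nxt <- step_state_r(st, rbt)
      expect_equal(which(ch$P[s, ] > 0), chain_state_index(ch, nxt),
                   ignore_attr = TRUE)
    }
  }
  ## dosed chains stay row-stochastic
  ch <- build_chain(gated_ring_toy(6, gated = 4L), dosage_spec(c(G = 0.3)))
  expect_close(max(abs(Matrix::rowSums(ch$P) - 1)), 0, 1e-12)
})

test_that("a single-occurrence target at d = 0.5 splits {1: 0.5, 0: 0.5}", {
  m <- occurrence_toy()
  ch <- build_chain(m, dosage_spec(c(G = 0.5)))
  from <- chain_state_index(ch, c(G = 1L, T = 0L, CYT = 0L, MASS = 1L))
  p_on <- sum(ch$P[from, ch$states[, "T"] == 1L])
  expect_equal(p_on, 0.5)
  expect_equal(sum(ch$P[from, ch$states[, "T"] == 0L]), 0.5)
})

test_that("exact occupancies match the known toy values", {
  ## period-2 toggle over an even horizon: 0.5 / 0.5 on the two cycle states
  tg <- make_toy_model("toggle")
  ch <- build_chain(tg)
  occ <- transient_occupancy(ch, n_steps = 10)
  expect_equal(sort(occ[occ > 0]), c(0.5, 0.5))
  ph <- oracle_phase_occupancy(ch, occ)
  expect_equal(unname(ph[c("G1", "S_G2")]), c(0.5, 0.5))

  ## a knocked-out gate is absorbing: occupancy of the stalled state -> 1
  m <- gated_ring_toy(6, gated = 4L)
  ch0 <- build_chain(m, dosage_spec(c(G = 0)))
  occ_short <- transient_occupancy(ch0, n_steps = 20)
  occ_long <- transient_occupancy(ch0, n_steps = 400)
  expect_true(max(occ_long) > max(occ_short))
  expect_close(max(occ_long), 1, 0.05)
})

test_that("engine and oracle agree exactly at d in {0, 1}", {
  m <- gated_ring_toy(6, gated = 4L)
  for (d in c(0, 1)) {
    ch <- build_chain(m, dosage_spec(c(G = d)))
    occ <- oracle_phase_occupancy(ch, transient_occupancy(ch, n_steps = 120))
    prof <- phase_profile(m, dosage_spec(c(G = d)), sim_config(120, 2, 1))
    expect_close(max(abs(prof$raw_fraction - occ[1:3])), 0, 1e-12)
    expect_close(prof$unclassified_fraction, occ[["unclassified"]], 1e-12)
  }
})

test_that("Monte-Carlo occupancies agree with the exact chain within 3 SE", {
  fixtures <- list(
    list(model = gated_ring_toy(6, gated = 4L), dose = c(G = 0.5)),
    list(model = gated_ring_toy(7, gated = c(4L, 6L)), dose = c(G = 0.7)),
    list(model = occurrence_toy(expr_or(expr_ge("G"), expr_ge("G"))),
         dose = c(G = 0.5)))
  for (fx in fixtures) {
    ch <- build_chain(fx$model, dosage_spec(fx$dose))
    occ <- oracle_phase_occupancy(ch, transient_occupancy(ch, n_steps = 150))
    prof <- phase_profile(fx$model, dosage_spec(fx$dose),
                          sim_config(150, 500, seed = 17))
    for (ph in c("G1", "S_G2", "M")) {
      se <- max(prof$se[[ph]], 1e-6)
      expect_true(abs(prof$raw_fraction[[ph]] - occ[[ph]]) <= 3 * se,
                  label = sprintf("%s %s: MC %.4f vs exact %.4f (se %.5f)",
                                  fx$model$name, ph, prof$raw_fraction[[ph]],
                                  occ[[ph]], se))
    }
  }
})

test_that("oversized state spaces are refused with advice", {
  expect_error(build_chain(yeast_model()), "Monte-Carlo")
})
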