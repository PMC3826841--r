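test_that("control coefficients reproduce their closed forms", {
  ## flat flux: C = 0 exactly
  flat <- data.frame(gene = "X", dose = c(1, 0.5), rate = c(1, 1))
  expect_equal(control_coefficients(flat)$C, 0)
  ## J falls by 10% when E falls by 50%: midpoint form gives
  ## (dJ/Jbar) / (dE/Ebar) = (-0.1/0.95) / (-0.5/0.75) = 0.15789...
  ## while the plain high-point form gives the textbook 0.2
  drop10 <- data.frame(gene = "X", dose = c(1, 0.5), rate = c(1, 0.9))
  cc <- control_coefficients(drop10)
  expect_equal(cc$dJ_over_J, -0.1 / 0.95)
  expect_equal(cc$dE_over_E, -0.5 / 0.75)
  expect_equal(cc$C, (-0.1 / 0.95) / (-0.5 / 0.75))
  expect_close((drop10$rate[2] - drop10$rate[1]) / drop10$rate[1] /
                 ((drop10$dose[2] - drop10$dose[1]) / drop10$dose[1]),
               0.2, 1e-12)
  ## proportional flux J = E: C = 1 on every interval
  lin <- data.frame(gene = "X", dose = c(1, 0.5, 0.25),
                    rate = c(1, 0.5, 0.25))
  expect_equal(control_coefficients(lin)$C, c(1, 1))
})

test_that("coefficients are scale invariant and signed by direction", {
  base <- data.frame(gene = "X", dose = c(1, 0.75, 0.5),
                     rate = c(1, 0.9, 0.7))
  scaled <- transform(base, rate = rate * 37)
  expect_equal(control_coefficients(base)$C, control_coefficients(scaled)$C)
  ## haploinsufficient-like (J falls with E): C > 0
  expect_true(all(control_coefficients(base)$C > 0))
  ## haploproficient-like (J rises as E falls): C < 0
  up <- data.frame(gene = "X", dose = c(1, 0.5), rate = c(1, 1.2))
  expect_true(control_coefficients(up)$C < 0)
})

test_that("arrested and degenerate series are handled", {
  rows <- data.frame(gene = "X", dose = c(1, 0.5, 0),
                     rate = c(1, 0.8, 0), arrested = c(FALSE, FALSE, TRUE))
  expect_warning(cc <- control_coefficients(rows), "arrested")
  expect_equal(nrow(cc), 1L)
  expect_error(suppressWarnings(control_coefficients(rows[c(1, 3), ])),
               "at least 2")
})

test_that("a gene gating two ring transitions carries unit flux control", {
  ## gated ring, k = 6 with two gated entries: expected period
  ## T(d) = 4 + 2/d^2, so J(1) = 1 and J(0.5) = 0.5 -- the flux tracks the
  ## effector over {1, 0.5} and the interval coefficient is 1
  m <- gated_ring_toy(6, gated = c(3L, 5L))
  s <- run_dose_series(m, "G", c(1, 0.5), sim_config(2000, 120, seed = 9),
                       profiles = FALSE)
  expect_close(s$rows$rate[1], 1, 1e-9)
  expect_close(s$rows$rate[2], 0.5, 0.03)
  expect_close(control_coefficients(s)$C, 1, 0.12)
  ## while a spectator gene in the same model has C = 0 exactly:
  ## dosing the yeast osmotic-pathway genes leaves the flux flat
  y <- yeast_model()
  sy <- run_dose_series(y, "HOG1", c(1, 0.5, 0.25),
                        sim_config(600, 20, seed = 9), profiles = FALSE)
  expect_equal(control_coefficients(sy)$C, c(0, 0))
})

test_that("dose series are ordered, anchored at WT, and cache-consistent", {
  m <- gated_ring_toy(6, gated = 4L)
  s <- run_dose_series(m, "G", c(0.5, 1, 0.75), sim_config(500, 30, seed = 4))
  expect_equal(s$rows$dose, c(1, 0.75, 0.5))
  expect_equal(s$rows$rate[1], 1)
  expect_error(run_dose_series(m, "G", c(0.75, 0.5)), "1.0")
  ## degenerate single-dose series: one WT row
  s1 <- run_dose_series(m, "G", 1, sim_config(100, 5, seed = 4),
                        profiles = FALSE)
  expect_equal(nrow(s1$rows), 1L)
  expect_equal(s1$rows$rate, 1)
})
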