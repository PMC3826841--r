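test_that("packaged extended model has the expected size and structure", {
  m <- yeast_model()
  act <- active_nodes(m)
  ## 22-node core extended by 30 checkpoint-related nodes
  expect_equal(nrow(act), 22 + 30)
  expect_setequal(unique(act$role), c("gene", "state-variable", "event-marker"))
  expect_equal(attr(validate_model(m), "wt_period"), 31L)
  ## every rule and signature reference resolves (validation passed), and
  ## the event designation is coherent
  expect_true(m$event_nodes$cytokinesis_level <=
                act$max_level[act$name == m$event_nodes$cytokinesis])
  expect_setequal(names(m$modules),
                  c("spindle_checkpoint", "dna_damage", "osmotic_stress"))
})

test_that("parse -> write -> parse is the identity and writes are canonical", {
  m <- yeast_model()
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_model(m, f1)
  m2 <- parse_model(f1)
  keep <- c("name", "nodes", "rules", "signatures", "start_state",
            "event_nodes", "modules")
  expect_equal(unclass(m2)[keep], unclass(m)[keep])
  write_model(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
})

test_that("the installed extdata model file matches the constructor", {
  m <- parse_model(yeast_model_path())
  expect_equal(attr(validate_model(m), "wt_period"), 31L)
  f <- tempfile(fileext = ".json")
  write_model(yeast_model(), f)
  expect_identical(readLines(f), readLines(yeast_model_path()))
})

test_that("module toggles are recorded through the file round trip", {
  m <- toggle_module(yeast_model(), "dna_damage", TRUE)
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  expect_true(parse_model(f, validate = FALSE)$modules$dna_damage$enabled)
})

test_that("schema violations are rejected with the offending name", {
  f <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    name = "bad",
    nodes = list(list(name = "A", max_level = 1, role = "gene"),
                 list(name = "B", max_level = 1, role = "gene")),
    rules = list(list(target = "A", target_level = 1,
                      expr = list("GE", "X", 1))),
    signatures = list(G1 = list("GE", "A", 0), S_G2 = list("GE", "X", 1),
                      M = list("GE", "X", 1)),
    start_state = list(A = 1, B = 0),
    event_nodes = list(cytokinesis = "A", mass = "B", cytokinesis_level = 1),
    modules = list()), auto_unbox = TRUE), f)
  expect_error(parse_model(f), "\"X\"")

  ## level outside the referenced node's range
  bad <- occurrence_toy()
  bad$rules[[2]]$expr <- expr_ge("G", 5L)
  expect_error(validate_model(bad), "out of range")

  ## non-exclusive signatures on the WT cycle
  bad2 <- occurrence_toy()
  bad2$signatures$S_G2 <- expr_ge("G")
  expect_error(validate_model(bad2), "not a partition")
})

test_that("module toggling follows the activation semantics", {
  m <- blockable_ring_toy(6)
  expect_error(toggle_module(m, "nonsense", TRUE), "arrest_block")

  ## an empty module block does not change the dynamics
  m_empty <- toggle_module(m, "empty_module", TRUE)
  expect_equal(wt_cycle(m_empty)$states, wt_cycle(m)$states)

  ## an enabled but untriggered checkpoint module leaves the WT period alone
  y_sac <- toggle_module(yeast_model(), "spindle_checkpoint", TRUE)
  expect_equal(wt_cycle(y_sac)$period, 31L)

  ## a module clamping the cytokinesis marker abolishes growth
  cfg <- sim_config(n_steps = 200, n_replicates = 1, seed = 1)
  expect_equal(growth_rate(m, config = cfg)$relative_growth_rate, 1)
  g_blocked <- growth_rate(toggle_module(m, "arrest_block", TRUE),
                           config = cfg, wt_period = 6)
  expect_true(g_blocked$arrested)
  expect_equal(g_blocked$relative_growth_rate, 0)
})

test_that("toy generators have their advertised analytic behaviour", {
  expect_equal(wt_cycle(make_toy_model("toggle"))$period, 2L)
  for (k in c(6L, 8L))
    expect_equal(wt_cycle(make_toy_model("ring-oscillator", k))$period, k)
  expect_equal(wt_cycle(make_toy_model("paced", 5))$period, 5L)
  ## the arrester rests at its arrested fixed point
  expect_equal(wt_cycle(make_toy_model("arrester", 6))$period, 1L)
  ## enumeration bound is enforced for the exact-analysis kinds
  expect_error(make_toy_model("ring-oscillator", 12), "4096")
})
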