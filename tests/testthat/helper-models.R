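## Shared fixture builders. All fixtures are constructed in code; the gated
## ring is the workhorse for engine-vs-oracle comparisons because its gate
## gene gives it nontrivial dosage dynamics while the token structure keeps
## the reachable state set small and cleanly classified.

## Token ring of k stages whose entries into the stages listed in `gated`
## require the constitutive gene G to be read active. With G at dosage d the
## per-step pass probability of each gate is d^2 (state x occurrence), so
## the expected period is k + n_gates * (1/d^2 - 1).
gated_ring_toy <- function(k = 6L, gated = c(4L)) {
  stopifnot(k >= 6L)
  stages <- paste0("S", seq_len(k))
  nodes <- data.frame(
    name = c(stages, "G", "CYT", "MASS"),
    max_level = c(rep(1L, k), 1L, 2L, 2L),
    role = c(rep("state-variable", k), "gene", "event-marker", "event-marker"))
  rules <- lapply(seq_len(k), function(i) {
    prv <- if (i == 1L) k else i - 1L
    nxt <- if (i == k) 1L else i + 1L
    entry <- list(expr_ge(stages[prv]), expr_not(expr_ge(stages[i])))
    if (i %in% gated) entry <- c(entry, list(expr_ge("G")))
    list(target = stages[i], target_level = 1L,
         expr = expr_or(do.call(expr_and, entry),
                        expr_and(expr_ge(stages[i]),
                                 expr_not(expr_ge(stages[nxt])))))
  })
  mass1 <- expr_or(expr_ge(stages[k - 1L]), expr_ge(stages[k]),
                   expr_ge("S1"), expr_ge("S2"))
  rules <- c(rules, list(
    list(target = "G", target_level = 1L, expr = expr_ge("G", 0L)),
    list(target = "CYT", target_level = 2L,
         expr = expr_or(expr_ge(stages[k - 3L]), expr_ge(stages[k - 2L]))),
    list(target = "MASS", target_level = 2L, expr = expr_not(mass1)),
    list(target = "MASS", target_level = 1L, expr = mass1)))
  a <- max(1L, floor(k / 3)); b <- max(a + 1L, floor(2 * k / 3))
  or_of <- function(idx) do.call(expr_or, lapply(stages[idx], expr_ge))
  sigs <- list(G1 = expr_and(or_of(1:a), expr_not(expr_ge(stages[a + 1L]))),
               S_G2 = expr_and(or_of((a + 1L):b),
                               expr_not(expr_ge(stages[b + 1L]))),
               M = expr_and(or_of((b + 1L):k), expr_not(expr_ge("S1"))))
  start <- stats::setNames(rep(0L, nrow(nodes)), nodes$name)
  start[c(stages[k], "S1", "G", "MASS")] <- 1L
  model_definition(nodes, rules, sigs, start,
                   event_nodes = list(cytokinesis = "CYT", mass = "MASS",
                                      cytokinesis_level = 2L),
                   name = "gated-ring")
}

## Minimal 2-node fixture for occurrence-level semantics: constitutive gene
## G and a target T. `target_expr` defaults to a single occurrence; pass
## expr_or(expr_ge("G"), expr_ge("G")) for the double-occurrence case.
occurrence_toy <- function(target_expr = expr_ge("G")) {
  nodes <- data.frame(
    name = c("G", "T", "CYT", "MASS"),
    max_level = c(1L, 1L, 2L, 1L),
    role = c("gene", "state-variable", "event-marker", "event-marker"))
  rules <- list(
    list(target = "G", target_level = 1L, expr = expr_ge("G", 0L)),
    list(target = "T", target_level = 1L, expr = target_expr),
    list(target = "MASS", target_level = 1L, expr = expr_ge("MASS", 0L)))
  sigs <- list(G1 = expr_ge("MASS"),
               S_G2 = expr_and(expr_ge("CYT"), expr_not(expr_ge("MASS"))),
               M = expr_and(expr_ge("CYT", 2L), expr_not(expr_ge("MASS"))))
  model_definition(nodes, rules, sigs,
                   start_state = c(G = 1L, T = 1L, CYT = 0L, MASS = 1L),
                   event_nodes = list(cytokinesis = "CYT", mass = "MASS",
                                      cytokinesis_level = 2L),
                   name = "occurrence-toy")
}

## Ring toy carrying a module whose single node, once enabled, clamps the
## cytokinesis marker below its completion level (a hard checkpoint block),
## plus a genuinely empty module block.
blockable_ring_toy <- function(k = 6L) {
  m <- gated_ring_toy(k, gated = integer(0))
  stages <- paste0("S", seq_len(k))
  cyt_rule <- which(vapply(m$rules, function(r)
    r$target == "CYT" && r$target_level == 2L, logical(1L)))
  m$rules[[cyt_rule]]$expr <- expr_and(m$rules[[cyt_rule]]$expr,
                                       expr_not(expr_ge("BLOCK")))
  m$modules <- list(
    arrest_block = list(
      nodes = data.frame(name = "BLOCK", max_level = 1L,
                         role = "state-variable"),
      rules = list(list(target = "BLOCK", target_level = 1L,
                        expr = expr_ge("BLOCK", 0L))),
      enabled = FALSE),
    empty_module = list(
      nodes = data.frame(name = character(0), max_level = integer(0),
                         role = character(0)),
      rules = list(), enabled = FALSE))
  validate_model(m)
  m
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.4f within %.4f of %.4f", object, tol,
                              expected))
}
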