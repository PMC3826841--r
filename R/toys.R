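#' Generate small test models with analytically known behaviour
#'
#' Toy fixtures exercising the full machinery (event nodes, signatures,
#' dosage gating) at a size where behaviour can be derived by hand or by
#' exact enumeration:
#'
#' * `"toggle"` — a deterministic period-2 two-node oscillator.
#' * `"ring-oscillator"` — a token ring of `size` stages with deterministic
#'   period `size`; one cytokinesis run (length 3) and one mass return per
#'   lap, so `floor(n_steps / size)` events complete in `n_steps` steps.
#' * `"arrester"` — a ring whose first transition requires a permanently
#'   inactive node; the START state is the arrested fixed point and no
#'   cytokinesis event is ever reachable.
#' * `"paced"` — a ring of `2 * size` stages with a shortcut after stage
#'   `size` taken whenever the pacing gene `PACE` is read active: the
#'   wild-type period is `size`, and a `PACE` knockout (`d = 0`) forces the
#'   long way round, exactly doubling the period (relative growth rate 0.5).
#'
#' The three enumerable kinds are kept within the exact-oracle bound
#' (state space at most 4096 states, checked); `"paced"` is a Monte-Carlo
#' scale fixture and is exempt from the bound.
#'
#' @param kind One of `"toggle"`, `"ring-oscillator"`, `"arrester"`,
#'   `"paced"`.
#' @param size Ring length (stage count); ignored for `"toggle"`.
#' @return A validated `logicyc_model`.
#' @export
make_toy_model <- function(kind = c("toggle", "ring-oscillator", "arrester",
                                    "paced"),
                           size = 6L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  switch(kind,
         "toggle" = toy_toggle(),
         "ring-oscillator" = toy_ring(size, arrest = FALSE),
         "arrester" = toy_ring(size, arrest = TRUE),
         "paced" = toy_paced(size))
}

toy_state_bound <- function(card, kind) {
  if (prod(card) > 4096)
    stop("state space of toy \"", kind, "\" would have ", prod(card),
         " states, exceeding the exact-enumeration bound of 4096",
         call. = FALSE)
}

toy_toggle <- function() {
  nodes <- data.frame(
    name = c("T1", "T2", "CYT", "MASS"),
    max_level = c(1L, 1L, 2L, 1L),
    role = c("state-variable", "state-variable", "event-marker",
             "event-marker"))
  ## the two nodes swap values each step: (1,0) -> (0,1) -> (1,0), period 2
  rules <- list(
    list(target = "T1", target_level = 1L, expr = expr_ge("T2")),
    list(target = "T2", target_level = 1L, expr = expr_ge("T1")),
    list(target = "MASS", target_level = 1L, expr = expr_ge("MASS", 0L)))
  sigs <- list(G1 = expr_ge("T1"),
               S_G2 = expr_and(expr_not(expr_ge("T1")), expr_ge("T2")),
               M = expr_and(expr_ge("T1"), expr_ge("T2")))
  toy_state_bound(nodes$max_level + 1L, "toggle")
  model_definition(
    nodes, rules, sigs,
    start_state = c(T1 = 1L, T2 = 0L, CYT = 0L, MASS = 1L),
    event_nodes = list(cytokinesis = "CYT", mass = "MASS",
                       cytokinesis_level = 2L),
    name = "toy-toggle")
}

## token-ring stage rule: on when the predecessor hands over (entry), stays
## on until the successor has taken over (maintenance)
ring_stage_rule <- function(i, k, extra_entry = NULL, gate = NULL) {
  prv <- if (i == 1L) k else i - 1L
  nxt <- if (i == k) 1L else i + 1L
  entry <- c(list(expr_ge(paste0("S", prv)),
                  expr_not(expr_ge(paste0("S", i)))), gate)
  list(target = paste0("S", i), target_level = 1L,
       expr = expr_or(do.call(expr_and, entry),
                      expr_and(expr_ge(paste0("S", i)),
                               expr_not(expr_ge(paste0("S", nxt))))))
}

ring_signatures <- function(k, stages = paste0("S", seq_len(k))) {
  a <- max(1L, floor(k / 3)); b <- max(a + 1L, floor(2 * k / 3))
  or_of <- function(idx) do.call(expr_or, lapply(stages[idx], expr_ge))
  list(G1 = expr_and(or_of(1:a), expr_not(expr_ge(stages[a + 1L]))),
       S_G2 = expr_and(or_of((a + 1L):b), expr_not(expr_ge(stages[b + 1L]))),
       M = expr_and(or_of((b + 1L):k), expr_not(expr_ge(stages[1L]))))
}

toy_ring <- function(k, arrest = FALSE) {
  if (k < 6L) stop("ring toys need size >= 6", call. = FALSE)
  stages <- paste0("S", seq_len(k))
  nodes <- data.frame(
    name = c(stages, if (arrest) "GO", "CYT", "MASS"),
    max_level = c(rep(1L, k), if (arrest) 1L, 2L, 2L),
    role = c(rep("state-variable", k + arrest), "event-marker",
             "event-marker"))
  toy_state_bound(nodes$max_level + 1L,
                  if (arrest) "arrester" else "ring-oscillator")
  rules <- lapply(seq_len(k), function(i)
    ring_stage_rule(i, k, gate = if (arrest && i == 2L) list(expr_ge("GO"))))
  mass1 <- expr_or(expr_ge(stages[k - 1L]), expr_ge(stages[k]),
                   expr_ge("S1"), expr_ge("S2"))
  rules <- c(rules, list(
    list(target = "CYT", target_level = 2L,
         expr = expr_or(expr_ge(stages[k - 3L]), expr_ge(stages[k - 2L]))),
    list(target = "MASS", target_level = 2L, expr = expr_not(mass1)),
    list(target = "MASS", target_level = 1L, expr = mass1)))
  start <- stats::setNames(rep(0L, nrow(nodes)), nodes$name)
  if (arrest) {
    start["S1"] <- 1L   # the arrested fixed point: the gate never opens
  } else {
    start[c(stages[k], "S1")] <- 1L
  }
  start["MASS"] <- 1L
  model_definition(
    nodes, rules, ring_signatures(k),
    start_state = start,
    event_nodes = list(cytokinesis = "CYT", mass = "MASS",
                       cytokinesis_level = 2L),
    name = if (arrest) "toy-arrester" else "toy-ring")
}

toy_paced <- function(k) {
  if (k < 4L) stop("paced toys need size >= 4", call. = FALSE)
  n <- 2L * k
  stages <- paste0("S", seq_len(n))
  nodes <- data.frame(
    name = c(stages, "PACE", "PACED", "CYT", "MASS"),
    max_level = c(rep(1L, n), 1L, 1L, 2L, 2L),
    role = c(rep("state-variable", n), "gene", "state-variable",
             "event-marker", "event-marker"))
  rules <- lapply(seq_len(n), function(i) ring_stage_rule(i, n))
  sk <- paste0("S", k); sk1 <- paste0("S", k + 1L)
  ## shortcut: after stage k the token jumps back to S1 when the pacing
  ## signal was read active, else continues the long way round
  rules[[1L]]$expr <- expr_or(
    expr_and(expr_ge(stages[n]), expr_not(expr_ge("S1"))),
    expr_and(expr_ge(sk), expr_ge("PACED"), expr_not(expr_ge("S1")),
             expr_not(expr_ge(sk1))),
    expr_and(expr_ge("S1"), expr_not(expr_ge("S2"))))
  rules[[k + 1L]]$expr <- expr_or(
    expr_and(expr_ge(sk), expr_not(expr_ge("PACED")),
             expr_not(expr_ge(sk1)), expr_not(expr_ge("S1"))),
    expr_and(expr_ge(sk1), expr_not(expr_ge(paste0("S", k + 2L)))))
  ## stage k hands over to either successor
  rules[[k]]$expr <- expr_or(
    expr_and(expr_ge(paste0("S", k - 1L)), expr_not(expr_ge(sk))),
    expr_and(expr_ge(sk), expr_not(expr_ge(sk1)), expr_not(expr_ge("S1"))))
  mass1 <- expr_or(expr_ge(paste0("S", k - 1L)), expr_ge(sk), expr_ge("S1"))
  rules <- c(rules, list(
    list(target = "PACE", target_level = 1L, expr = expr_ge("PACE", 0L)),
    list(target = "PACED", target_level = 1L, expr = expr_ge("PACE")),
    list(target = "CYT", target_level = 2L,
         expr = expr_or(expr_ge("S1"), expr_ge("S2"))),
    list(target = "MASS", target_level = 2L, expr = expr_not(mass1)),
    list(target = "MASS", target_level = 1L, expr = mass1)))
  ## phase boundaries chosen so the fast-path handover pair {S_k, S1} is
  ## classified unambiguously (S_k opens M, S1 opens G1)
  or_of <- function(idx) do.call(expr_or, lapply(stages[idx], expr_ge))
  sigs <- list(
    G1 = expr_and(or_of(1:2), expr_not(expr_ge("S3"))),
    S_G2 = expr_and(or_of(3:(k - 1L)), expr_not(expr_ge(sk))),
    M = expr_and(or_of(k:n), expr_not(expr_ge("S1"))))
  ## START sits on the fast cycle: the handover pair {S_k, S1}
  start <- stats::setNames(rep(0L, nrow(nodes)), nodes$name)
  start[c(sk, "S1", "PACE", "PACED")] <- 1L
  start["MASS"] <- 1L
  model_definition(
    nodes, rules, sigs,
    start_state = start,
    event_nodes = list(cytokinesis = "CYT", mass = "MASS",
                       cytokinesis_level = 2L),
    name = "toy-paced")
}
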