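#' Exact Markov chain of a dosed logical model
#'
#' Enumerates the full state space of a (small) model and, for each state,
#' the exact one-step transition distribution under the dosage semantics:
#' every stochastic occurrence of a dosed node across the rules of a target
#' (an occurrence whose current read value is positive) is enumerated
#' jointly, the rules are evaluated for each joint outcome, and the
#' outcome-level reset of dosed targets is applied analytically. Because
#' occurrence draws are independent across target nodes, the transition
#' distribution factorises over targets and the row distribution is their
#' product. This is the ground-truth validator for the Monte-Carlo engine:
#' at `d = 1` the matrix is the deterministic synchronous step map; at
#' intermediate dosages engine occupancies must agree within Monte-Carlo
#' error.
#'
#' @param model A `logicyc_model` whose active state space has at most
#'   `max_states` states.
#' @param dosage A `logicyc_dosage`.
#' @param max_states State-space bound (default 4096); beyond it exact
#'   enumeration is refused and Monte-Carlo simulation is advised.
#' @param max_occurrences Per-target cap on jointly enumerated stochastic
#'   occurrences (default 16, i.e. 65536 joint outcomes).
#' @return A `logicyc_chain`: `states` (matrix, one row per state),
#'   `P` (sparse row-stochastic transition matrix), `model`, `dosage`.
#' @export
build_chain <- function(model, dosage = dosage_spec(), max_states = 4096L,
                        max_occurrences = 16L) {
  dosage <- as_dosage(dosage)
  act <- active_nodes(model)
  card <- act$max_level + 1L
  n_states <- prod(card)
  if (n_states > max_states)
    stop("state space has ", n_states, " states (> ", max_states,
         "); exact enumeration refused - use Monte-Carlo simulation instead",
         call. = FALSE)
  nm <- act$name
  dfrac <- stats::setNames(rep(1, nrow(act)), nm)
  if (length(dosage$fractions)) {
    miss <- setdiff(names(dosage$fractions), nm)
    if (length(miss))
      stop("dosed gene(s) not in the active model: ",
           paste(miss, collapse = ", "), call. = FALSE)
    dfrac[names(dosage$fractions)] <- dosage$fractions
  }
  dosed <- nm[dfrac < 1]

  ## mixed-radix enumeration of all states (first node varies fastest)
  states <- as.matrix(expand.grid(lapply(card, function(k) 0:(k - 1L)),
                                  KEEP.OUT.ATTRS = FALSE))
  colnames(states) <- nm
  radix <- cumprod(c(1L, card[-length(card)]))
  state_index <- function(st) 1L + sum(st * radix)  # st over nm, 0-based levels

  rbt <- rules_by_target(active_rules(model))
  ip <- jp <- integer(0); xp <- numeric(0)

  for (s in seq_len(n_states)) {
    st <- stats::setNames(states[s, ], nm)
    ## per-target next-level distributions
    dists <- vector("list", length(nm))
    for (v in seq_along(nm)) {
      target <- nm[v]
      rules <- rbt[[target]]
      if (is.null(rules)) { dists[[v]] <- c("0" = 1); next }
      ## stochastic occurrences of dosed nodes across this target's rules
      occ_n <- sum(vapply(rules, function(r)
        count_occurrences(r$expr, st, dosed), integer(1L)))
      if (occ_n > max_occurrences)
        stop("target \"", target, "\" has ", occ_n, " stochastic occurrences",
             " (> ", max_occurrences, "); exact enumeration refused",
             call. = FALSE)
      prop_dist <- new.env(parent = emptyenv())
      add_p <- function(env, level, p) {
        k <- as.character(level)
        assign(k, p + (if (exists(k, env)) get(k, env) else 0), envir = env)
      }
      eval_prop <- function(occ_values, p) {
        ## which occurrence reads its true value vs 0, in DFS order
        occ <- new.env(parent = emptyenv())
        occ$nodes <- dosed; occ$i <- 0L
        prob <- p
        ## walk rules, drawing from occ_values as occurrence slots are met
        occ$values <- occ_values
        proposed <- 0L
        for (r in rules) {
          if (eval_expr_occ(r$expr, st, occ)) { proposed <- r$target_level; break }
        }
        ## note: occurrences in rules after the first satisfied one are not
        ## consumed; their joint outcomes are marginalised by construction
        ## because eval does not depend on them
        add_p(prop_dist, proposed, prob)
      }
      if (occ_n == 0L) {
        eval_prop(integer(0), 1)
      } else {
        ## enumerate joint outcomes; occurrence k belongs to a specific leaf
        ## whose true read value and dosage we recover by a collection pass
        occ_meta <- collect_occ_meta(rules, st, dosed, dfrac)
        for (mask in 0:(2^occ_n - 1L)) {
          keep <- bitwAnd(mask, 2^(seq_len(occ_n) - 1L)) > 0L
          vals <- ifelse(keep, occ_meta$value, 0L)
          p <- prod(ifelse(keep, occ_meta$d, 1 - occ_meta$d))
          eval_prop(as.integer(vals), p)
        }
      }
      ## outcome-level reset for dosed targets
      dist <- unlist(as.list(prop_dist))
      lv <- as.integer(names(dist))
      if (dfrac[[target]] < 1) {
        dv <- dfrac[[target]]
        pos <- lv > 0L
        zero_extra <- sum(dist[pos]) * (1 - dv)
        dist[pos] <- dist[pos] * dv
        dist["0"] <- (if ("0" %in% names(dist)) dist[["0"]] else 0) + zero_extra
      }
      dist <- dist[dist > 0]
      dists[[v]] <- dist
    }
    ## product over targets -> joint next-state distribution
    combos <- data.frame(p = 1)
    nxt <- matrix(0L, nrow = 1L, ncol = length(nm))
    for (v in seq_along(nm)) {
      dist <- dists[[v]]
      k <- length(dist)
      n0 <- nrow(nxt)
      nxt <- nxt[rep(seq_len(n0), times = k), , drop = FALSE]
      nxt[, v] <- rep(as.integer(names(dist)), each = n0)
      combos <- data.frame(p = rep(combos$p, times = k) *
                             rep(unname(dist), each = n0))
    }
    for (r in seq_len(nrow(nxt))) {
      ip <- c(ip, s)
      jp <- c(jp, 1L + sum(nxt[r, ] * radix))
      xp <- c(xp, combos$p[r])
    }
  }
  P <- Matrix::sparseMatrix(i = ip, j = jp, x = xp,
                            dims = c(n_states, n_states))
  structure(list(states = states, P = P, card = card, radix = radix,
                 model = model, dosage = dosage, node_names = nm),
            class = "logicyc_chain")
}

## metadata for each stochastic occurrence (DFS order across a target's
## rules): the node's current value and its dosage fraction
collect_occ_meta <- function(rules, st, dosed, dfrac) {
  value <- integer(0); d <- numeric(0)
  walk <- function(expr) {
    op <- expr_op(expr)
    if (op %in% c("GE", "EQ")) {
      nm <- expr[[2L]]
      v <- st[[nm]]
      if (is.null(v)) v <- 0L
      if (nm %in% dosed && v > 0L) {
        value <<- c(value, v); d <<- c(d, dfrac[[nm]])
      }
      return(invisible(NULL))
    }
    if (op == "NOT") return(walk(expr[[2L]]))
    for (sub in expr[-1L]) walk(sub)
  }
  for (r in rules) walk(r$expr)
  list(value = value, d = d)
}

#' @export
print.logicyc_chain <- function(x, ...) {
  cat("exact chain over", nrow(x$states), "states,",
      length(x$P@x), "nonzero transitions\n")
  invisible(x)
}

#' State index within a chain
#'
#' @param chain A `logicyc_chain`.
#' @param state Named integer vector over the chain's nodes.
#' @return 1-based row index into the chain's state enumeration.
#' @export
chain_state_index <- function(chain, state) {
  st <- as.integer(state[chain$node_names])
  as.integer(1L + sum(st * chain$radix))
}

#' Exact transient occupancy
#'
#' Expected per-state visit fractions over `n_steps` synchronous updates
#' from `start`, by iterated application of the transition matrix. The
#' average is taken over the states *after* each of the `n_steps` updates
#' (the start state itself is not counted), matching the Monte-Carlo
#' engine's occupancy convention.
#'
#' @param chain A `logicyc_chain`.
#' @param start Named start state (defaults to the model's START state).
#' @param n_steps Number of updates.
#' @return Numeric vector of expected visit fractions (sums to 1).
#' @export
transient_occupancy <- function(chain, start = NULL, n_steps = 100L) {
  if (is.null(start)) start <- active_start_state(chain$model)
  p <- numeric(nrow(chain$states))
  p[chain_state_index(chain, start)] <- 1
  acc <- numeric(length(p))
  for (t in seq_len(n_steps)) {
    p <- as.numeric(p %*% chain$P)
    acc <- acc + p
  }
  acc / n_steps
}

#' Exact phase occupancy from a chain
#'
#' Sums a per-state occupancy vector over the states matching each phase
#' signature (fractions over classified states, plus the unclassified
#' fraction of all steps, matching [phase_profile()]).
#'
#' @param chain A `logicyc_chain`.
#' @param occupancy Vector from [transient_occupancy()].
#' @return Named vector `G1`, `S_G2`, `M`, `unclassified`.
#' @export
oracle_phase_occupancy <- function(chain, occupancy) {
  ## classify only states actually visited; signatures need not partition
  ## the unreachable corners of the state space
  visited <- which(occupancy > 0)
  phase <- vapply(visited, function(i)
    classify_phase(stats::setNames(as.integer(chain$states[i, ]),
                                   chain$node_names), chain$model),
    character(1L))
  out <- c(G1 = sum(occupancy[visited[phase == "G1"]]),
           S_G2 = sum(occupancy[visited[phase == "S_G2"]]),
           M = sum(occupancy[visited[phase == "M"]]),
           unclassified = sum(occupancy[visited[phase == "unclassified"]]))
  cls <- sum(out[c("G1", "S_G2", "M")])
  if (cls > 0) out[c("G1", "S_G2", "M")] <- out[c("G1", "S_G2", "M")] / cls
  out
}
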