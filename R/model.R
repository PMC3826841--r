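#' Construct a logical model definition
#'
#' A model is a multi-valued logical network: nodes with integer levels
#' `0..max_level`, one update rule per (target, level) whose expression is
#' evaluated against the previous full state (synchronous updating), phase
#' signatures classifying states into G1 / S_G2 / M, a designated START
#' state, designated event nodes (cytokinesis and mass), and optional named
#' module blocks that can be toggled on or off.
#'
#' Update semantics for a multi-valued node: its rules are evaluated in
#' descending `target_level` order and the first satisfied rule sets the next
#' level; if no rule is satisfied the next level is 0. Nodes belonging to a
#' disabled module are held at 0 and references to them read 0.
#'
#' @param nodes Data frame with columns `name`, `max_level`, `role`
#'   (`"gene"`, `"state-variable"` or `"event-marker"`).
#' @param rules List of rules, each `list(target=, target_level=, expr=)`.
#' @param signatures Named list with elements `G1`, `S_G2`, `M`, each an
#'   expression tree (see [expr_and()]).
#' @param start_state Named integer vector assigning a level to every core
#'   node: the START state used as initial condition and cycle delimiter.
#' @param event_nodes `list(cytokinesis=, mass=, cytokinesis_level=)`.
#' @param modules Named list of module blocks, each
#'   `list(nodes=, rules=, enabled=)` (`nodes` as above, possibly empty).
#' @param name Optional model name.
#' @param validate Run [validate_model()] (including the wild-type dynamics
#'   checks) before returning.
#' @return An object of class `logicyc_model`.
#' @seealso [parse_model()], [yeast_model()], [make_toy_model()]
#' @export
model_definition <- function(nodes, rules, signatures, start_state,
                             event_nodes, modules = list(), name = "model",
                             validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$max_level <- as.integer(nodes$max_level)
  rules <- lapply(rules, function(r) {
    list(target = r$target, target_level = as.integer(r$target_level),
         expr = r$expr)
  })
  model <- structure(
    list(name = name, nodes = nodes, rules = rules, signatures = signatures,
         start_state = vapply(start_state, as.integer, integer(1L)),
         event_nodes = event_nodes, modules = modules),
    class = "logicyc_model")
  model$rules <- order_rules(model$rules)
  for (m in names(model$modules))
    model$modules[[m]]$rules <- order_rules(model$modules[[m]]$rules)
  if (validate) validate_model(model)
  model
}

order_rules <- function(rules) {
  if (length(rules) == 0L) return(rules)
  ord <- order(vapply(rules, `[[`, character(1L), "target"),
               -vapply(rules, `[[`, integer(1L), "target_level"))
  rules[ord]
}

#' @export
print.logicyc_model <- function(x, ...) {
  act <- active_nodes(x)
  cat("logicyc model \"", x$name, "\": ", nrow(act), " active nodes, ",
      length(active_rules(x)), " rules\n", sep = "")
  if (length(x$modules)) {
    on <- vapply(x$modules, `[[`, logical(1L), "enabled")
    cat("modules:", paste0(names(x$modules), ifelse(on, " [on]", " [off]"),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Active nodes and rules of a model
#'
#' Core nodes/rules plus those of enabled modules.
#'
#' @param model A `logicyc_model`.
#' @return `active_nodes()`: data frame of nodes; `active_rules()`: list of
#'   rules.
#' @export
active_nodes <- function(model) {
  out <- model$nodes
  for (m in model$modules)
    if (isTRUE(m$enabled) && !is.null(m$nodes) && NROW(m$nodes) > 0L)
      out <- rbind(out, as.data.frame(m$nodes, stringsAsFactors = FALSE))
  out
}

#' @rdname active_nodes
#' @export
active_rules <- function(model) {
  out <- model$rules
  for (m in model$modules)
    if (isTRUE(m$enabled) && length(m$rules)) out <- c(out, m$rules)
  out
}

## All declared nodes (core + every module, enabled or not).
declared_nodes <- function(model) {
  out <- model$nodes
  for (m in model$modules)
    if (!is.null(m$nodes) && NROW(m$nodes) > 0L)
      out <- rbind(out, as.data.frame(m$nodes, stringsAsFactors = FALSE))
  out
}

## Full start state over the active node set (module nodes start at 0
## unless the model's start_state names them).
active_start_state <- function(model) {
  act <- active_nodes(model)
  st <- stats::setNames(integer(nrow(act)), act$name)
  common <- intersect(names(model$start_state), names(st))
  st[common] <- model$start_state[common]
  st
}

## One deterministic synchronous step (reference semantics, no dosage).
## rules_by_target: list keyed by target of rules in descending level order.
step_state_r <- function(state, rules_by_target) {
  nxt <- state
  nxt[] <- 0L
  for (nm in names(rules_by_target)) {
    for (r in rules_by_target[[nm]]) {
      if (eval_expr(r$expr, state)) {
        nxt[[nm]] <- r$target_level
        break
      }
    }
  }
  nxt
}

rules_by_target <- function(rules) {
  split(rules, vapply(rules, `[[`, character(1L), "target"))
}

#' Validate a model definition
#'
#' Checks the structural invariants (unique node names, levels in range,
#' resolvable references, at most one rule per (target, level), event nodes
#' present) and, when `check_dynamics = TRUE`, the wild-type dynamics
#' invariants: simulation from the START state with all dosages at 1 must be
#' periodic (return to START within `max_period` steps), and on every step
#' of that cycle exactly one phase signature must match.
#'
#' @param model A `logicyc_model`.
#' @param check_dynamics Verify WT periodicity and the phase partition.
#' @param max_period Step cap when searching for the periodic return.
#' @return The model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model, check_dynamics = TRUE, max_period = 4096L) {
  nodes <- declared_nodes(model)
  if (anyDuplicated(nodes$name))
    stop("duplicate node name: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "),
         call. = FALSE)
  if (any(nodes$max_level < 1L))
    stop("max_level must be >= 1 (node ",
         nodes$name[which(nodes$max_level < 1L)[1L]], ")", call. = FALSE)
  bad_role <- setdiff(unique(nodes$role), c("gene", "state-variable", "event-marker"))
  if (length(bad_role))
    stop("unknown node role: ", paste(bad_role, collapse = ", "), call. = FALSE)
  node_max <- stats::setNames(nodes$max_level, nodes$name)

  all_rules <- c(model$rules, unlist(lapply(model$modules, `[[`, "rules"),
                                     recursive = FALSE))
  keys <- character(0)
  for (r in all_rules) {
    if (!r$target %in% nodes$name)
      stop("rule targets undeclared node \"", r$target, "\"", call. = FALSE)
    if (r$target_level < 1L || r$target_level > node_max[[r$target]])
      stop("rule for \"", r$target, "\": target_level ", r$target_level,
           " outside [1, ", node_max[[r$target]], "]", call. = FALSE)
    key <- paste0(r$target, "=", r$target_level)
    check_expr(r$expr, node_max, paste0("rule ", key))
    keys <- c(keys, key)
  }
  ## duplicate (target, level) only matters among simultaneously active rules
  act_keys <- vapply(active_rules(model), function(r)
    paste0(r$target, "=", r$target_level), character(1L))
  if (anyDuplicated(act_keys))
    stop("more than one active rule for ",
         paste(unique(act_keys[duplicated(act_keys)]), collapse = ", "),
         call. = FALSE)

  if (!all(c("G1", "S_G2", "M") %in% names(model$signatures)))
    stop("signatures must define G1, S_G2 and M", call. = FALSE)
  for (ph in names(model$signatures))
    check_expr(model$signatures[[ph]], node_max, paste0("signature ", ph))

  ev <- model$event_nodes
  for (f in c("cytokinesis", "mass"))
    if (!ev[[f]] %in% nodes$name)
      stop("event node \"", ev[[f]], "\" not declared", call. = FALSE)
  if (ev$cytokinesis_level > node_max[[ev$cytokinesis]] || ev$cytokinesis_level < 1L)
    stop("cytokinesis completion level ", ev$cytokinesis_level,
         " exceeds max_level of node \"", ev$cytokinesis, "\"", call. = FALSE)

  act <- active_nodes(model)
  missing_start <- setdiff(setdiff(act$name, names(model$start_state)),
                           unlist(lapply(model$modules, function(m)
                             if (NROW(m$nodes)) m$nodes$name else character(0))))
  if (length(missing_start))
    stop("start_state missing node(s): ",
         paste(missing_start, collapse = ", "), call. = FALSE)

  if (check_dynamics) {
    rbt <- rules_by_target(active_rules(model))
    st <- active_start_state(model)
    traj <- list(st)
    period <- NA_integer_
    cur <- st
    for (t in seq_len(max_period)) {
      cur <- step_state_r(cur, rbt)
      traj[[t + 1L]] <- cur
      if (identical(unname(cur[names(st)]), unname(st))) { period <- t; break }
    }
    if (is.na(period))
      stop("unperturbed simulation from start_state did not return to ",
           "start_state within ", max_period, " steps", call. = FALSE)
    for (t in seq_len(period)) {
      matches <- names(model$signatures)[vapply(model$signatures, eval_expr,
                                                logical(1L), state = traj[[t]])]
      if (length(matches) != 1L)
        stop("phase signatures not a partition on the WT cycle: step ", t - 1L,
             " matches {", paste(matches, collapse = ", "), "}", call. = FALSE)
    }
    attr(model, "wt_period") <- period
  }
  invisible(model)
}

#' Toggle an optional module block
#'
#' Enabled modules contribute their nodes and rules to the dynamics;
#' disabled module nodes are held at 0 (references to them read 0) and are
#' excluded from the active node set.
#'
#' @param model A `logicyc_model`.
#' @param name Module name.
#' @param on Logical flag.
#' @return The modified model.
#' @export
toggle_module <- function(model, name, on) {
  if (!name %in% names(model$modules))
    stop("unknown module \"", name, "\"; available: ",
         if (length(model$modules)) paste(names(model$modules), collapse = ", ")
         else "(none)", call. = FALSE)
  model$modules[[name]]$enabled <- isTRUE(on)
  validate_model(model, check_dynamics = FALSE)
  model
}

expr_to_json <- function(expr) expr  # nested lists serialise as nested arrays

json_to_expr <- function(x) {
  if (!is.list(x)) stop("malformed expression in model file", call. = FALSE)
  op <- x[[1L]]
  if (op %in% c("GE", "EQ")) return(list(op, x[[2L]], as.integer(x[[3L]])))
  c(list(op), lapply(x[-1L], json_to_expr))
}

#' Read a model definition from JSON
#'
#' The file format has top-level keys `name`, `nodes`, `rules` (expressions
#' as nested arrays with operators `AND`/`OR`/`NOT` and leaves
#' `["GE"|"EQ", node, level]`), `signatures`, `start_state`, `event_nodes`
#' and `modules`. The parsed model is validated, including the wild-type
#' periodicity and phase-partition checks.
#'
#' @param path Path to a model JSON file.
#' @param validate Validate after parsing (default `TRUE`).
#' @return A `logicyc_model`.
#' @seealso [write_model()]
#' @export
parse_model <- function(path, validate = TRUE) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  parse_nodes <- function(lst)
    data.frame(name = vapply(lst, `[[`, character(1L), "name"),
               max_level = vapply(lst, function(n) as.integer(n$max_level), integer(1L)),
               role = vapply(lst, `[[`, character(1L), "role"),
               stringsAsFactors = FALSE)
  parse_rules <- function(lst)
    lapply(lst, function(r) list(target = r$target,
                                 target_level = as.integer(r$target_level),
                                 expr = json_to_expr(r$expr)))
  modules <- lapply(j$modules, function(m)
    list(nodes = if (length(m$nodes)) parse_nodes(m$nodes)
                 else data.frame(name = character(0), max_level = integer(0),
                                 role = character(0)),
         rules = parse_rules(m$rules),
         enabled = isTRUE(m$enabled)))
  model_definition(
    nodes = parse_nodes(j$nodes),
    rules = parse_rules(j$rules),
    signatures = lapply(j$signatures, json_to_expr),
    start_state = unlist(j$start_state),
    event_nodes = list(cytokinesis = j$event_nodes$cytokinesis,
                       mass = j$event_nodes$mass,
                       cytokinesis_level = as.integer(j$event_nodes$cytokinesis_level)),
    modules = modules,
    name = if (is.null(j$name)) "model" else j$name,
    validate = validate)
}

#' Write a model definition to canonical JSON
#'
#' Emits keys and list elements in a fixed order so that two writes of the
#' same model are byte-identical and files are diff-able.
#'
#' @param model A `logicyc_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  fmt_nodes <- function(df)
    lapply(seq_len(NROW(df)), function(i)
      list(name = df$name[i], max_level = df$max_level[i], role = df$role[i]))
  fmt_rules <- function(rules)
    lapply(rules, function(r) list(target = r$target,
                                   target_level = r$target_level,
                                   expr = expr_to_json(r$expr)))
  out <- list(
    name = model$name,
    nodes = fmt_nodes(model$nodes),
    rules = fmt_rules(model$rules),
    signatures = model$signatures[c("G1", "S_G2", "M")],
    start_state = as.list(model$start_state),
    event_nodes = model$event_nodes[c("cytokinesis", "mass", "cytokinesis_level")],
    modules = lapply(model$modules, function(m)
      list(nodes = fmt_nodes(m$nodes), rules = fmt_rules(m$rules),
           enabled = isTRUE(m$enabled)))
  )
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = 2L, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Deterministic wild-type trajectory and period
#'
#' Simulates the unperturbed model from START with the reference R evaluator
#' until it returns to START.
#'
#' @param model A `logicyc_model`.
#' @param max_period Step cap.
#' @return List with `period` and `states` (list of named vectors, START
#'   first, length `period + 1`).
#' @export
wt_cycle <- function(model, max_period = 4096L) {
  rbt <- rules_by_target(active_rules(model))
  st <- active_start_state(model)
  states <- list(st)
  cur <- st
  for (t in seq_len(max_period)) {
    cur <- step_state_r(cur, rbt)
    states[[t + 1L]] <- cur
    if (identical(unname(cur[names(st)]), unname(st)))
      return(list(period = t, states = states))
  }
  stop("no return to start_state within ", max_period, " steps", call. = FALSE)
}
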