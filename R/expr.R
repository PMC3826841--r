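#' Logical expression constructors
#'
#' Update rules and phase signatures are logical expression trees. Leaves are
#' threshold comparisons on node levels; internal operators are `AND`, `OR`
#' and `NOT`. Expressions are stored as nested lists (serialised to nested
#' JSON arrays by [write_model()]), e.g.
#' `expr_and(expr_ge("CLN1"), expr_not(expr_eq("SIC1", 1)))`.
#'
#' @param node Node name referenced by a leaf.
#' @param level Integer threshold (`GE`: node value >= level; `EQ`: equal).
#' @param ... Sub-expressions.
#' @param x Sub-expression to negate.
#' @return An expression tree (nested list).
#' @examples
#' expr_or(expr_ge("CLB2", 2), expr_and(expr_ge("CLB1"), expr_not(expr_ge("SIC1"))))
#' @name expr
NULL

#' @rdname expr
#' @export
expr_ge <- function(node, level = 1L) list("GE", node, as.integer(level))

#' @rdname expr
#' @export
expr_eq <- function(node, level) list("EQ", node, as.integer(level))

#' @rdname expr
#' @export
expr_and <- function(...) c(list("AND"), list(...))

#' @rdname expr
#' @export
expr_or <- function(...) c(list("OR"), list(...))

#' @rdname expr
#' @export
expr_not <- function(x) list("NOT", x)

## read a node level from a named state vector; absent nodes (e.g. nodes of
## a disabled module) read 0
node_value <- function(state, nm) {
  i <- match(nm, names(state))
  if (is.na(i)) 0L else state[[i]]
}

expr_op <- function(expr) {
  if (!is.list(expr) || length(expr) < 2L || !is.character(expr[[1L]]))
    stop("malformed expression: ", deparse(expr, nlines = 1L), call. = FALSE)
  expr[[1L]]
}

is_leaf_expr <- function(expr) expr_op(expr) %in% c("GE", "EQ")

#' Evaluate an expression deterministically
#'
#' Reads node values from `state`; nodes absent from `state` (e.g. nodes of a
#' disabled module) read as 0. This evaluator performs no dosage sampling; it
#' is the reference semantics used by the model validator and the exact
#' oracle, independent of the compiled simulation engine.
#'
#' @param expr Expression tree.
#' @param state Named integer vector of node levels.
#' @return `TRUE` or `FALSE`.
#' @keywords internal
eval_expr <- function(expr, state) {
  op <- expr_op(expr)
  switch(op,
    GE = node_value(state, expr[[2L]]) >= expr[[3L]],
    EQ = node_value(state, expr[[2L]]) == expr[[3L]],
    NOT = !eval_expr(expr[[2L]], state),
    AND = all(vapply(expr[-1L], eval_expr, logical(1L), state = state)),
    OR  = any(vapply(expr[-1L], eval_expr, logical(1L), state = state)),
    stop("unknown expression operator: ", op, call. = FALSE)
  )
}

## eval_expr where leaf reads of selected nodes are replaced, occurrence by
## occurrence, with pre-drawn values (used by the exact oracle to enumerate
## joint occurrence outcomes). `occ` is an environment with fields:
##   nodes  - character vector of dosed node names
##   values - integer vector, the value each stochastic occurrence reads
##   i      - next occurrence index (mutated during the walk)
## Occurrences are numbered in depth-first, left-to-right order, matching
## collect_occurrences().
eval_expr_occ <- function(expr, state, occ) {
  op <- expr_op(expr)
  if (op %in% c("GE", "EQ")) {
    nm <- expr[[2L]]
    v <- node_value(state, nm)
    if (nm %in% occ$nodes && v > 0L) {
      occ$i <- occ$i + 1L
      v <- occ$values[[occ$i]]
    }
    return(if (op == "GE") v >= expr[[3L]] else v == expr[[3L]])
  }
  switch(op,
    NOT = !eval_expr_occ(expr[[2L]], state, occ),
    AND = all(vapply(expr[-1L], eval_expr_occ, logical(1L), state = state, occ = occ)),
    OR  = any(vapply(expr[-1L], eval_expr_occ, logical(1L), state = state, occ = occ))
  )
}

## Count stochastic occurrences of `nodes` in `expr` given `state`: an
## occurrence is stochastic only when the referenced node's current value is
## positive (a zero value reads zero whether or not it is resampled).
count_occurrences <- function(expr, state, nodes) {
  op <- expr_op(expr)
  if (op %in% c("GE", "EQ")) {
    nm <- expr[[2L]]
    return(as.integer(nm %in% nodes && node_value(state, nm) > 0L))
  }
  if (op == "NOT") return(count_occurrences(expr[[2L]], state, nodes))
  sum(vapply(expr[-1L], count_occurrences, integer(1L), state = state, nodes = nodes))
}

## All node names referenced anywhere in an expression.
expr_nodes <- function(expr) {
  op <- expr_op(expr)
  if (op %in% c("GE", "EQ")) return(expr[[2L]])
  if (op == "NOT") return(expr_nodes(expr[[2L]]))
  unique(unlist(lapply(expr[-1L], expr_nodes)))
}

## Structural validation of an expression against a node table.
## `where` names the rule/signature for error messages.
check_expr <- function(expr, node_max, where) {
  op <- expr_op(expr)
  if (op %in% c("GE", "EQ")) {
    if (length(expr) != 3L)
      stop(where, ": leaf must be [op, node, level]", call. = FALSE)
    nm <- expr[[2L]]
    if (!nm %in% names(node_max))
      stop(where, ": reference to undeclared node \"", nm, "\"", call. = FALSE)
    lv <- expr[[3L]]
    if (!is.numeric(lv) || lv != as.integer(lv) || lv < 0L || lv > node_max[[nm]])
      stop(where, ": level ", lv, " out of range [0, ", node_max[[nm]],
           "] for node \"", nm, "\"", call. = FALSE)
    return(invisible(TRUE))
  }
  if (op == "NOT") {
    if (length(expr) != 2L) stop(where, ": NOT takes one operand", call. = FALSE)
    return(check_expr(expr[[2L]], node_max, where))
  }
  if (!op %in% c("AND", "OR"))
    stop(where, ": unknown operator \"", op, "\"", call. = FALSE)
  if (length(expr) < 2L)
    stop(where, ": ", op, " needs at least one operand", call. = FALSE)
  for (sub in expr[-1L]) check_expr(sub, node_max, where)
  invisible(TRUE)
}
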