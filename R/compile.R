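## Compile a model's active rules and signatures to the flat postfix
## bytecode consumed by the C++ engine. Instructions are triplets
## (op, a, b): GE/EQ push a leaf comparison of node a (0-based) against
## level b; NOT negates; AND/OR pop a operands. References to nodes of
## disabled modules compile to constants (their value is 0 by definition):
## an empty AND pushes TRUE, an empty OR pushes FALSE.

OPC <- c(GE = 0L, EQ = 1L, NOT = 2L, AND = 3L, OR = 4L)

compile_expr <- function(expr, node_index, node_max) {
  op <- expr_op(expr)
  if (op %in% c("GE", "EQ")) {
    nm <- expr[[2L]]
    lv <- as.integer(expr[[3L]])
    idx <- node_index[[nm]]
    if (is.null(idx)) {  # inactive module node: reads 0
      truth <- if (op == "GE") 0L >= lv else 0L == lv
      return(c(if (truth) OPC[["AND"]] else OPC[["OR"]], 0L, 0L))
    }
    return(c(OPC[[op]], idx, lv))
  }
  if (op == "NOT")
    return(c(compile_expr(expr[[2L]], node_index, node_max),
             OPC[["NOT"]], 0L, 0L))
  kids <- expr[-1L]
  c(unlist(lapply(kids, compile_expr, node_index = node_index,
                  node_max = node_max)),
    OPC[[op]], length(kids), 0L)
}

compile_model <- function(model) {
  act <- active_nodes(model)
  node_index <- as.list(stats::setNames(seq_len(nrow(act)) - 1L, act$name))
  node_max <- stats::setNames(act$max_level, act$name)

  rules <- active_rules(model)
  ## group rules by target in node order, descending level within target
  tg <- vapply(rules, `[[`, character(1L), "target")
  lv <- vapply(rules, `[[`, integer(1L), "target_level")
  ord <- order(match(tg, act$name), -lv)
  rules <- rules[ord]
  tg <- tg[ord]

  code <- integer(0)
  rule_code_start <- rule_code_len <- rule_target <- rule_level <- integer(length(rules))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    rc <- compile_expr(r$expr, node_index, node_max)
    rule_code_start[i] <- length(code) / 3L
    rule_code_len[i] <- length(rc) / 3L
    rule_target[i] <- node_index[[r$target]]
    rule_level[i] <- r$target_level
    code <- c(code, rc)
  }
  node_rule_start <- node_rule_count <- integer(nrow(act))
  for (v in seq_len(nrow(act))) {
    hit <- which(tg == act$name[v])
    node_rule_start[v] <- if (length(hit)) hit[1L] - 1L else 0L
    node_rule_count[v] <- length(hit)
  }

  sig_start <- sig_len <- integer(3L)
  for (s in seq_along(c("G1", "S_G2", "M"))) {
    ph <- c("G1", "S_G2", "M")[s]
    sc <- compile_expr(model$signatures[[ph]], node_index, node_max)
    sig_start[s] <- length(code) / 3L
    sig_len[s] <- length(sc) / 3L
    code <- c(code, sc)
  }

  ev <- model$event_nodes
  list(n_nodes = nrow(act), node_names = act$name, node_max = unname(node_max),
       code = code,
       rule_target = rule_target, rule_level = rule_level,
       rule_code_start = rule_code_start, rule_code_len = rule_code_len,
       node_rule_start = node_rule_start, node_rule_count = node_rule_count,
       sig_start = sig_start, sig_len = sig_len,
       cyt = node_index[[ev$cytokinesis]], mass = node_index[[ev$mass]],
       cyt_level = as.integer(ev$cytokinesis_level))
}

## Per-active-node dosage fraction vector (1 = undosed).
dose_vector <- function(model, dosage) {
  dosage <- as_dosage(dosage)
  act <- active_nodes(model)
  d <- rep(1, nrow(act))
  if (length(dosage$fractions)) {
    miss <- setdiff(names(dosage$fractions), act$name)
    if (length(miss))
      stop("dosed gene(s) not in the active model: ",
           paste(miss, collapse = ", "), call. = FALSE)
    d[match(names(dosage$fractions), act$name)] <- unname(dosage$fractions)
  }
  d
}
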