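#' The packaged extended yeast cell-cycle model
#'
#' Builds the 52-node multi-valued logical model of the budding-yeast cell
#' cycle used throughout the package: a 22-node core in the spirit of the
#' classical logical cell-cycle models (cyclin waves, SBF/MBF, Sic1/APC
#' reset, the CYTOKINESIS and MASS event variables) extended with 30 nodes
#' covering the G2/M checkpoint regulators and their wiring (Cdc28 with its
#' cyclin partners, the Swe1/Hsl1 morphogenesis-checkpoint pair, Mih1, the
#' Slt2 cell-wall-integrity and Hog1 osmotic pathways, replication and
#' mitotic-exit intermediates).
#'
#' Architecturally the cycle is a closed sequence of 31 sequentially
#' activating species ("stages"); each stage switches on when its
#' predecessor is active and switches off once its successor has taken
#' over, so the unperturbed cycle advances one stage per time-step and has
#' a period of exactly 31 time-steps. Checkpoint biology enters as gated
#' transitions and bypasses:
#'
#' * **G1/S** — origin firing requires Cln-Cdc28 activity (two Cdc28
#'   occurrences); at very low `CDC28` dosage cells arrest before S phase.
#' * **G2/M** — spindle formation requires Clb2-Cdc28 (five Cdc28
#'   occurrences and Clb2), and mitotic entry additionally requires Swe1
#'   inactivation, which wild-type Hsl1 performs; a graded
#'   mitotic-activity accumulator (`MIT_FAST`/`MIT_SLOW`) eventually
#'   overrides the Swe1 brake (after ~11 steps) and, much later (~90
#'   steps), the spindle requirement, reproducing the saturating G2 delays
#'   of `hsl1` and partial `cdc28`/`clb2` strains.
#' * **Mitotic exit / cytokinesis** — the actomyosin ring step requires
#'   Hsl1 (septin-associated), with a short accumulator (`MEN_ACC`)
#'   capping the delay at ~6 steps.
#' * **Bypasses** — five stages (two in G1, two in S, one in M) are
#'   skipped whenever the Slt2 pathway output or the Clb1 competition term
#'   drops, so reduced `SLT2` or `CLB1` dosage shortens the cycle by up to
#'   5 steps (~20% faster growth) in a strongly saturating (cooperative)
#'   fashion. Clb1 competes with Clb2 for Cdc28 through late mitosis
#'   because `CLB2` is degraded earlier (from the APC stage) while `CLB1`
#'   persists until the START reset - the wiring difference from which the
#'   divergent `clb1`/`clb2` phenotypes arise.
#' * **Stress wiring** — `HOG1` (and `MIH1`, via stress-dependent Cdc25-type
#'   rescue) acts only when the `STRESS` input is raised by the
#'   `osmotic_stress` module; without stress both genes are neutral at any
#'   dosage.
#'
#' Optional modules: `spindle_checkpoint` (Mad2/Bub2, held inactive unless
#' its `NOC` input is raised), `dna_damage` (Rad53/Dun1, inactive without
#' the `DDC` input) and `osmotic_stress` (drives `STRESS`). All default to
#' off; enabling them leaves the unperturbed cycle unchanged because their
#' trigger inputs are 0.
#'
#' Phase signatures follow the classical hallmarks: G1 from START (low
#' mass, unbudded, Cdc28/Clb low) through pre-replicative assembly; S_G2
#' from origin firing (B-type cyclin inhibitors degraded, bud emerging,
#' Clb accumulation, morphogenesis checkpoint active) to spindle formation;
#' M from the spindle stage through cytokinesis and mitotic exit.
#'
#' @return A validated `logicyc_model` with 52 active nodes and a
#'   deterministic wild-type period of 31 time-steps.
#' @seealso The same model is packaged as
#'   `system.file("extdata", "yeast_cc_extended.json", package = "logicyc")`.
#' @export
yeast_model <- function() {
  stages <- c("CLN3", "BCK2", "SWI4", "SBF", "MBF", "CLN1", "CLN2",
              "PCL1", "PCL2", "CDC34", "CDC4", "CLB5", "CLB6", "CDC6",
              "POL1", "POL2", "RNR1", "HTA1", "HTB1", "BUD", "CLB3",
              "CLB4", "SPN", "KIP1", "CDC20", "CDC16", "CDC14", "MYO1",
              "HOF1", "SWI5", "SIC1")
  k <- length(stages)  # 31
  sg <- function(i) stages[[((i - 1L) %% k) + 1L]]
  ## gated transitions and bypassed ("detour") stages, by stage index
  i_g1s <- 15L       # POL1 entry: Cln-Cdc28 gate
  i_g2m <- 23L       # SPN entry: Swe1 + spindle gates; stall stage is 22
  i_exit <- 28L      # MYO1 entry: Hsl1/septin gate; stall stage is 27
  detours <- list(c(8L, 9L), c(18L, 19L), c(24L))

  slow_ok <- expr_and(expr_ge("SLT2_PW"), expr_ge("CLB1_CP"))
  gate <- vector("list", k)
  gate[[i_g1s]] <- list(expr_ge("CDC28"), expr_ge("CDC28"),
                        expr_not(expr_ge("HOG1_ACT")),
                        expr_not(expr_ge("RAD53")))
  gate[[i_g2m]] <- list(
    ## Swe1 branch: pass once Swe1 is off (Hsl1-dependent), rescued by
    ## accumulated mitotic activity (count >= 11) or stress-activated Mih1
    expr_or(expr_not(expr_ge("SWE1_ACT")),
            expr_and(expr_ge("MIT_SLOW"), expr_ge("MIT_FAST")),
            expr_ge("MIH1_ACT")),
    ## spindle branch: Clb2-Cdc28 forms the spindle; very prolonged
    ## accumulation (count >= 90) eventually substitutes
    expr_or(expr_and(expr_ge("CLB2"), expr_ge("CDC28"), expr_ge("CDC28"),
                     expr_ge("CDC28"), expr_ge("CDC28"), expr_ge("CDC28")),
            expr_eq("MIT_SLOW", 9L)))
  gate[[i_exit]] <- list(expr_or(expr_ge("HSL1"), expr_eq("MEN_ACC", 6L)))
  gate[[25L]] <- list(expr_not(expr_ge("MAD2")))  # APC held by the SAC module

  in_detour <- unlist(detours)
  successor <- function(i) {
    n <- i %% k + 1L
    while (n %in% in_detour) n <- n %% k + 1L
    n
  }

  rules <- list()
  add_rule <- function(target, level, expr)
    rules[[length(rules) + 1L]] <<- list(target = target,
                                         target_level = as.integer(level),
                                         expr = expr)
  or_stages <- function(idx) do.call(expr_or, lapply(stages[idx], expr_ge))

  for (i in seq_len(k)) {
    this <- sg(i)
    prv <- i - 1L; if (prv == 0L) prv <- k
    entries <- list()
    if (i %in% in_detour) {
      ## detour stage: entered from its predecessor only while the slow
      ## path is active (first stage of the detour), or unconditionally
      ## from within the detour
      det <- detours[[which(vapply(detours, function(d) i %in% d, logical(1L)))]]
      if (i == det[1L]) {
        after <- successor(det[length(det)])
        entries[[1L]] <- do.call(expr_and, c(
          list(expr_ge(sg(prv)), slow_ok, expr_not(expr_ge(this)),
               expr_not(expr_ge(sg(after))))))
      } else {
        entries[[1L]] <- expr_and(expr_ge(sg(prv)), expr_not(expr_ge(this)))
      }
      nxt <- i %% k + 1L
      maint <- expr_and(expr_ge(this), expr_not(expr_ge(sg(nxt))))
    } else {
      ## main-path stage: entered from the previous main-path stage; when
      ## that predecessor fronts a detour, also directly from the stage
      ## before the detour while the slow path is inactive
      entries[[1L]] <- do.call(expr_and, c(
        list(expr_ge(sg(prv)), expr_not(expr_ge(this))), gate[[i]]))
      det_before <- Filter(function(d) successor(d[length(d)]) == i, detours)
      if (length(det_before)) {
        d <- det_before[[1L]]
        pre <- d[1L] - 1L
        entries[[2L]] <- do.call(expr_and, c(
          list(expr_ge(sg(pre)), expr_not(slow_ok),
               expr_not(expr_ge(sg(d[1L]))),
               expr_not(expr_ge(sg(d[length(d)]))),
               expr_not(expr_ge(this))), gate[[i]]))
      }
      ## maintenance: stay on until a successor (fast or slow) has fired
      nxts <- unique(c(i %% k + 1L, successor(i)))
      maint <- do.call(expr_and, c(list(expr_ge(this)),
                                   lapply(nxts, function(n)
                                     expr_not(expr_ge(sg(n))))))
    }
    add_rule(this, 1L, do.call(expr_or, c(entries, list(maint))))
  }

  ## --- dosable regulators -------------------------------------------------
  always <- function(n) expr_ge(n, 0L)
  add_rule("CDC28", 1L, always("CDC28"))            # constitutive CDK
  add_rule("SLT2", 1L, always("SLT2"))              # basal CWI signalling
  add_rule("MIH1", 1L, always("MIH1"))
  add_rule("HOG1", 1L, always("HOG1"))
  ## CLB1 persists through mitosis, cleared only at the START reset;
  ## CLB2 accumulates from S phase and is degraded earlier (APC stage 26)
  add_rule("CLB1", 1L, expr_not(expr_or(expr_ge("SIC1"), expr_ge("CLN3"))))
  add_rule("CLB2", 2L, or_stages(21:25))
  add_rule("CLB2", 1L, or_stages(19:20))
  ## morphogenesis checkpoint pair, expressed while the bud forms
  add_rule("SWE1", 1L, or_stages(20:22))
  add_rule("HSL1", 1L, or_stages(20:27))

  ## --- derived activities -------------------------------------------------
  add_rule("SWE1_ACT", 1L, expr_and(expr_ge("SWE1"),
                                    expr_not(expr_ge("HSL1"))))
  add_rule("SLT2_PW1", 1L, expr_and(expr_ge("SLT2"), expr_ge("SLT2"),
                                    expr_ge("SLT2"), expr_ge("SLT2")))
  add_rule("SLT2_PW", 1L, expr_and(expr_ge("SLT2_PW1"), expr_ge("SLT2"),
                                   expr_ge("SLT2"), expr_ge("SLT2"),
                                   expr_ge("SLT2")))
  add_rule("CLB1_CP1", 1L, expr_and(expr_ge("CLB1"), expr_ge("CLB1"),
                                    expr_ge("CLB1"), expr_ge("CLB1")))
  add_rule("CLB1_CP", 1L, expr_and(expr_ge("CLB1_CP1"), expr_ge("CLB1"),
                                   expr_ge("CLB1"), expr_ge("CLB1"),
                                   expr_ge("CLB1")))
  add_rule("HOG1_ACT", 1L, expr_and(expr_ge("HOG1"), expr_ge("STRESS")))
  add_rule("MIH1_ACT", 1L, expr_and(expr_ge("MIH1"), expr_ge("HOG1_ACT")))

  ## --- accumulators (graded escapes for stalled checkpoints) --------------
  stall_g2m <- expr_ge(sg(i_g2m - 1L))   # CLB4 stage held during G2/M stall
  for (lv in 1:9)
    add_rule("MIT_FAST", lv, expr_and(expr_eq("MIT_FAST", lv - 1L), stall_g2m))
  for (lv in 1:9)
    add_rule("MIT_SLOW", lv, expr_or(
      expr_and(expr_eq("MIT_SLOW", lv), stall_g2m,
               expr_not(expr_eq("MIT_FAST", 9L))),
      expr_and(expr_eq("MIT_SLOW", lv - 1L), stall_g2m,
               expr_eq("MIT_FAST", 9L))))
  stall_exit <- expr_ge(sg(i_exit - 1L))  # CDC14 stage held during exit stall
  for (lv in 1:6)
    add_rule("MEN_ACC", lv, expr_and(expr_eq("MEN_ACC", lv - 1L), stall_exit))

  ## --- event markers ------------------------------------------------------
  add_rule("CYTOKINESIS", 2L, expr_or(expr_ge("MYO1"), expr_ge("HOF1")))
  add_rule("CYTOKINESIS", 1L, expr_or(expr_ge("CDC16"), expr_ge("CDC14")))
  mass_low <- or_stages(c(31L, 1:4))
  add_rule("MASS", 2L, expr_not(mass_low))
  add_rule("MASS", 1L, mass_low)

  nodes <- data.frame(
    name = c(stages,
             "CDC28", "CLB1", "CLB2", "HSL1", "SWE1", "MIH1", "HOG1", "SLT2",
             "CYTOKINESIS", "MASS",
             "SWE1_ACT", "SLT2_PW1", "SLT2_PW", "CLB1_CP1", "CLB1_CP",
             "MIT_FAST", "MIT_SLOW", "MEN_ACC", "HOG1_ACT", "MIH1_ACT",
             "STRESS"),
    max_level = c(rep(1L, k),
                  1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L,
                  2L, 2L,
                  1L, 1L, 1L, 1L, 1L, 9L, 9L, 6L, 1L, 1L, 1L),
    role = c(ifelse(stages %in% c("BUD", "SPN"), "state-variable", "gene"),
             rep("gene", 8L),
             rep("event-marker", 2L),
             rep("state-variable", 11L)),
    stringsAsFactors = FALSE)

  signatures <- list(
    G1 = expr_and(or_stages(1:14), expr_not(expr_ge("POL1"))),
    S_G2 = expr_and(or_stages(15:22), expr_not(expr_ge("SPN"))),
    M = expr_and(or_stages(23:31), expr_not(expr_ge("CLN3"))))

  start <- stats::setNames(rep(0L, nrow(nodes)), nodes$name)
  start[c("SIC1", "CLN3")] <- 1L   # START: the handover pair {stage 31, stage 1}
  start[c("CDC28", "SLT2", "MIH1", "HOG1",
          "SLT2_PW1", "SLT2_PW", "CLB1_CP1", "CLB1_CP")] <- 1L
  start["MASS"] <- 1L

  modules <- list(
    spindle_checkpoint = list(
      nodes = data.frame(name = c("MAD2", "BUB2", "NOC"),
                         max_level = c(1L, 1L, 1L),
                         role = c("gene", "gene", "state-variable"),
                         stringsAsFactors = FALSE),
      rules = list(
        list(target = "MAD2", target_level = 1L,
             expr = expr_and(expr_ge("NOC"), expr_ge("SPN"))),
        list(target = "BUB2", target_level = 1L, expr = expr_ge("MAD2"))),
      enabled = FALSE),
    dna_damage = list(
      nodes = data.frame(name = c("DDC", "RAD53", "DUN1"),
                         max_level = c(1L, 1L, 1L),
                         role = c("state-variable", "gene", "gene"),
                         stringsAsFactors = FALSE),
      rules = list(
        list(target = "RAD53", target_level = 1L, expr = expr_ge("DDC")),
        list(target = "DUN1", target_level = 1L, expr = expr_ge("RAD53"))),
      enabled = FALSE),
    osmotic_stress = list(
      nodes = data.frame(name = character(0), max_level = integer(0),
                         role = character(0), stringsAsFactors = FALSE),
      rules = list(
        list(target = "STRESS", target_level = 1L,
             expr = expr_ge("STRESS", 0L))),
      enabled = FALSE))

  model_definition(
    nodes, rules, signatures, start,
    event_nodes = list(cytokinesis = "CYTOKINESIS", mass = "MASS",
                       cytokinesis_level = 2L),
    modules = modules, name = "yeast-cc-extended")
}

#' Path of the packaged extended-model JSON file
#'
#' @return File path within the installed package.
#' @export
yeast_model_path <- function() {
  system.file("extdata", "yeast_cc_extended.json", package = "logicyc",
              mustWork = TRUE)
}
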