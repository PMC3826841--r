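#' Simulation configuration
#'
#' @param n_steps Time-steps per replicate (production default 10000).
#' @param n_replicates Number of Monte-Carlo replicates (production default
#'   10000; deterministic wild-type runs need only 1).
#' @param seed Integer seed; all stochasticity derives from it through
#'   counter-based per-(replicate, step) substreams, so results are
#'   reproducible and replicate-order independent.
#' @param record_trajectory Keep the full state sequence of the first
#'   replicate.
#' @return A `logicyc_config`.
#' @export
sim_config <- function(n_steps = 10000L, n_replicates = 10000L, seed = 1L,
                       record_trajectory = FALSE) {
  stopifnot(n_steps >= 1L, n_replicates >= 1L)
  structure(list(n_steps = as.integer(n_steps),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 record_trajectory = isTRUE(record_trajectory)),
            class = "logicyc_config")
}

#' One synchronous update step
#'
#' Computes the next full state from `state`: every node's rules are
#' evaluated against the previous state (first satisfied rule, in descending
#' target-level order, sets the level; none satisfied gives 0), with
#' per-occurrence and outcome-level dosage sampling applied for dosed nodes.
#' With all dosages at 1 the step is a deterministic function.
#'
#' @param state Named integer vector over the active nodes.
#' @param model A `logicyc_model`.
#' @param dosage A `logicyc_dosage` (default wild type).
#' @param seed,replicate,step Coordinates of the RNG substream used for the
#'   sampling draws (ignored when no node is dosed).
#' @return Named integer vector, the next state.
#' @export
step_model <- function(state, model, dosage = dosage_spec(), seed = 1L,
                       replicate = 0L, step = 1L) {
  dosage <- as_dosage(dosage)
  if (!length(dosage$fractions)) {
    rbt <- rules_by_target(active_rules(model))
    return(step_state_r(state, rbt))
  }
  cm <- compile_model(model)
  d <- dose_vector(model, dosage)
  st <- as.integer(state[cm$node_names])
  res <- .engine_simulate(cm, d, st, 1L, 1L, as.numeric(seed), TRUE, TRUE,
                          as.integer(replicate) * 1000003L + as.integer(step) - 1L)
  stats::setNames(res$trajectory[2L, ], cm$node_names)
}

#' Run synchronous stochastic simulations
#'
#' Each replicate runs `n_steps` synchronous steps from the START state
#' under its own RNG substream. Per-step phase occupancy and cytokinesis
#' events are accumulated in streaming fashion; full states are kept only
#' when `record_trajectory` is set (first replicate).
#'
#' @param model A `logicyc_model`.
#' @param dosage A `logicyc_dosage` (default wild type).
#' @param config A `logicyc_config`.
#' @param require_mass_return If `TRUE` (default) a cycle event requires the
#'   mass node to return to 1 after the qualifying cytokinesis run; if
#'   `FALSE` the run alone counts.
#' @param replicate_offset Shift of the replicate index used for substream
#'   derivation (for running disjoint replicate blocks).
#' @return A `logicyc_sim`: per-replicate summary data frame (`phase counts`,
#'   `events`, `period_sum`, `period_count`), plus the trajectory when
#'   recorded.
#' @export
simulate_model <- function(model, dosage = dosage_spec(), config = sim_config(),
                           require_mass_return = TRUE, replicate_offset = 0L) {
  dosage <- as_dosage(dosage)
  cm <- compile_model(model)
  d <- dose_vector(model, dosage)
  st <- as.integer(active_start_state(model)[cm$node_names])
  res <- .engine_simulate(cm, d, st, config$n_steps, config$n_replicates,
                          as.numeric(config$seed), config$record_trajectory,
                          isTRUE(require_mass_return),
                          as.integer(replicate_offset))
  if (res$signature_conflicts > 0L)
    stop("internal consistency error: ", res$signature_conflicts,
         " simulated state(s) matched more than one phase signature; ",
         "the model's signatures are not mutually exclusive", call. = FALSE)
  pc <- res$phase_counts
  colnames(pc) <- c("G1", "S_G2", "M", "unclassified")
  out <- list(
    replicates = data.frame(replicate = seq_len(config$n_replicates) - 1L +
                              as.integer(replicate_offset),
                            pc, events = res$events,
                            period_sum = res$period_sum,
                            period_count = res$period_count),
    config = config, dosage = dosage, model_name = model$name,
    node_names = cm$node_names)
  if (config$record_trajectory) {
    traj <- res$trajectory
    colnames(traj) <- cm$node_names
    out$trajectory <- traj
  }
  structure(out, class = "logicyc_sim")
}

#' @export
print.logicyc_sim <- function(x, ...) {
  cat("logicyc simulation of \"", x$model_name, "\": ",
      nrow(x$replicates), " replicate(s) x ", x$config$n_steps, " steps\n",
      sep = "")
  cat("mean events/replicate:", mean(x$replicates$events), "\n")
  invisible(x)
}

#' Detect cycle events in a trajectory
#'
#' Scans a recorded trajectory for maximal runs of the cytokinesis node at
#' its completion level. A run of more than two successive steps qualifies;
#' the cycle event closes at the first subsequent step where the mass node
#' returns to 1 (when `require_mass_return`, the default). Runs or pending
#' events truncated by the trajectory end are discarded as incomplete.
#'
#' @param trajectory Integer matrix of states (rows = steps 0..n, columns
#'   named by node), e.g. from `simulate_model(..., record_trajectory=TRUE)`.
#' @param model The model that produced it (for the event-node designation).
#' @param require_mass_return See [simulate_model()].
#' @return Data frame with one row per completed event: `start_step`,
#'   `run_start`, `run_length`, `end_step`, `period`.
#' @export
detect_cycles <- function(trajectory, model, require_mass_return = TRUE) {
  ev <- model$event_nodes
  cyt <- trajectory[, ev$cytokinesis]
  mass <- trajectory[, ev$mass]
  lvl <- ev$cytokinesis_level
  n <- length(cyt) - 1L  # row 1 is step 0
  events <- list()
  run_len <- 0L; run_start <- NA_integer_
  pending <- list(); last_end <- 0L
  for (t in seq_len(n)) {
    v <- cyt[t + 1L]
    if (v == lvl) {
      if (run_len == 0L) run_start <- t
      run_len <- run_len + 1L
    } else {
      if (run_len > 2L) {
        if (require_mass_return) {
          pending[[length(pending) + 1L]] <- c(run_start, run_len)
        } else {
          events[[length(events) + 1L]] <-
            data.frame(start_step = last_end, run_start = run_start,
                       run_length = run_len, end_step = t, period = t - last_end)
          last_end <- t
        }
      }
      run_len <- 0L
    }
    if (length(pending) && mass[t + 1L] == 1L) {
      for (p in pending)
        events[[length(events) + 1L]] <-
          data.frame(start_step = last_end, run_start = p[1L],
                     run_length = p[2L], end_step = t, period = t - last_end)
      last_end <- t
      pending <- list()
    }
  }
  if (length(events)) do.call(rbind, events)
  else data.frame(start_step = integer(0), run_start = integer(0),
                  run_length = integer(0), end_step = integer(0),
                  period = integer(0))
}

#' Relative growth rate from cytokinesis-event counting
#'
#' Simulates the dosed model and converts completed cell-cycle periods into
#' a growth rate relative to wild type: each replicate contributes
#' `wt_period / mean(own periods)` (or 0 if it completed no event), and the
#' relative growth rate is the replicate average. The raw period ratio
#' `mean_period / wt_period` (the slowdown factor) is reported alongside. A
#' strain is flagged arrested only when no replicate completes any event.
#'
#' @inheritParams simulate_model
#' @param wt_period Wild-type cycle length in time-steps; computed from the
#'   unperturbed model (deterministically) when `NULL`.
#' @return A `logicyc_growth` with fields `completed_events`, `mean_period`,
#'   `relative_growth_rate`, `period_ratio`, `arrested`, `se`, `wt_period`.
#' @export
growth_rate <- function(model, dosage = dosage_spec(), config = sim_config(),
                        wt_period = NULL, require_mass_return = TRUE,
                        replicate_offset = 0L) {
  if (is.null(wt_period)) wt_period <- wt_cycle(model)$period
  sim <- simulate_model(model, dosage, config, require_mass_return,
                        replicate_offset)
  rep_df <- sim$replicates
  rates <- ifelse(rep_df$period_count > 0L,
                  wt_period / (rep_df$period_sum / pmax(rep_df$period_count, 1L)),
                  0)
  total_periods <- sum(rep_df$period_count)
  mean_period <- if (total_periods > 0L) sum(rep_df$period_sum) / total_periods
                 else NA_real_
  arrested <- all(rep_df$events == 0L)
  structure(list(
    completed_events = mean(rep_df$events),
    mean_period = mean_period,
    relative_growth_rate = if (arrested) 0 else mean(rates),
    period_ratio = if (arrested) NA_real_ else mean_period / wt_period,
    arrested = arrested,
    se = if (length(rates) > 1L) stats::sd(rates) / sqrt(length(rates)) else 0,
    wt_period = wt_period,
    n_replicates = nrow(rep_df)), class = "logicyc_growth")
}

#' @export
print.logicyc_growth <- function(x, ...) {
  cat(sprintf("relative growth rate %.4f (se %.4f), mean period %.2f steps%s\n",
              x$relative_growth_rate, x$se,
              if (is.na(x$mean_period)) NA else x$mean_period,
              if (x$arrested) " [ARRESTED]" else ""))
  invisible(x)
}
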