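#' Classify a state into a cell-cycle phase
#'
#' Evaluates the model's phase signatures on one state. Exactly one matching
#' signature gives the phase; no match gives `"unclassified"` (possible only
#' for states outside the wild-type cycle reached under perturbation); more
#' than one match is an internal consistency error signalling a bad model
#' file.
#'
#' @param state Named integer vector of node levels.
#' @param model A `logicyc_model`.
#' @return `"G1"`, `"S_G2"`, `"M"` or `"unclassified"`.
#' @export
classify_phase <- function(state, model) {
  matches <- names(model$signatures)[vapply(model$signatures, eval_expr,
                                            logical(1L), state = state)]
  if (length(matches) > 1L)
    stop("internal consistency error: state matches signatures {",
         paste(matches, collapse = ", "), "}", call. = FALSE)
  if (length(matches) == 0L) "unclassified" else matches
}

#' Cell-cycle phase-occupancy profile
#'
#' Counts the time-steps each replicate spends in G1, S_G2 and M over
#' `n_steps`, averages the per-replicate fractions, and normalises the
#' result to the wild-type profile of the same model and step count (WT = 1
#' per phase). Fractions are taken over classified steps; states matching no
#' signature are excluded from the fractions but reported as
#' `unclassified_fraction` (of all steps).
#'
#' @inheritParams simulate_model
#' @param wt Optional precomputed wild-type `logicyc_profile` to normalise
#'   against (computed on the fly when `NULL`; the unperturbed model is
#'   deterministic, so a single replicate suffices for it).
#' @return A `logicyc_profile` with `raw_fraction`, `relative`, `se`,
#'   `unclassified_fraction`, `n_steps_classified`.
#' @export
phase_profile <- function(model, dosage = dosage_spec(), config = sim_config(),
                          wt = NULL, replicate_offset = 0L) {
  dosage <- as_dosage(dosage)
  sim <- simulate_model(model, dosage, config,
                        replicate_offset = replicate_offset)
  rep_df <- sim$replicates
  phases <- c("G1", "S_G2", "M")
  classified <- rowSums(rep_df[, phases])
  fr <- as.matrix(rep_df[, phases]) / ifelse(classified > 0L, classified, 1L)
  raw <- colMeans(fr)
  se <- apply(fr, 2L, stats::sd) / sqrt(nrow(fr))
  is_wt <- length(dosage$fractions) == 0L || all(dosage$fractions == 1)
  if (is.null(wt) && !is_wt) {
    wt <- phase_profile(model, dosage_spec(),
                        sim_config(n_steps = config$n_steps,
                                   n_replicates = 1L, seed = config$seed))
  }
  wt_raw <- if (is_wt) raw else wt$raw_fraction
  structure(list(
    raw_fraction = raw,
    relative = raw / wt_raw,
    se = se,
    unclassified_fraction = mean(rep_df$unclassified) / config$n_steps,
    n_steps_classified = sum(classified),
    dosage = dosage, model_name = model$name), class = "logicyc_profile")
}

#' @export
print.logicyc_profile <- function(x, ...) {
  df <- data.frame(phase = names(x$raw_fraction),
                   raw_fraction = round(unname(x$raw_fraction), 4L),
                   relative = round(unname(x$relative), 3L),
                   se = signif(unname(x$se), 3L))
  print(df, row.names = FALSE)
  if (x$unclassified_fraction > 0)
    cat(sprintf("unclassified fraction: %.4f\n", x$unclassified_fraction))
  invisible(x)
}
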