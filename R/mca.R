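#' Run a gene-dosage series
#'
#' Simulates growth rate and phase profile for one gene across a series of
#' copy fractions (the in-silico analogue of a tetraploid deletion series).
#' The wild-type reference is simulated once (it is deterministic) and each
#' dose runs under an independent replicate-index block of the same seed, so
#' the whole series is reproducible from `config$seed`.
#'
#' @param model A `logicyc_model`.
#' @param gene Gene node to dose.
#' @param doses Copy fractions, must include 1.0; sorted to strictly
#'   decreasing order.
#' @param config A `logicyc_config`.
#' @param profiles Also compute phase profiles per dose (default `TRUE`).
#' @return A `logicyc_series`: data frame `rows` with columns `gene`,
#'   `dose`, `rate` (relative growth rate, WT = 1), `se`, `arrested`,
#'   `mean_period`, plus a list of `logicyc_profile`s when requested.
#'   An essential-gene arrest at low dose is a valid result, not an error.
#' @export
run_dose_series <- function(model, gene, doses = c(1, 0.75, 0.5, 0.25, 0),
                            config = sim_config(), profiles = TRUE) {
  act <- active_nodes(model)
  if (!gene %in% act$name)
    stop("gene \"", gene, "\" is not a node of the active model", call. = FALSE)
  doses <- sort(unique(as.numeric(doses)), decreasing = TRUE)
  if (!any(doses == 1))
    stop("the dose series must include the wild-type dose 1.0", call. = FALSE)
  if (any(doses < 0 | doses > 1))
    stop("doses must lie in [0, 1]", call. = FALSE)

  wt_period <- wt_cycle(model)$period
  wt_prof <- phase_profile(model, dosage_spec(),
                           sim_config(n_steps = config$n_steps,
                                      n_replicates = 1L, seed = config$seed))
  rows <- list(); profs <- list()
  for (i in seq_along(doses)) {
    d <- doses[i]
    dos <- dosage_spec(stats::setNames(d, gene))
    off <- (i - 1L) * config$n_replicates  # independent substream block
    cfg <- if (d == 1) sim_config(config$n_steps, 1L, config$seed) else config
    g <- growth_rate(model, dos, cfg, wt_period = wt_period,
                     replicate_offset = off)
    rows[[i]] <- data.frame(gene = gene, dose = d,
                            rate = g$relative_growth_rate, se = g$se,
                            arrested = g$arrested,
                            mean_period = g$mean_period)
    if (profiles)
      profs[[as.character(d)]] <- phase_profile(model, dos, cfg, wt = wt_prof,
                                                replicate_offset = off)
  }
  structure(list(rows = do.call(rbind, rows), profiles = if (profiles) profs,
                 gene = gene, wt_period = wt_period, config = config),
            class = "logicyc_series")
}

#' @export
print.logicyc_series <- function(x, ...) {
  cat("dose series for", x$gene, "\n")
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Flux-control coefficients from a dose series
#'
#' For each adjacent dose pair the flux-control coefficient
#' `C = (dJ/J) / (dE/E)` is computed by finite differences, with the
#' effector E the copy fraction, the flux J the relative growth rate, and
#' midpoint denominators `J = (J_hi + J_lo)/2`, `E = (E_hi + E_lo)/2`.
#' Coefficients are reported per dose interval rather than as one global
#' value because the dose-flux relationship is generally non-linear.
#' Arrested rows are excluded with a warning. `C` is exactly 0 whenever
#' `dJ = 0`; haploproficient-like behaviour (J rises as E falls) gives
#' `C < 0`, haploinsufficient-like gives `C > 0`.
#'
#' @param series A `logicyc_series`, or a data frame with columns `dose`,
#'   `rate` (and optionally `arrested`, `gene`).
#' @return Data frame with one row per interval: `gene`, `d_low`, `d_high`,
#'   `C`, `dJ_over_J`, `dE_over_E`.
#' @export
control_coefficients <- function(series) {
  rows <- if (inherits(series, "logicyc_series")) series$rows else
    as.data.frame(series)
  if (is.null(rows$arrested)) rows$arrested <- FALSE
  if (is.null(rows$gene)) rows$gene <- NA_character_
  usable <- rows[!rows$arrested, , drop = FALSE]
  if (nrow(usable) < nrow(rows))
    warning(sum(rows$arrested), " arrested dose(s) excluded from ",
            "control-coefficient estimation", call. = FALSE)
  if (nrow(usable) < 2L)
    stop("need at least 2 non-arrested doses to form a finite difference",
         call. = FALSE)
  usable <- usable[order(usable$dose, decreasing = TRUE), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(usable) - 1L)) {
    hi <- usable[i, ]; lo <- usable[i + 1L, ]
    dJ <- lo$rate - hi$rate
    dE <- lo$dose - hi$dose
    Jm <- (hi$rate + lo$rate) / 2
    Em <- (hi$dose + lo$dose) / 2
    rel_J <- dJ / Jm
    rel_E <- dE / Em
    C <- if (dJ == 0) 0 else rel_J / rel_E
    out[[i]] <- data.frame(gene = hi$gene, d_low = lo$dose, d_high = hi$dose,
                           C = C, dJ_over_J = rel_J, dE_over_E = rel_E)
  }
  do.call(rbind, out)
}
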