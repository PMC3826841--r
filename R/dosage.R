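#' Gene-dosage specification
#'
#' A dosage specification maps gene nodes to copy fractions `d` in `[0, 1]`
#' (1 = wild type). During simulation a dosed node is subject to stochastic
#' resets with probability `p = 1 - d` at two sites:
#'
#' * **occurrence level** — every time the node appears as a leaf in the
#'   update rule of any node, an independent draw decides whether that
#'   occurrence reads the node's true value (probability `d`) or 0
#'   (probability `p`);
#' * **outcome level** — when the dosed node's own rules propose a positive
#'   next level, the node is set to that level with probability `d` and
#'   reset to 0 with probability `p`. A proposed level of 0 stays 0.
#'
#' `d = 1` reproduces the deterministic unperturbed model exactly; `d = 0`
#' is a hard knockout (the node and all its reads are clamped to 0). Nodes
#' absent from the specification behave as `d = 1`. Fractions are not
#' restricted to quarters: any value in `[0, 1]` is accepted, which is how
#' hypomorphic (DAmP-like) alleles and continuous inhibitor titrations are
#' expressed.
#'
#' @param fractions Named numeric vector of copy fractions, e.g.
#'   `c(HSL1 = 0, CDC28 = 0.5)`. May be empty (wild type).
#' @return An object of class `logicyc_dosage`.
#' @examples
#' dosage_spec(c(CDC28 = 0.5))
#' @export
dosage_spec <- function(fractions = numeric(0)) {
  fractions <- unlist(fractions)
  if (length(fractions)) {
    if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
      stop("dosage fractions must be named by gene node", call. = FALSE)
    if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1))
      stop("copy fractions must lie in [0, 1]", call. = FALSE)
    if (anyDuplicated(names(fractions)))
      stop("duplicate gene in dosage specification", call. = FALSE)
  }
  structure(list(fractions = fractions), class = "logicyc_dosage")
}

#' @export
print.logicyc_dosage <- function(x, ...) {
  if (!length(x$fractions)) {
    cat("dosage: wild type (all fractions 1)\n")
  } else {
    cat("dosage:", paste0(names(x$fractions), "=", x$fractions, collapse = ", "),
        "\n")
  }
  invisible(x)
}

as_dosage <- function(x) {
  if (inherits(x, "logicyc_dosage")) return(x)
  dosage_spec(x)
}

#' Inhibitor-style activity reduction
#'
#' Reducing a node's activity to a residual fraction (e.g. by a
#' kinase-specific inhibitor) uses the same stochastic-reset semantics as a
#' fractional gene dosage, so an activity of 0.25 behaves statistically like
#' a single-copy (25%) tetraploid dosage and activities below 0.25 extend
#' the titration continuously.
#'
#' @param node Target node name.
#' @param activity Residual activity fraction in `[0, 1]`.
#' @param base Optional existing `logicyc_dosage` to extend.
#' @return A `logicyc_dosage`.
#' @export
inhibitor_spec <- function(node, activity, base = dosage_spec()) {
  if (!is.numeric(activity) || length(activity) != 1L ||
      !is.finite(activity) || activity < 0 || activity > 1)
    stop("activity must be a single value in [0, 1]", call. = FALSE)
  fr <- base$fractions
  fr[node] <- activity
  dosage_spec(fr)
}

#' Reset probability of each dosed node
#'
#' @param dosage A `logicyc_dosage`.
#' @return Named numeric vector `p = 1 - d`.
#' @export
reset_probability <- function(dosage) {
  d <- as_dosage(dosage)$fractions
  stats::setNames(1 - d, names(d))
}

#' Single occurrence-level dosage draw
#'
#' Reference implementation of the per-occurrence sampling rule: with
#' probability `d` the occurrence reads the node's current value, otherwise
#' it reads 0. Exposed for illustration and for the exact oracle's unit
#' checks; the compiled engine applies the same rule internally.
#'
#' @param value Current level of the node.
#' @param d Copy fraction.
#' @param u Uniform(0,1) draw (defaults to a fresh `runif(1)`).
#' @return The level this occurrence reads.
#' @export
sample_occurrence <- function(value, d, u = stats::runif(1L)) {
  if (d < 0 || d > 1) stop("d must lie in [0, 1]", call. = FALSE)
  if (value == 0L || d == 1) return(as.integer(value))
  if (u < d) as.integer(value) else 0L
}

#' Outcome-level dosage reset
#'
#' Reference implementation of the target-update rule: a proposed level of 0
#' stays 0; a positive proposed level is kept with probability `d` and reset
#' to 0 with probability `1 - d`.
#'
#' @param proposed_level Deterministic rule outcome for the node this step.
#' @param d Copy fraction of the node.
#' @param u Uniform(0,1) draw.
#' @return The node's next level.
#' @export
apply_target_reset <- function(proposed_level, d, u = stats::runif(1L)) {
  if (d < 0 || d > 1) stop("d must lie in [0, 1]", call. = FALSE)
  if (proposed_level == 0L || d == 1) return(as.integer(proposed_level))
  if (u < d) as.integer(proposed_level) else 0L
}
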