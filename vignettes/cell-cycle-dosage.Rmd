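---
title: "Modelling gene-dosage effects on the yeast cell cycle with stochastic logical networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene-dosage effects on the yeast cell cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logicyc)
```

## The modelling problem

Gene copy-number variation — a tetraploid deletion series with 4, 3, 2, 1
or 0 copies of a gene, a destabilised (DAmP-like) allele, or a titratable
kinase inhibitor — changes the *supply* of a regulator without changing
its wiring. `logicyc` asks what such graded supply changes do to the
budding-yeast cell cycle: the cycle period (hence growth rate), the
distribution of cells over G1, S/G2 and M, and the flux-control
coefficient of each regulator over the cycle.

The model class is the discrete, synchronous, multi-valued logical
network: every node takes an integer level in `0..max_level`, and all
nodes are recomputed each time-step from the previous full state. Rules
for a multi-valued node are evaluated in descending target-level order;
the first satisfied rule sets the level and an unsatisfied node falls to
0. Synchronous updating is a deliberate choice: a fixed wild-type period
measured in time-steps is only well-defined for a deterministic update
schedule, and all period and occupancy statistics below are expressed in
fractions of a cycle rather than chronological time (supply changes also
change real-time cycle length through nutrient physiology, which is
outside the model).

## Dosage as per-occurrence stochastic resets

A copy fraction `d` (1 = wild type) turns into a reset probability
`p = 1 - d` applied at two sites each time-step:

* **occurrence level** — each appearance of the dosed node as a leaf of
  any rule independently reads the node's true value with probability `d`
  and 0 with probability `p`;
* **outcome level** — when the dosed node's own rules propose a positive
  level, that level is kept with probability `d` and reset to 0 with
  probability `p` (a proposed 0 stays 0; for multi-valued nodes the
  satisfied level is kept, not an intermediate one).

Both sites are active because the rubric speaks both of the node's value
*within expressions* and of the node's *own update*; the exact
Markov-chain oracle (below) implements the same two-site semantics
analytically, so the convention is pinned down by tests rather than by
prose. One consequence worth knowing when calibrating: a constitutively
re-expressed gene has state `1` with probability `d` (outcome site), so a
single occurrence of it in a gate passes with probability `d^2`, and a
conjunction of `m` occurrences with probability `d^(m+1)`. Dosages are
not restricted to quarters; any `d` in `[0, 1]` is accepted, which is how
`inhibitor_spec()` expresses continuous activity titration.

Randomness comes from counter-based splitmix64 substreams indexed by
`(seed, replicate, step)`. Identical seeds give byte-identical summary
tables, replicates are order-independent (so replicate blocks pool
exactly), and a run with no dosed node consumes no randomness at all and
is deterministic for every seed.

## The packaged extended model

`yeast_model()` (also shipped as `inst/extdata/yeast_cc_extended.json`)
follows the size convention of a 22-node logical core extended by 30
checkpoint-related nodes, 52 active nodes in total. The published rule
set for the extension is not reproduced verbatim here; the network is
instead *calibrated by behaviour*: its architecture is fixed first (a
31-stage sequential-activation backbone naming the canonical firing order
CLN3 → SBF/MBF → CLN1/2 → CLB5/6 → origin firing → bud emergence →
CLB3/4 → spindle → APC → mitotic exit → cytokinesis → SIC1 reset), and
the gate stoichiometries were then chosen analytically so that the
wild-type period is exactly 31 steps (14 G1 + 8 S/G2 + 9 M) and the
dosage series of the eight focal regulators reproduce their reported
phenotypes. The load-time validator enforces the behavioural contract:
periodic return to START, and exactly one phase signature matching every
step of the cycle.

The mechanically distinct pieces, with the parameters that matter:

* **Gated transitions.** G1/S requires two Cdc28 occurrences (pass
  probability `d^3`), so G1 arrest appears only at very low `CDC28`
  dosage. G2/M is a conjunction of a *Swe1 branch* (pass `d_HSL1^2`;
  Swe1 is active exactly when Hsl1 fails to be read) and a *spindle
  branch* requiring Clb2 plus five Cdc28 occurrences (pass
  `d_CLB2^2 * d_CDC28^6`). Cytokinesis onset requires Hsl1 (pass
  `d_HSL1^2`).
* **Graded escapes.** Two accumulator nodes (`MIT_FAST`/`MIT_SLOW`, a
  two-digit base-10 counter running while the pre-mitotic stage is held)
  release the Swe1 brake after ~11 stalled steps and the spindle
  requirement after ~90; `MEN_ACC` caps the cytokinesis delay at ~6.
  These caps are what make `hsl1` null *slow* (period 48, growth 65% of
  WT, S/G2 occupancy 1.5x) rather than arrested, and what turns the
  CDC28 dose-response bimodal: the G2 delay saturates near 90 steps
  while the G1 delay keeps growing as `d^-3`, so G2 occupancy peaks
  (~2.5x WT at 50% dosage) and then hands over to G1 arrest below ~10%.
* **Saturating bypasses.** Five backbone stages (two G1, two S, one M)
  are skipped whenever the Slt2 pathway output or the Clb1 competition
  term drops. Both terms need ten consecutive-occurrence successes
  (probability `d^10`), so any partial deletion of `SLT2` or `CLB1`
  collapses them almost completely and shortens the cycle from 31 to ~26
  steps — the flat ~19% growth advantage — while leaving the phase
  profile near wild type because the skipped stages are spread over the
  phases proportionally. `CLB2` is wired differently: it is degraded
  earlier (from the APC stage) and gates the spindle branch, so its
  series is haploinsufficient-like with a threshold between 50% and 25%
  dosage; the `CLB1`/`CLB2` divergence in the model is exactly this
  degradation-timing difference.
* **Stress neutrality.** `HOG1` and `MIH1` feed forward only through
  `STRESS`-dependent activity nodes; with the `osmotic_stress` module
  off (the default) their dosage has provably no effect — the model's
  version of "no phenotype in the absence of external stress".

Known mis-specification, kept deliberately: the model predicts no
phenotype for `SWE1` reduction alone (Swe1 activity is already fully
suppressed by wild-type Hsl1), whereas `swe1` deletants actually grow
~18% faster; the behavioural calibration surface did not include a
mechanism for that haploproficiency, and the reference behaviour the
model follows was itself wrong about the low-copy end of the `SWE1`
series.

## Events, growth rate and profiles

A completed cycle is the progression START → a run of *more than two*
consecutive steps with `CYTOKINESIS` at level 2 → the return of `MASS`
to 1. Runs of length 2 or less are noise by definition and never count;
runs still open at the end of a trajectory are discarded as incomplete,
a conservative choice that slightly undercounts rather than fabricating
partial events. Whether the mass return is required for *counting* (and
not just for delimiting the measured period) is switchable
(`require_mass_return`, default `TRUE`, the stricter reading).

The relative growth rate of a strain is `T_WT / T_strain` — wild-type
period over mean period — *not* the period ratio itself: slower strains
must come out below 1 for the quantity to be a growth rate
(proportional to inverse doubling time). The raw period ratio is
reported alongside. Each replicate contributes the rate of its own mean
period, replicates that complete no event contribute rate 0, and a
strain is flagged `arrested` only when *no* replicate completes an
event; incomplete terminal cycles are excluded from the period mean for
unbiasedness.

Phase profiles count, per replicate, the steps classified by the three
signature expressions, normalised over classified steps. States matching
no signature (reachable only under perturbation) are excluded from the
fractions but reported as an `unclassified` fraction rather than being
forced into a nearest phase — silent misclassification would corrupt
exactly the profiles the perturbations are meant to change. In the
packaged model the perturbed stall states remain classified, so this
fraction is 0 throughout the shipped analyses. Profiles are normalised
to the wild-type profile of the same model and step count; the "S/G2"
and "G2/S" conventions are pooled into the single phase `S_G2`.

## Flux-control coefficients

`control_coefficients()` computes, per adjacent dose pair,
`C = (dJ/J) / (dE/E)` with the effector `E` the copy fraction (mRNA
tracks copy number; protein abundance is not modelled) and `J` the
relative growth rate, using midpoint denominators. Coefficients are
reported per interval rather than pooled into one number because the
dose-flux curves of interest are strongly non-linear (flat for `HOG1`,
bimodal for `CDC28`); a single global coefficient would average away the
finding. `C` is exactly 0 for a flat flux, positive for
haploinsufficient-like behaviour, negative for haploproficient-like. No
published numeric coefficients exist for these genes, so the
implementation is validated on closed forms and on a synthetic toy whose
flux provably tracks its effector (`J(d) = d` over the tested interval,
giving `C = 1`).

## The exact oracle and the toy generators

`build_chain()` enumerates the full state space (at most 4096 states;
at most 16 jointly-enumerated stochastic occurrences per target) and
builds the exact one-step transition matrix under the dosage semantics;
`transient_occupancy()` iterates it. Because occurrence draws are
independent across targets, the row distribution factorises over nodes,
which keeps enumeration exact and cheap. The oracle shares the pure-R
expression evaluator with the validator but none of the compiled engine
code, so engine-versus-oracle agreement (exact at `d` in {0, 1},
within 3 Monte-Carlo standard errors at intermediate `d`) is a genuine
dual-route check.

`make_toy_model()` generates the fixtures used for those checks: a
period-2 toggle, token rings of known period `k` (one cytokinesis run
and one mass return per lap), an arrester resting at its arrested fixed
point, and a "paced" ring whose pacing-gene knockout exactly doubles the
period. The toys exercise every code path the yeast model uses — gates,
multi-valued event markers, signatures — at exactly-solvable size. What
toy-level agreement does *not* show is fidelity of the yeast wiring
itself to real cells; that calibration is only as good as the behaviours
listed above, and features such as cell death (viability), cell size
control, nutrient physiology and DNA-content histograms are out of the
model's scope altogether.

## Numerical and scale choices

The production simulation protocol is 10,000 steps x 10,000 replicates.
The package's tests and the bundled acceptance analysis use 2,000 steps
x 500 replicates per dosage, chosen so that every reported quantity has
a Monte-Carlo standard error at least an order of magnitude below the
tolerance applied to it (the wild type is deterministic and needs a
single replicate). Expressions are compiled to a postfix bytecode and
stepped in C++; a full dosage series at the test scale runs in seconds.
Degenerate inputs are resolved as follows: dosing a node absent from
the active model is an error (not silently ignored); an essential-gene
arrest inside a dose series is a result, not an error; duplicate
(target, level) rules and unresolvable references are rejected at load
time with the offending names; and toy sizes exceeding the enumeration
bound are refused rather than approximated.
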