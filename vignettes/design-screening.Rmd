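---
title: "Screening channeling and crosstalk designs in monolignol biosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening channeling and crosstalk designs in monolignol biosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignindesign)
```

## The modeling question

The G and S branches of monolignol biosynthesis in *Medicago* share their
substrate pool (caffeoyl CoA) and several promiscuous enzymes. Two putative
enzyme channels — CCR1·CAD toward coniferyl alcohol (G lignin) and COMT·F5H
toward 5-hydroxyconiferyl aldehyde (S lignin) — and five candidate
metabolite-level regulatory mechanisms can be combined into hundreds of
mechanistically distinct *designs*. Most of these combinations cannot be
distinguished by intuition, and the relevant kinetic parameters are unknown.
The package therefore treats the question statistically: for every design it
builds a large ensemble of randomly parameterized kinetic models anchored to
a common wild-type steady state, simulates four genetic perturbations, and
counts how many ensemble members reproduce the observed S/G lignin-ratio
changes. A design whose count is zero across a large ensemble is considered
incompatible with the observations; a design with many surviving
parameterizations is robust.

## Pathway scaffold and enumeration

The scaffold spans caffeoyl CoA (`X1`), caffeyl aldehyde (`X2`), feruloyl
CoA (`X3`), coniferyl aldehyde (`X4`, present only when a free route touches
it), coniferyl alcohol (`X5`), 5-hydroxyconiferyl aldehyde (`X6`) and
sinapaldehyde (`X7`), with effluxes into the G, 5HG and S lignin sinks.
5-hydroxyconiferyl alcohol and sinapyl alcohol are lumped into the 5HG and S
efflux steps, so the model has at most seven dependent pools; the
channels-only configuration, where coniferyl aldehyde is untouched, has six.
Six enzymes (CCR1, CCR2, CCoAOMT, COMT, F5H, CAD) are independent variables.

Six reactions are optional: the two channels plus the free-enzyme routes
through coniferyl aldehyde (free COMT, free CCR1, free CAD, free F5H). A
subset of optional edges is admissible when

* caffeyl aldehyde and feruloyl CoA each have an outgoing edge and coniferyl
  alcohol and 5-hydroxyconiferyl aldehyde each have an incoming one, and
* coniferyl aldehyde has free-route producers *iff* it has free-route
  consumers.

The second rule is deliberately bidirectional. Requiring only
produced-implies-consumed admits 22 subsets; a consuming edge with no
producer, however, is a dead edge whose model is indistinguishable from the
configuration without it, so the package treats such subsets as duplicates
and excludes them, leaving 19 configurations. Labels `A` (all six edges) to
`S` (channels only) are assigned by descending edge count with a fixed
tie-break; only the anchors `A` and `S` are meaningful externally, the
remaining letters are internal bookkeeping and analyses should refer to edge
sets.

Crosstalk mechanisms: M1 (feruloyl CoA competitively inhibits the CCR2 step),
M2 (caffeyl aldehyde weakly inhibits the 3-O-methylation of caffeoyl CoA),
M3 (the same interaction with activating sign; M2 and M3 are mutually
exclusive), M4 (caffeoyl CoA inhibits the free-COMT methylation of caffeyl
aldehyde) and M5 (substrate inhibition of free COMT by caffeyl aldehyde).
The inhibition family (subsets of {M1, M2, M4, M5}) has 16 patterns and,
with 19 topologies, 304 designs. M4 and M5 are vacuous wherever the
free-COMT edge is absent; they are recorded but change nothing.

## Model form

Every reaction is one power-law term
\(V_i = \gamma_i \prod_j X_j^{f_{ij}}\). Kinetic-order sign conventions:
substrates positive, inhibitors negative, absent variables zero, enzymes
exactly 1. Channel fluxes carry *both* component enzymes with kinetic order
1 each — the mass-action assumption for a bimolecular complex. This choice
(the reference analysis does not state a channel rate law) matters: it makes
COMT down-regulation act on the S channel and CCR1 perturbations act on the
G channel, which is what lets the screen discriminate channel-containing
topologies. The G efflux (polymerization) carries no enzyme variable; the
5HG and S effluxes lump the CAD reduction of their aldehydes and carry CAD.
The influx into caffeoyl CoA is constant — the upstream phenylpropanoid
pathway is outside the model.

Default kinetic-order ranges (configurable, including per-slot overrides):
substrates and activators sampled uniformly from [0.1, 1], inhibitors from
[-1, -0.1]. Uniform sampling is the maximum-entropy choice on a bounded
interval. M5 is realized by sampling the free-COMT substrate exponent from
the inhibitor range: in power-law form, an inhibiting substrate *is* a
negative apparent kinetic order (`m5_range` option).

An optional `split_methylation` switch models each 3-O-methylation as two
parallel terms (CCoAOMT-carried and COMT-carried); the default keeps the
minimal lumped form.

## Wild-type flux sampling

At steady state each pool balance is linear in the fluxes. Together with the
wild-type S/G flux-ratio row \(V_S - \rho\,V_G = 0\), the normalization
\(V_{influx} = 1\) (absolute scale is irrelevant after normalization) and
per-flux positivity \(V_i \ge \varepsilon = 10^{-3}\), these define a
bounded polytope. The positivity floor exists because a present edge with
zero flux would silently duplicate a different topology and break the
flux-weighted aggregation below. All reactions are treated as irreversible;
reversibility bounds can be added per reaction through the constraint
builder.

Extreme points are enumerated exactly by scanning basic feasible solutions
(all active-bound subsets whose rows, with the equalities, have full column
rank), deduplicated at 1e-9. Boundedness is verified by checking that the
normalized recession cone is empty, so a missing normalization row is
reported rather than silently mis-enumerated. Wild-type flux vectors are
drawn as convex combinations of the vertices with flat Dirichlet weights —
the literal parametric description of the polytope. This measure is not
uniform over the polytope; a hit-and-run walker (`method = "hitandrun"`) is
available when approximate uniformity over P is preferred. The reference
analysis does not state its sampling measure.

## S-system solving and its domain of validity

Normalizing \(Y_i = X_i/X_{iS}\) replaces every rate constant by the sampled
flux \(V_{iS}\) and puts the wild type at \(Y = 1\). Aggregating each pool's
production terms (and, separately, consumption terms) into single power laws
gives the S-system: aggregate rates \(\alpha_i = \beta_i\) equal the total
steady-state flux through pool *i*, and aggregate kinetic orders are the
flux-weighted means of the term exponents. At the operating point the
S-system and GMA models coincide; the package verifies this equivalence
(identity perturbation equal to 1e-10; second-order agreement on shrinking
perturbation ladders) against a damped-Newton GMA fixed-point solver.

Perturbed steady states solve the log-linear system
\((G - H)\,y = (H_E - G_E)\ln m\). Numerical policy: a reciprocal condition
number below 1e-12 flags the instantiation *degenerate* (excluded and
tallied separately); a solution with \(\max_i |y_i| > \ln 1000\) (strictly)
is *ill-behaved*, mirroring the more-than-1000-fold exclusion rule.
Knockouts are simulated as 5% residual activity — a zero multiplier lies
outside the power-law domain. Away from the operating point the S-system is
an approximation to the GMA model; its solutions need not conserve mass
exactly, and this is intentional: the screen's statistics are defined on
S-system solutions, with the GMA solver kept as a diagnostic oracle. The
first-order agreement constant grows as an instantiation approaches
singularity, so instance-wise deviations at finite perturbations vary over
orders of magnitude; the test suite asserts the convergence *order*
everywhere and the absolute bound for the typical instance. Local stability
of the perturbed states is not checked (steady-state screening only).

## Perturbation scenarios and screening statistics

Four lines are simulated per instantiation: CCoAOMT-down (default
multiplier 0.24, i.e. about a 4.2-fold activity reduction), COMT-down
(multiplier 0.1), and the *ccr1* and *ccr2* knockouts (residual 0.05). The
*ccr2* scenario optionally applies hierarchical regulation — CCR1 and
CCoAOMT multiplied by 1.5 — reflecting the observed up-regulation of the
other branch in that mutant; the true magnitudes are not published, so 1.5
is a flagged placeholder. Observed S/G values for the two quantitative
alfalfa lines and the wild-type ratio \(\rho_{WT}\) are user inputs; the
shipped defaults (\(\rho_{WT} = 0.5\), 0.75 and 0.05) are placeholders and
the loader warns about them. Literal reproduction of a screen against the
transgenic datasets requires entering the measured values in the scenario
YAML.

An instantiation is **valid** when (i) no scenario is ill-behaved or
degenerate, (ii) the mean squared difference between predicted and observed
S/G over the quantitative lines is below 0.01, and (iii) each knockout
prediction moves beyond 5% of \(\rho_{WT}\) in the observed direction.
`Q` counts valid instantiations; `Q'` counts those passing the qualitative
clauses and *either* the MSE test or a 25% per-line relative-error test.
Defining the relaxed count as this union keeps \(Q \le Q'\) for any observed
values (with observations of order 0.5–1, the 25% band strictly contains
the MSE band and the union reduces to the plain relaxed criterion).

The data-free quadrant statistics (counts of instantiations with *ccr1*
S/G below \(0.95\rho\) and *ccr2* above \(1.05\rho\) — the "northwest
quadrant") characterize the design space without any observations. Two
findings from the package's own screens, computed in the test suite:

* The dual-inhibition pattern {M2, M5} populates the northwest quadrant
  without hierarchical regulation. Its mechanism is visible in the model
  structure: M5 flattens the caffeyl-aldehyde consumption response, so the
  pool rises sharply when CCR2 is knocked out, and M2 converts that rise
  into suppression of the competing methylation flux.
* The activation pattern {M3} reaches the northwest quadrant only when the
  hierarchical component of the *ccr2* scenario is active; under these
  knockout depths and kinetic-order ranges the activation loss alone cannot
  push the predicted S/G above the wild-type margin. The acceptance suite
  therefore screens {M3} with hierarchical regulation on.
* Every topology that reaches the northwest quadrant under either pattern
  contains the G channel.

One caveat is reported honestly rather than tuned away: with the 1.5
hierarchical placeholder, a thin corner (~0.1%) of *crosstalk-free*
instantiations in the two topologies that consume coniferyl aldehyde only
through free F5H also crosses the *ccr2* margin, by diverting the
hierarchically boosted CCR1 flux to the S side. These are genuine GMA fixed
points, not linearization artifacts. The reference analysis reports zero
such cases; since its hierarchical magnitudes are unpublished, the
corresponding acceptance assertion is left failing rather than adjusting
the placeholder to force agreement.

## Synthetic ground-truth scenarios

`generate_synthetic_scenario()` draws one instantiation of a chosen design
(exactly as the screening kernel would), solves the four scenarios, and
emits the predictions as observations: quantitative values for the alfalfa
lines (optionally with multiplicative lognormal noise), directions for the
knockouts. A knockout prediction inside the 5% strip has no defined
direction and is emitted quantitatively instead — necessarily so for the
channels-only topology, where the *ccr1* knockout has exactly no
steady-state phenotype (its substrate pool compensates the enzyme loss
exactly). Screening the true design against its own noiseless scenario must
recover it (`Q > 0`); this closes the loop on every stage of the pipeline
without external data. What synthetic scenarios do *not* emulate: biological
replicate variance, internode-resolved measurements, and any model
misspecification — a passing recovery test shows the pipeline is
self-consistent, not that the model family matches real plants.

## Determinism and problem sizes

All sampling is driven by explicit integer seeds; per-design seeds are
derived from the run seed and the design index, so `screen_all()` results
are independent of evaluation order, and repeated runs are byte-identical.
The package's tests run ensembles of 10^4 instantiations per design
(roughly 75 µs per instantiation: one 7x7 log-linear solve for all four
scenarios plus flux-weighted aggregation); the reference ensemble size of
10^5 per design is a command-line flag away (`--n 100000`). Existence-style
conclusions (is Q positive?) are insensitive to the ensemble size once the
per-design rates (10^-3 and up) are resolvable.

## Known limitations

* Table-level kinetic-order bounds and the reversibility inequalities of the
  reference analysis are not published; defaults are sign-rule-based and
  fully overridable.
* Letter labels beyond `A` and `S` cannot be matched to the reference
  figures; robust sets should be compared as edge sets.
* The screen evaluates steady states only; transient behavior and local
  stability are out of scope (a diagnostic stability check would operate on
  the S-system Jacobian, which is available from the instance matrices).
* Transcriptional regulation is not modeled beyond the hierarchical
  multipliers of the *ccr2* scenario.
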