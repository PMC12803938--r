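---
title: "Methods: metabolomics-constrained differential flux variability analysis"
author: "dfva"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolomics-constrained differential flux variability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfva)
```

## The problem

Targeted metabolomics experiments that sample two conditions (for example
a wild-type and a deletion genotype) at a baseline and a follow-up
timepoint measure *abundances*, not fluxes. Constraint-based metabolic
modelling offers a way to translate abundance dynamics into statements
about *flux capability*: if a metabolite's abundance ratio between the
two timepoints differs between conditions, the demonstrated exchange
capacity for that metabolite can be rescaled accordingly, and the two
rescaled models can be compared reaction by reaction. `dfva` implements
this translation as a deterministic pipeline: parsimonious reference
state, ratio-scaled exchange bounds, loopless flux variability analysis,
and per-reaction altered-flux calls.

The output is a *capability* statement, not a flux measurement: a
reaction called "decreased" has a smaller feasible flux range in
condition B than in condition A under identical optimality assumptions.
No claim is made about the flux the tissue actually realized.

## Model and assumptions

A metabolic model is a stoichiometric matrix $S$ (metabolites $\times$
reactions), finite flux bounds $lb \le v \le ub$, and a linear biomass
objective $c$. The analyses assume:

* **Steady state.** All flux vectors satisfy $S v = 0$; metabolite pools
  are not modelled.
* **Near-optimal growth.** Both conditions are assumed to operate within
  a fraction (default 0.9) of their own biomass optimum. A
  `shared_optimum` switch instead constrains both models by the base
  model's optimum; note that a strongly restricted condition model may
  then be infeasible, which the pipeline reports as an error rather than
  silently relaxing.
* **Parsimony.** Total absolute flux is close to the minimum necessary
  (at most a factor, default 1.1, above it). This is the standard proxy
  for enzyme-cost efficiency and is what makes exchange fluxes in the
  reference state well defined.
* **Finite bounds.** "Unbounded" reactions carry $\pm$`default_bound`
  (1000), the common convention in constraint-based modelling; flux
  variability presumes finite bounds.

## Pipeline stages

### Reference state

`pfba()` is the two-stage linear program: maximize $c^\top v$, then
minimize $\sum_i |v_i|$ subject to $c^\top v \ge f \cdot z^*$ (default
$f = 1$). Absolute values are handled by forward/reverse flux splitting
($v = p - q$, $p, q \ge 0$), keeping every problem a pure LP. The
reference is computed **after** artificial exchanges are inserted
(`ensure_exchanges()`), so that measured metabolites without a natural
exchange can carry nonzero reference flux; inserting them afterwards
would force their scaled bound to $0 \times r = 0$ and make them inert.

### Ratios

`compute_ratios()` uses ratios of replicate **means** (not medians):
with 3–4 replicates per group, medians discard too much information and
the mean is the natural estimator for the mean-unbiased multiplicative
noise model below. Metabolites with nonpositive numerator or denominator
means are dropped with a warning and recorded in the provenance table, so
all retained ratios are strictly positive — a precondition for the
sign-preserving bound update. Metabolite-to-model mapping is an explicit
user-supplied table; no fuzzy name matching is attempted, because silent
mis-mapping is the dominant failure mode in metabolomics–model
integration.

### Bound parameterization

For each measured metabolite with exchange reaction $e$ and reference
flux $v^*$, the new bound is $b = v^* \cdot r$ applied to the *active
side only*: the lower bound if $v^* < 0$ (uptake), the upper bound if
$v^* > 0$ (secretion). The opposite bound is untouched. Rescaling one
side reinterprets the ratio as scaling the *demonstrated exchange
capacity*; fixing both bounds would pin the exchange flux, collapse its
variability range to a point, and make range comparison meaningless.
Since $r > 0$, the update never flips an exchange between
uptake-capable and secretion-only.

Exchanges whose reference flux is zero carry no demonstrated capacity to
rescale. The default policy (`leave`) keeps their bounds and records them
in the returned model's provenance; `clamp` closes them to $[0, 0]$
(strict reading: no demonstrated exchange, no allowed exchange) and
`epsilon` leaves a small symmetric window ($10^{-6} \times$
`default_bound`). `leave` is the default because the alternatives inject
strong assumptions the measurements do not support.

### Loopless flux variability

`fva()` computes per-reaction flux minima and maxima subject to the
biomass fraction and, when `pfba_factor` is set, a total-flux cap
$\sum_i |v_i| \le$ `pfba_factor` $\times$ (minimum total flux *at the
same biomass fraction*). The cap is deliberately relative to the
*constrained* minimum ("at most 10% more than necessary"), with one
documented consequence: raising `fraction_of_optimum` raises the minimum
necessary total flux and thereby *loosens* the cap, so range
monotonicity in the fraction is only guaranteed with the cap disabled.
The test suite asserts monotonicity exactly in the regimes where the
feasible sets nest (fraction with cap off; cap factor at fixed
fraction).

Loopless post-processing follows the cycle-free flux idea as implemented
in the standard constraint-based toolkits: at each per-reaction optimum,
fix all exchange fluxes, restrict every internal flux to the sign and
magnitude it has in the optimal solution, and minimize the internal
$L_1$ norm. If the scored reaction keeps its optimal flux, the optimum
was loop-free and is reported as is. Otherwise the reaction is pinned at
its optimum, the minimization is repeated, and the reactions that are
zero in the unpinned but nonzero in the pinned solution — the loop
partners — are closed in the outer problem, which is then re-optimized.
This keeps the whole analysis LP-only; mixed-integer loopless
formulations are out of scope. The exported `remove_loops()` applies the
same construction to a single flux distribution, with an
objective-equality constraint so the returned distribution has identical
exchange fluxes and objective value.

### Altered-flux calls

A bound pair $(a, b)$ differs iff
$|a - b| > \max(\texttt{abs\_tol}, \texttt{rel\_tol} \cdot \max(|a|, |b|))$,
with defaults `abs_tol` $= 10^{-6}$ and `rel_tol` $= 10^{-4}$. A strict
equality test would flag essentially every reaction due to solver
arithmetic; the two-tier tolerance separates numerical jitter from real
bound movement at both small and large flux magnitudes. Both tolerances
are exposed on the function, the config file, and the CLI.

The direction call summarizes signed bound movement from A to B:
**decreased** when at least one bound moved down (beyond tolerance) and
none moved up, **increased** for the mirror image, **mixed** when bounds
moved both ways. This formulation was chosen over the superficially
simpler "upper dropped while lower held" rule because the latter
misclassifies the most important case — a range that shifts bodily
downward, as the pentose-phosphate reactions do under a glucose
knockdown ($[4.5, 5] \to [2.25, 2.5]$) — and because it is exactly
antisymmetric: swapping the conditions exchanges increased and
decreased, which the test suite verifies property-style. Note the sign
convention for uptake exchanges: less uptake capability means the
(negative) bounds move toward zero, i.e. *up*, so a glucose knockdown
reports uptake exchanges as "increased" while every dependent internal
pathway is "decreased". The binary `altered` call is always reported
alongside the direction and never replaced by it.

## Numerical design

The LP kernel is a dense two-phase primal tableau simplex written for
this package: problems here are small (tens of variables and rows), but
flux polytopes are highly degenerate, so the kernel uses Dantzig pricing
with a switch to Bland's rule after a burn-in (guaranteeing
termination), lowest-index tie-breaking in both pricing and the ratio
test, and a fixed variable ordering derived from reaction order. Every
solve is therefore bit-reproducible, which propagates to byte-identical
pipeline reports — an explicitly tested property. Pivot and feasibility
tolerances are $10^{-9}$; post-hoc invariant checks (mass balance,
bounds) are asserted at $10^{-6}$; FVA range pairs whose min exceeds
their max by less than $10^{-9}$ are clamped to their midpoint. Fluxes
with magnitude below $10^{-6}$ are treated as zero in loop detection.
The kernel is validated in the test suite against an independent
reference implementation (run through the `python` interpreter) on the
bundled fixtures, to $10^{-6}$ on every objective, flux, and range
bound.

## The toy model

Desk-scale testing uses a hand-analyzable 16-metabolite, 20-reaction
single-compartment network: glucose exchange (uptake bound $-10$),
lumped glycolysis, an oxidative pentose-phosphate branch producing
NADPH (2 per glucose-6-phosphate) and ribulose-5-phosphate with a lumped
non-oxidative return to glycolysis, a TCA cycle with pyruvate-carboxylase
anaplerosis, amino-acid exchanges (glutamine, glycine, serine, arginine;
uptake bounds $-5$), a biomass reaction consuming pyruvate,
ribulose-5-phosphate, NADPH, 2-oxoglutarate and the amino acids, and a
deliberately loop-forming irreversible citrate/isocitrate pair whose
intermediate is otherwise dead-ended. Its optima are derivable by hand:
the biomass optimum is 10 (glucose- and glutamine-limited
simultaneously), the parsimonious total flux is 70, and the NADPH
balance forces the oxidative PPP flux to exactly half the biomass flux —
which is what makes the PPP the cleanest readout of a glucose
knockdown. A separate 5-reaction diamond fixture provides the
route-selection algebra (parsimonious total flux 30; with a 1.1
total-flux cap the long route is bounded by 3 and the short route by
$[7, 10]$).

## The synthetic-data generator

`flux_scenario()` / `generate_abundance()` emulate the targeted
metabolomics design the pipeline expects: two conditions, timepoints 0 h
and 20 h, 4 replicates per group by default (the typical 3–4 animals per
group of such designs), strictly positive abundances, and genotype- and
metabolite-specific true fold changes. Replicate noise is multiplicative
log-normal with mean correction: $\varepsilon \sim
N(-\sigma^2/2, \sigma^2)$, $\sigma^2 = \log(1 + \mathrm{cv}^2)$, so the
expected abundance equals the deterministic part and the coefficient of
variation equals `noise_cv` (default 0.2, a typical targeted LC/GC-MS
replicate spread). Baseline means (default 30–100 instrument units per
metabolite) are arbitrary scale factors: ratios cancel them exactly.

`knockdown_scenario()` multiplies condition B's glucose fold change by
`strength` (default 0.5) and attaches the per-reaction ground truth of
the resulting differential analysis on the toy model, derived once by
exhaustive LP analysis with an independent solver. Because every
non-trivial flux bound of the toy model scales linearly with the
glucose-limited biomass optimum, the altered set is the same for any
strength meaningfully below 1 (17 of 20 reactions; the forced-zero
non-oxidative PPP step and the closed 2-cycle are unchanged).

The generator deliberately does **not** emulate instrument drift, batch
effects, missingness, censoring at detection limits, or correlated
replicate structure. Passing recovery tests therefore demonstrates that
the pipeline's inference is correct *under its own noise model*, not
that real kidney or liver metabolomics would behave as cleanly; with
real data the ratio estimates inherit whatever normalization and batch
structure the upstream processing left in.

## Problem sizes and runtime choices

All tests and the acceptance script run on the toy fixtures: 20-reaction
FVA (two models per differential run) takes well under a second, a full
differential run under one second, and the Monte-Carlo recovery study
(20 seeds at 4 replicates, CV 0.2) under half a minute on one CPU. These
sizes were chosen so the entire evidence base is exhaustively
re-checkable against hand algebra and an independent solver; the
implementation itself has no toy-specific shortcuts and accepts any
model expressible in the JSON dialect or the SBML subset.

## Known limitations

* The SBML support is a deliberate subset (species, reactions, FBC
  bounds, one active objective, subsystem/artificial flags in notes);
  kinetic laws, gene–protein–reaction rules, groups and annotations are
  ignored on read with a warning.
* Loopless analysis is the LP cycle-free formulation, not the
  mixed-integer loop-law; like the toolkits it mirrors, it removes
  cycles per scored optimum rather than globally forbidding them.
* The altered-flux call is deterministic, not a statistical test: it
  propagates mean abundance ratios, not their replicate uncertainty. A
  resampling wrapper around `run_differential()` would be the natural
  extension.
* Ratios are taken as-is (no truncation of extreme fold changes); a
  metabolite measured at only one timepoint is dropped from ratios and
  its exchange left untouched, both recorded in provenance.
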