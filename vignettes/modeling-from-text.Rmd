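---
title: "From reaction text to executable ODE models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From reaction text to executable ODE models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactode)
```

reactode turns a plain-text list of biochemical reactions into an executable
ODE model of a signaling network, constrains its rate constants by
thermodynamic detailed balance, and provides the machinery around that core:
simulation under stimulus conditions, ensemble fitting to time-course data,
local sensitivity analysis, import of KEGG KGML pathway files, and
literature co-occurrence weighting of pathway graphs. This vignette explains
the model, the numerical choices, and the design decisions that were
genuinely open — and what the synthetic-fixture tests do and do not show
about real data.

## The reaction language and its rate laws

A model is a text file with one reaction per line:

```
A binds B --> AB
E phosphorylates S --> pS
S is phosphorylated --> pS
TF transcribes M
M is translated into P
X is degraded
X is synthesized
```

Each verb carries a kinetic meaning through a user-extensible registry
(`defaultRateLaws()`, `registerRateLaw()`):

| line form | rate law | parameters (defaults, fit bounds) |
|---|---|---|
| `A binds B --> AB` (and `is dissociated into`) | reversible mass action, $v = k_f[A][B] - k_r[AB]$ | $k_f, k_r$ (1, $[10^{-3}, 10^3]$) |
| `E phosphorylates S --> pS` | Michaelis–Menten, $v = V[E][S]/(K+[S])$ | $V, K$ |
| `S is phosphorylated --> pS` | reversible first-order mass action | $k_f, k_r$ |
| `pS is dephosphorylated --> S` | irreversible first-order mass action | $k_f$ |
| `TF transcribes M` | Hill, $v = V[TF]^n/(K^n+[TF]^n)$ | $V, K, n$ ($n = 2$, bounds $[1,4]$) |
| `M is translated into P` | first order in the template, template not consumed | $k_f$ |
| `X is degraded` / `X is synthesized` | first order / zeroth order | $k_f$ |

Open choices fixed here, and why:

* **The enzyme concentration multiplies $V$** in the Michaelis–Menten
  template. Folding the enzyme into $V$ makes the enzyme a dead parameter
  and silently breaks enzyme-knockdown simulations; the explicit form is the
  standard signaling-model convention.
* **Unary "is phosphorylated" is reversible; enzymatic "phosphorylates" is
  irreversible MM.** A catalyzed modification is driven and effectively
  irreversible on signaling timescales; a bare state transition with no
  driver should relax both ways.
* **"is dephosphorylated" is irreversible.** It exists mainly as the
  first-order reversion the KGML converter auto-adds for active forms; a
  reversible version would re-phosphorylate without any kinase.
* **Enzymes and the mRNA template of translation are modifiers**, not
  consumed: their stoichiometric column entries are zero (catalyst
  conservation), though they drive the rate.
* Parameters are reaction-scoped (`kf_r3`), species are enumerated in
  first-appearance order, and compilation is deterministic, so two compiles
  of the same text are byte-comparable.

Directives carry everything that is not a reaction: `@obs` (named linear
combinations of species — the observables compared to data), `@init`
(initial amounts, default 0), `@sim_condition` (named initial-override
sets), `@param_bound` (per-parameter fitting boxes).

## Detailed balance on reaction cycles

If reversible reactions form a closed loop — the canonical case being two
assembly routes to the same complex, `A+B⇌AB`, `AB+C⇌ABC`, `A+C⇌AC`,
`AC+B⇌ABC` — then at thermodynamic equilibrium the product of equilibrium
constants around the loop must be 1 (the Wegscheider condition). Arbitrary
rate constants violate it, producing a model whose "equilibrium" carries a
perpetual circulating flux.

**How cycles are found.** A vector $n$ over the reversible mass-action
reactions with $S_{rev} n = 0$ (right null space of the reversible
stoichiometric submatrix) is exactly a closed loop: running each reaction
$n_i$ times returns every species to its starting amount, and detailed
balance requires $\prod_i K_{eq,i}^{n_i} = 1$. `cycleBasis()` computes an
integer basis of that null space by exact rational row reduction. This is a
deliberate design choice over a species- or composition-graph encoding:
graph encodings miss loops whose edges share no node (the binding diamond's
two routes pass through disjoint composition states — its composition graph
has 7 nodes, 4 edges, 3 components and no graph cycle, yet the
thermodynamic loop is real). The null-space dimension is the exact count of
independent loops; for the diamond it is 1. `buildReversibleGraph()` still
exposes the composition graph for inspection and reporting.

**Which parameter each loop determines.** Per cycle, the reverse rate
constant of the highest-indexed reaction not already derived becomes a
derived parameter (`assignConstraints()`), computed at every use from the
free ones: $K_{eq,d} = \prod_{i \ne d} K_{eq,i}^{-n_i/n_d}$, $k_{r,d} =
k_{f,d}/K_{eq,d}$. The anchoring at the highest index is deterministic and
lets auto-added (late) reactions yield to curated (early) ones. Free
parameters drop by exactly one per independent cycle — for the diamond,
8 → 7.

**What the constrained model guarantees** (and the tests check): the
equilibrium reached from different initializations with the same conserved
totals is identical, and every reaction is *individually* equilibrated —
its reaction quotient equals its $K_{eq}$ — so both assembly routes predict
the same complex abundance. Without the constraint the system still reaches
a unique steady state, but a non-equilibrium one: the realized quotients
match no consistent $K_{eq}$ assignment and a circulating flux persists.
The violation is therefore asserted on reaction quotients, not on
initialization dependence of the long-run state (which, numerically, does
not distinguish the two cases for this network).

## Simulation and normalization

`integrateModel()` uses a stiff-capable solver (deSolve's lsoda) at
relative tolerance $10^{-8}$ and absolute tolerance $10^{-10}$
(configurable). Stimuli are initial-amount overrides at $t=0$ — the ligand
is added to the dish — rather than time-varying inputs; this is the
simplest scheme faithful to growth-factor addition experiments. States in
$[-10^{-8}, 0)$ are clipped to zero as integrator noise; anything more
negative is treated as a solver failure, so numerical noise and genuine
model pathology are not conflated.

Observables are normalized immunoblot-style: within one observable, across
*all* conditions of a dataset, every value is divided by the common maximum
(so the maximum is exactly 1). Band intensities are comparable within a
blot but not across antibodies; sharing the scale across conditions (not
per condition) preserves the relative amplitudes that distinguish stimuli.

Conserved moieties — integer left-null vectors of the stoichiometric
matrix, computed by the same exact kernel routine and combined toward
nonnegative weights — are used as invariants: along every trajectory each
conserved total must stay constant to $10^{-6}$ relative, which is the
package's primary guard against integration and stoichiometry bugs.

## Fitting: objective, optimizer, ensembles

The objective is the sum of squared differences between *normalized*
simulation and *normalized* data over exactly the data's (observable,
condition, time) points; when the data carry standard deviations, residuals
are divided by the (identically scaled) sd. Both sides are normalized per
observable group by their maximum over those data points. Normalizing the
simulation over a denser grid would make a model evaluated at its own
generating parameters score nonzero whenever the trajectory peaks between
data points; evaluating both sides on the same support keeps the
self-consistency identity exact (cost at the generating parameters of
noiseless synthetic data is 0). Solver failures score a large finite
penalty ($10^{10}$) so the search can move off pathological regions.

Optimization is a seeded differential-evolution search in $\log_{10}$
parameter space (rand/1/bin, $F = 0.8$, $CR = 0.9$), one independent run
per requested parameter set, each followed by a Nelder-Mead polish clamped
to the bounds. Nelder-Mead was chosen for the polish because the
max-normalization makes the objective piecewise smooth: whichever data
point currently attains the group maximum switches under parameter changes,
and the resulting kinks stall gradient-based refinement well above the
noise floor, while the simplex walks through them. Detailed-balance
constraints are re-applied at every evaluation, so every visited parameter
vector is thermodynamically consistent. The "ensemble" is a multi-start
collection ordered by cost — a spread of plausible fits, not a posterior
sample — and `ensembleSummary()` reports the pointwise mean and sd of the
normalized member trajectories, the usual way fits averaged across
parameter sets are displayed.

## Sensitivity analysis

`sensitivityCoefficients()` reports normalized log-log finite differences,
$s = \ln(q(p \cdot f)/q(p)) / \ln f$ with $f = 1.01$ — the
metabolic-control-analysis convention, dimensionless and comparable across
parameters. Only free parameters are perturbed; derived parameters follow
their constraint formula so each perturbed model remains thermodynamically
consistent. Reaction-level coefficients multiply one reaction's rate
instead. Response metrics (time integral, maximum, value at a time, of one
observable under one condition) are user-supplied: no single "drug target"
metric is privileged. The implementation is validated against the closed
form $s = -kT$ for first-order decay.

## KGML import

`parseKgml()` reads KEGG KGML (entries with types and graphics labels;
relations with types and subtypes), taking the first comma-separated token
of the graphics name as the display name (the KEGG convention lists the
primary symbol first; which alias the original curators picked is not
knowable, so the first is used). `expandStates()` adds the intermediate
active species KGML leaves implicit: every gene or group entry targeted by
an activating relation gains one active form, named `p`+name when
phosphorylation is evidenced among the incoming subtypes and `a`+name
otherwise (collision-checked), and the entry's outgoing relations are
re-sourced from the active form — signals propagate through active
proteins.

`networkToText()` maps relation subtypes to lines: expression →
`transcribes`; binding/association → `binds`; activation and/or
phosphorylation → `phosphorylates` (into `pT` or `aT`); inhibition or
dephosphorylation → `dephosphorylates` on the target's active form.
Subtypes in the skip set (default: `indirect effect`, which is not a
mechanistic reaction) are dropped and counted; any other unmapped subtype
is an error rather than a guess. Deactivations of a target that was never
activated have no species to act on and are counted as skipped with a
reason. With `addReverse` (default), every active form lacking an explicit
deactivator gains a first-order reversion line, and `degrade` lists extra
degradation lines — both reified as options so that what would otherwise
be manual curation steps are scriptable and reproducible. Group entries
become one complex species joining member names with `_` (KGML groups
denote complexes); compound and map entries are excluded from reaction
generation because KGML encodes no kinetics for them. Every conversion
returns full provenance (each line maps to exactly one relation or one
option) and a count report, and its output is guaranteed to re-parse.

## Literature co-occurrence weights

Weighting is document-level: a gene counts once per document mentioning it
(case-folded exact match, no synonym expansion — alias handling is the
caller's responsibility, keeping the counts deterministic and auditable),
and a gene pair counts in documents mentioning both. The enrichment of a
query-filtered corpus over the background is a pseudocounted rate ratio

$$\mathrm{fold} = \frac{(c_q + \pi)/(N_q + 2\pi)}{(c_b + \pi)/(N_b + 2\pi)},
\qquad \pi = 0.5,$$

chosen as the simplest statistic that is finite for zero counts and
exactly 1 when query and background coincide. No significance testing is
attached — the folds feed node-size/edge-width overlays
(`annotateNetwork()`) for visual comparison of contexts (e.g. two cell
lines), not hypothesis tests.

## Synthetic fixtures: what the tests show

All fixtures are pure functions of their arguments and a seed.

* **Toy KGML** pathways have gene entries and relations with realistic
  subtype structure but random topology; they exercise parsing, state
  expansion and conversion, not pathway biology.
* **Toy corpora** plant a co-mention signal: query documents (30% of the
  corpus) mention enriched genes with probability 0.8 versus 0.2 baseline,
  giving an expected fold around 2.1 — comfortably detectable at 200
  documents, which is what the calibration test asserts (> 1.5). The
  no-signal band check (folds within [0.5, 2] at 500 documents) bounds the
  sampling noise of the statistic.
* **The turnover model** (synthesis → reversible activation → degradation
  of the active form, both forms observed) is the recovery benchmark. It is
  studied under two conditions, basal ($A_0 = 1$) and pulse ($A_0 = 3$),
  13 timepoints over 5 time units each (52 data points), with 5%
  multiplicative lognormal noise — lognormal because immunoblot intensities
  are positive with roughly constant coefficient of variation. The second
  condition is part of the study design, not a convenience: with a single
  condition the normalized shapes admit a degenerate exchange-only fit
  (synthesis and degradation switched off), an instructive reminder that
  normalization destroys scale information; the shared normalization across
  two conditions restores the relative amplitudes and makes all rate
  parameters practically identifiable (noiseless refits recover them to
  well under 1%). Fits use 10 parameter sets, population 16, 1500
  evaluations each — sizes chosen so the whole benchmark runs in minutes on
  one CPU while recovering parameters well within the 25% target at 5%
  noise.

Passing these tests demonstrates that the machinery is correct — parsing is
lossless, integration conserves what stoichiometry says it must,
constraints hold to machine precision, the optimizer finds planted truths,
counting matches brute force. It does not demonstrate that any real
pathway's kinetics are identifiable from any real dataset: real immunoblot
data have unknown noise structure, model misspecification, and far fewer
effective degrees of freedom than these clean fixtures.

## Degenerate inputs and numerical corner cases

* Empty model files, duplicate reaction lines, unknown verbs and malformed
  overrides are parse errors, aggregated so one pass reports every bad
  line; arbitrary byte strings never crash the parser.
* All-zero observable groups cannot be normalized and error out (rather
  than producing NaN trajectories downstream).
* A zero baseline metric makes log-sensitivities undefined and errors with
  the metric's name.
* Zero-duration simulations return the initial state; `times = [0]` is
  legal.
* Integer kernels are computed with rational arithmetic on small-integer
  matrices; vectors are verified against the matrix exactly, so conserved
  moieties and cycle exponents are exact integers, not floats.
* The fitting objective treats solver failure as a finite penalty, never an
  exception, so a single pathological trial vector cannot abort a run.

## Known limitations

* No compartments, volumes, events, delays, or algebraic rules; no SBML.
* Michaelis-Menten and Hill reactions are irreversible by construction and
  take no part in detailed-balance constraints; free energies are not
  modeled.
* Co-occurrence matching is exact-string; synonymy and entity normalization
  must happen upstream.
* The ensemble spread is not an uncertainty quantification; no profile
  likelihood or MCMC is provided.
* KGML conversion covers the relation subtypes listed above; others must be
  explicitly skipped or the conversion fails loudly.
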