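# reactode

Executable ODE models of signaling networks from a plain-text reaction
language.

Mechanistic modeling of signaling pathways usually starts with a hand-written
system of differential equations — a bottleneck and an error source the
moment a model grows past a dozen reactions. reactode is for systems
biologists who want to keep the model in a form a human (or a pathway
database, or a language model) can produce and review: a text file with one
biochemical reaction per line. The package compiles that text into an ODE
system, keeps it thermodynamically honest, and provides the standard
analysis loop around it — simulate, fit to time-course data, rank
sensitivities — plus importers that generate model text from KEGG KGML
pathway files and literature co-occurrence weights for pathway graphs.

The core pieces:

* **Reaction language → ODEs.** `A binds B --> AB` becomes reversible mass
  action `v = kf·[A][B] − kr·[AB]`; `E phosphorylates S --> pS` becomes
  Michaelis–Menten `v = V·[E][S]/(K+[S])`; `TF transcribes M` becomes a Hill
  term `v = V·[TF]^n/(K^n+[TF]^n)`. The verb→rate-law mapping lives in a
  registry you can extend or override (`registerRateLaw()`).
* **Detailed balance.** Closed loops of reversible reactions are detected as
  the integer null space of the reversible stoichiometric submatrix; each
  independent loop must satisfy the Wegscheider condition
  `∏ Keq^n = 1`, so one reverse rate constant per loop becomes a derived
  parameter (`assignConstraints()`), removing a free variable and the
  unphysical circulating flux.
* **Simulation & fitting.** Stiff integration (deSolve), immunoblot-style
  normalization (each observable scaled by its maximum across all
  conditions), and seeded multi-start differential evolution in log10 space
  producing a parameter ensemble whose mean ± sd trajectory is reported
  (`fitEnsemble()`, `ensembleSummary()`).
* **Sensitivity.** Log-log finite-difference coefficients
  `s = ln q(1.01·p)/q(p) / ln 1.01` per free parameter or per reaction
  (`sensitivityCoefficients()`).
* **Knowledge import.** `parseKgml()` / `expandStates()` /
  `networkToText()` turn a KGML pathway into model text, adding the active
  intermediate species KGML leaves implicit and the reverse reactions they
  need; `countWeights()` / `cooccurrenceEnrichment()` /
  `annotateNetwork()` overlay query-vs-background literature co-occurrence
  folds on the pathway graph. A three-part prompt builder and an output
  validator (`buildLlmPrompt()`, `validateLlmOutput()`) support
  LLM-assisted model drafting without any network call.

## Worked example

```r
library(reactode)

txt <- "A binds B --> AB | kf=1, kr=1
@init A = 1
@init B = 1
@obs AB: AB"
model <- assignConstraints(compileModel(parseRxnModel(txt)))
tr <- integrateModel(model, times = c(0, 10^seq(0, 3, length.out = 8)))
tail(tr$states, 1)
#>             A        B       AB
#> [9,] 0.618034 0.618034 0.381966
```

At equilibrium `[AB]/([A][B]) = kf/kr = 1`, i.e. `AB = (3 − √5)/2 ≈
0.381966` — the solver lands on the closed-form root to 7 digits.

The binding diamond (two assembly routes to one ternary complex) shows the
thermodynamic constraint at work:

```r
d <- assignConstraints(compileModel(parseRxnModel(makeDiamondModel())))
cat(constraintReport(d))
#> Cycle 1: reactions r1, r2, r3, r4 (lines 1, 2, 3, 4), traversal --++
#>   derived: kr_r4 = kf_r4 / ((kf_r1/kr_r1)^1 * (kf_r2/kr_r2)^1 * (kf_r3/kr_r3)^-1)
length(freeParameters(d))  # 8 rate constants, 1 cycle -> 7 free
#> [1] 7
```

One cycle is found; `kr_r4` is derived from the other equilibrium constants
so the loop product is exactly 1, and the number of free parameters drops
from 8 to 7. Setting `Keq1=2, Keq2=3, Keq3=4` forces `Keq4 = 2·3/4 = 1.5`.

Converting a KGML pathway (here a seeded toy fixture) to model text:

```r
xml <- makeToyKgml(5, 4, seed = 7)
conv <- networkToText(expandStates(parseKgml(xml)))
cat(conv$text)
#> G3 phosphorylates G5 --> aG5
#> G4 phosphorylates G2 --> pG2
#> G3 binds G1 --> G3_G1
#> pG2 is dephosphorylated --> G2
#> aG5 is dephosphorylated --> G5
```

Activating relations became enzymatic phosphorylations into `p`/`a` active
forms, binding became a reversible complex, and each active form got the
first-order reversion KGML does not store. The text re-parses with
`parseRxnModel()` and compiles like any hand-written model.

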