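Package: reactode
Title: Executable ODE Models of Signaling Networks from a Plain-Text
    Reaction Language
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles a line-oriented, natural-language-like reaction
    description language into executable ordinary differential equation
    models of signaling networks, with mass-action, Michaelis-Menten and
    Hill rate laws drawn from a user-extensible registry. Detects closed
    loops of reversible reactions and constrains rate constants by the
    thermodynamic principle of detailed balance (Wegscheider condition).
    Imports KEGG KGML pathway XML, expands intermediate active states and
    emits model text; weights pathway nodes and edges by literature
    co-occurrence of gene mentions under query-filtered versus background
    corpora. Includes stiff ODE simulation with immunoblot-style
    normalization, seeded evolutionary parameter-ensemble fitting to
    time-course data, local log-log sensitivity analysis, DOT/GraphML
    graph export, and seeded synthetic-fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    xml2
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
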