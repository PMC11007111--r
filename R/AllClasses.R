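#' @import methods
NULL

#' Parsed reaction model
#'
#' Container for a model parsed from the plain-text reaction language: an
#' ordered list of reactions plus directives (`@obs`, `@init`,
#' `@sim_condition`, `@param_bound`). Each reaction is a named list with
#' elements `type`, `reactants`, `products`, `enzyme`, `reversible`,
#' `family`, `overrides`, `line`, `mentionOrder`.
#'
#' @slot reactions list of parsed reactions, in file order.
#' @slot directives list of parsed directives.
#' @slot source character scalar naming the input (file name or "<text>").
#' @seealso [parseRxnModel()], [compileModel()]
#' @export
setClass("RxnModel", representation(
  reactions  = "list",
  directives = "list",
  source     = "character"
))

setValidity("RxnModel", function(object) {
  if (length(object@reactions) < 1L) return("a model needs at least one reaction")
  lines <- vapply(object@reactions, function(r) r$line, numeric(1))
  if (anyDuplicated(lines)) return("reaction line numbers must be unique")
  TRUE
})

#' Compiled ODE model
#'
#' An executable ODE system: species with initial amounts, a parameter
#' table, per-reaction rate closures, the stoichiometric matrix, named
#' observables (linear combinations of species), simulation conditions and
#' (after [assignConstraints()]) detailed-balance cycle constraints.
#'
#' @slot species character vector of species names, first-appearance order.
#' @slot initials named numeric vector of initial amounts (default 0).
#' @slot parameters data.frame with columns name, value, lower, upper,
#'   status ("free", "fixed" or "derived") and reaction index.
#' @slot reactions list of compiled reaction descriptors (indices into the
#'   species vector and parameter table, plus a rate closure and a symbolic
#'   expression string).
#' @slot stoich integer matrix, species x reactions; column j holds -1 for
#'   each consumed species and +1 for each produced species of reaction j.
#'   Enzymes and templates (catalysts) do not appear.
#' @slot observables named list of named numeric coefficient vectors.
#' @slot conditions named list of initial-override vectors declared with
#'   `@sim_condition` directives.
#' @slot constraints list of detailed-balance cycle constraints (empty
#'   until [assignConstraints()] is applied).
#' @slot fastRate zero- or one-element list holding a vectorized rate
#'   evaluator compiled from the built-in rate-law families; empty when any
#'   reaction uses a custom template (those evaluate via their closures).
#' @export
setClass("OdeModel", representation(
  species     = "character",
  initials    = "numeric",
  parameters  = "data.frame",
  reactions   = "list",
  stoich      = "matrix",
  observables = "list",
  conditions  = "list",
  constraints = "list",
  fastRate    = "list"
))

setValidity("OdeModel", function(object) {
  n <- length(object@species)
  if (anyDuplicated(object@species)) return("species names must be unique")
  if (length(object@initials) != n) return("one initial amount per species")
  if (any(object@initials < 0)) return("initial amounts must be nonnegative")
  if (nrow(object@stoich) != n) return("stoichiometric matrix rows != species")
  if (ncol(object@stoich) != length(object@reactions))
    return("stoichiometric matrix columns != reactions")
  p <- object@parameters
  need <- c("name", "value", "lower", "upper", "status", "reaction")
  if (!all(need %in% names(p))) return("malformed parameter table")
  if (anyDuplicated(p$name)) return("parameter names must be unique")
  bad <- p$status != "derived" & (p$value < p$lower | p$value > p$upper)
  if (any(bad)) return(paste("parameter outside bounds:", p$name[bad][1]))
  TRUE
})

#' KGML-derived pathway network
#'
#' Entries (genes, compounds, groups, maps) and typed, subtyped relations
#' parsed from a KEGG KGML file, before or after intermediate-state
#' expansion. After [expandStates()], `species` maps each gene/group entry
#' to its base and (when activated) active-form species, and relations
#' carry the species they act through.
#'
#' @slot entries data.frame: id, type, display, members.
#' @slot relations data.frame: source, target, type, subtypes
#'   (";"-separated), plus sourceSpecies/targetBase/targetActive after
#'   expansion.
#' @slot stateExpanded logical flag guarding idempotence of expansion.
#' @slot species data.frame: species, entry, form ("base"/"active"),
#'   baseOf.
#' @export
setClass("PathwayNetwork", representation(
  entries       = "data.frame",
  relations     = "data.frame",
  stateExpanded = "logical",
  species       = "data.frame"
))

setValidity("PathwayNetwork", function(object) {
  e <- object@entries
  if (nrow(e) && anyDuplicated(e$id)) return("entry ids must be unique")
  r <- object@relations
  if (nrow(r)) {
    known <- r$source %in% e$id & r$target %in% e$id
    if (!all(known)) return("relation endpoints must reference entries")
  }
  TRUE
})

#' Document co-occurrence weight table
#'
#' Document-level occurrence counts of genes (nodes) and gene pairs
#' (edges) in an annotated corpus: the number of documents mentioning a
#' gene, or both genes of a pair, out of `nDocs` documents.
#'
#' @slot nDocs total number of documents counted.
#' @slot nodes named numeric vector of per-gene document counts.
#' @slot edges named numeric vector of per-pair document counts; names are
#'   "A|B" with the pair sorted.
#' @export
setClass("WeightTable", representation(
  nDocs = "numeric",
  nodes = "numeric",
  edges = "numeric"
))

setValidity("WeightTable", function(object) {
  if (object@nDocs < 0) return("nDocs must be nonnegative")
  if (any(object@nodes > object@nDocs)) return("node count exceeds corpus size")
  if (length(object@edges)) {
    for (k in names(object@edges)) {
      gh <- strsplit(k, "|", fixed = TRUE)[[1]]
      cap <- min(object@nodes[gh], na.rm = TRUE)
      if (is.finite(cap) && object@edges[[k]] > cap)
        return(paste("edge count exceeds endpoint count:", k))
    }
  }
  TRUE
})

#' Fitted parameter ensemble
#'
#' Result of multi-start evolutionary fitting: one full parameter vector
#' per independently seeded optimization run, ordered by final cost.
#'
#' @slot parameters numeric matrix, one row per set, columns named by
#'   parameter; derived (detailed-balance) entries already applied.
#' @slot costs final objective value per set (ascending).
#' @slot seeds RNG seed used for each set.
#' @slot evaluations number of objective evaluations spent per set.
#' @slot freeNames names of the parameters that were actually optimized.
#' @export
setClass("ParameterEnsemble", representation(
  parameters  = "matrix",
  costs       = "numeric",
  seeds       = "numeric",
  evaluations = "numeric",
  freeNames   = "character"
))

setValidity("ParameterEnsemble", function(object) {
  n <- nrow(object@parameters)
  if (length(object@costs) != n || length(object@seeds) != n ||
      length(object@evaluations) != n)
    return("one cost/seed/evaluation count per parameter set")
  if (is.unsorted(object@costs)) return("ensemble must be ordered by cost")
  TRUE
})
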