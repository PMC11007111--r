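#' Accessors and generics
#'
#' Small accessor generics used across the package's S4 containers.
#' @param x an object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("directives", function(x) standardGeneric("directives"))

#' @rdname accessors
#' @export
setGeneric("parameterTable", function(x) standardGeneric("parameterTable"))

#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname accessors
#' @export
setGeneric("observables", function(x) standardGeneric("observables"))

#' @rdname accessors
#' @export
setGeneric("freeParameters", function(x) standardGeneric("freeParameters"))

#' Export a model or pathway network as graph text
#'
#' Writes a DOT or GraphML representation of a compiled model (species
#' nodes, reaction edges; catalytic edges styled dashed) or of a pathway
#' network (entry nodes, relation edges). Optional weights attach node
#' `size` and edge `width` attributes, as used for literature co-occurrence
#' enrichment overlays.
#'
#' @param x an [OdeModel-class] or [PathwayNetwork-class].
#' @param format "dot" or "graphml".
#' @param weights optional list with elements `nodes` (named numeric) and
#'   `edges` (named numeric, names "A|B"); missing entries default to 1.
#' @param file optional path; when given the text is also written there.
#' @param ... unused.
#' @return the graph text, invisibly when `file` is given.
#' @export
setGeneric("exportGraph", function(x, format = c("dot", "graphml"),
                                   weights = NULL, file = NULL, ...)
  standardGeneric("exportGraph"))

#' @rdname accessors
#' @export
setMethod("speciesNames", "OdeModel", function(x) x@species)

#' @rdname accessors
#' @export
setMethod("reactions", "RxnModel", function(x) x@reactions)

#' @rdname accessors
#' @export
setMethod("reactions", "OdeModel", function(x) x@reactions)

#' @rdname accessors
#' @export
setMethod("directives", "RxnModel", function(x) x@directives)

#' @rdname accessors
#' @export
setMethod("parameterTable", "OdeModel", function(x) x@parameters)

#' @rdname accessors
#' @export
setMethod("stoichiometry", "OdeModel", function(x) x@stoich)

#' @rdname accessors
#' @export
setMethod("observables", "OdeModel", function(x) x@observables)

#' @rdname accessors
#' @export
setMethod("freeParameters", "OdeModel", function(x) {
  p <- x@parameters
  p$name[p$status == "free"]
})

setMethod("show", "RxnModel", function(object) {
  cat(sprintf("RxnModel '%s': %d reactions, %d directives\n",
              object@source, length(object@reactions), length(object@directives)))
  for (r in object@reactions[seq_len(min(5, length(object@reactions)))])
    cat("  ", renderReaction(r), "\n", sep = "")
  if (length(object@reactions) > 5) cat("  ...\n")
})

setMethod("show", "OdeModel", function(object) {
  p <- object@parameters
  cat(sprintf("OdeModel: %d species, %d reactions, %d parameters (%d free, %d derived)\n",
              length(object@species), length(object@reactions), nrow(p),
              sum(p$status == "free"), sum(p$status == "derived")))
  cat(sprintf("  observables: %s\n",
              if (length(object@observables)) paste(names(object@observables), collapse = ", ")
              else "none"))
  if (length(object@constraints))
    cat(sprintf("  detailed-balance cycles: %d\n", length(object@constraints)))
})

setMethod("show", "PathwayNetwork", function(object) {
  cat(sprintf("PathwayNetwork: %d entries, %d relations%s\n",
              nrow(object@entries), nrow(object@relations),
              if (object@stateExpanded) sprintf(", %d species (state-expanded)",
                                                nrow(object@species)) else ""))
})

setMethod("show", "WeightTable", function(object) {
  cat(sprintf("WeightTable: %d documents, %d genes, %d gene pairs\n",
              object@nDocs, length(object@nodes), length(object@edges)))
})

setMethod("show", "ParameterEnsemble", function(object) {
  cat(sprintf("ParameterEnsemble: %d sets, %d parameters (%d fitted)\n",
              nrow(object@parameters), ncol(object@parameters),
              length(object@freeNames)))
  cat(sprintf("  best cost %.4g (seed %d), worst %.4g\n",
              object@costs[1], as.integer(object@seeds[1]),
              object@costs[length(object@costs)]))
})
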