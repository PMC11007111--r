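# Detailed balance (Wegscheider) constraints on cycles of reversible
# mass-action reactions.
#
# A vector n over the reversible reactions with S_rev %*% n = 0 is a
# stoichiometric cycle: running each reaction n_i times returns the state
# to itself. At thermodynamic equilibrium every reaction is individually
# balanced, so prod_i Keq_i^{n_i} = 1 with Keq_i = kf_i/kr_i. Each
# independent cycle therefore removes one free rate constant.

reversibleIdx <- function(model) {
  which(vapply(model@reactions, function(rx)
    isTRUE(rx$reversible) && identical(rx$family, "mass_action"), logical(1)))
}

compLabel <- function(idx, species) {
  if (!length(idx)) "(nothing)"
  else paste(sort(species[idx]), collapse = " + ")
}

#' Graph of reversible mass-action reactions
#'
#' Nodes are species compositions (multisets of species consumed or
#' produced); each reversible mass-action reaction is one edge from the
#' composition it consumes to the composition it produces. Irreversible
#' reactions (Michaelis-Menten, Hill, degradation, synthesis) are
#' excluded. This graph is a report/visualization aid; cycle detection
#' itself operates on the stoichiometric cycle space (see [cycleBasis()]),
#' which also catches loops that share no composition node.
#'
#' @param model an [OdeModel-class].
#' @return list of class "reversible_graph": `nodes` (character) and
#'   `edges` (data.frame reaction, from, to, kf, kr).
#' @export
buildReversibleGraph <- function(model) {
  stopifnot(is(model, "OdeModel"))
  ridx <- reversibleIdx(model)
  edges <- lapply(ridx, function(j) {
    rx <- model@reactions[[j]]
    data.frame(reaction = j,
               from = compLabel(rx$consumed, model@species),
               to = compLabel(rx$produced, model@species),
               kf = rx$parNames[["kf"]], kr = rx$parNames[["kr"]],
               stringsAsFactors = FALSE)
  })
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(reaction = integer(0), from = character(0),
                           to = character(0), kf = character(0), kr = character(0))
  structure(list(nodes = unique(c(edges$from, edges$to)), edges = edges),
            class = "reversible_graph")
}

#' Independent cycles of reversible reactions
#'
#' Integer basis of the right null space of the stoichiometric submatrix
#' over reversible mass-action reactions. Each basis vector is one
#' independent closed loop; its entries are the (signed) number of times
#' each reaction is traversed. Deterministic given model order: the basis
#' comes from an RREF with left-to-right pivoting, so each cycle is
#' anchored at its highest-indexed reaction with coefficient +1.
#'
#' @param model an [OdeModel-class].
#' @return list of cycles, each a list with `reactions` (model reaction
#'   indices) and `exponents` (signed integers, same length).
#' @export
cycleBasis <- function(model) {
  stopifnot(is(model, "OdeModel"))
  ridx <- reversibleIdx(model)
  if (!length(ridx)) return(list())
  Srev <- model@stoich[, ridx, drop = FALSE]
  lapply(intKernel(Srev), function(v) {
    nz <- which(v != 0)
    list(reactions = ridx[nz], exponents = as.numeric(v[nz]))
  })
}

#' Elect derived parameters for detailed-balance cycles
#'
#' For each independent cycle, the reverse rate constant of the
#' highest-indexed reaction not already derived becomes a derived
#' parameter, computed from the other equilibrium constants so the cycle
#' product of Keq^sign equals 1. The number of free parameters decreases by
#' exactly the number of cycles.
#'
#' @param model an [OdeModel-class].
#' @param cycles output of [cycleBasis()]; computed when missing.
#' @return the model with parameter statuses updated and constraints
#'   stored (see [applyConstraints()]).
#' @export
assignConstraints <- function(model, cycles = cycleBasis(model)) {
  stopifnot(is(model, "OdeModel"))
  params <- model@parameters
  constraints <- list()
  derived <- character(0)
  for (cyc in cycles) {
    krNames <- vapply(cyc$reactions, function(j)
      model@reactions[[j]]$parNames[["kr"]], character(1))
    kfNames <- vapply(cyc$reactions, function(j)
      model@reactions[[j]]$parNames[["kf"]], character(1))
    elig <- which(!(krNames %in% derived))
    if (!length(elig))
      stop("over-constrained: every reaction of a cycle is already derived",
           call. = FALSE)
    d <- elig[which.max(cyc$reactions[elig])]
    derived <- c(derived, krNames[d])
    params$status[params$name == krNames[d]] <- "derived"
    others <- setdiff(seq_along(cyc$reactions), d)
    constraints[[length(constraints) + 1L]] <- list(
      reactions = cyc$reactions, exponents = cyc$exponents,
      kfNames = kfNames, krNames = krNames,
      derivedIdx = d, derivedParam = krNames[d],
      derivedReaction = cyc$reactions[d],
      # Keq_d = prod_{i != d} Keq_i ^ (-n_i/n_d);  kr_d = kf_d / Keq_d
      formula = sprintf("%s = %s / (%s)", krNames[d], kfNames[d],
                        if (length(others))
                          paste(sprintf("(%s/%s)^%s", kfNames[others], krNames[others],
                                        fmtNum(-cyc$exponents[others] / cyc$exponents[d])),
                                collapse = " * ")
                        else "1"))
  }
  model@parameters <- params
  model@constraints <- constraints
  validObject(model)
  model
}

#' Apply detailed-balance constraints to a parameter vector
#'
#' Overwrites each derived reverse rate constant with the value forced by
#' its cycle, so that around every cycle prod(Keq^sign) = 1 to machine
#' precision. Idempotent: derived entries are a function of the free ones
#' only, evaluated in a fixed order.
#'
#' @param params named numeric vector over all model parameters.
#' @param model an [OdeModel-class] whose constraints were assigned with
#'   [assignConstraints()] (a model without constraints returns `params`
#'   unchanged).
#' @return the parameter vector with derived entries filled in.
#' @export
applyConstraints <- function(params, model) {
  stopifnot(is(model, "OdeModel"), !is.null(names(params)))
  for (cn in model@constraints) {
    keq <- params[cn$kfNames] / params[cn$krNames]
    if (any(!is.finite(keq)) || any(params[cn$kfNames] <= 0) ||
        any(params[cn$krNames][-cn$derivedIdx] <= 0))
      stop("rate constants must be positive to apply detailed balance",
           call. = FALSE)
    d <- cn$derivedIdx
    keqD <- prod(keq[-d] ^ (-cn$exponents[-d] / cn$exponents[d]))
    params[[cn$derivedParam]] <- params[[cn$kfNames[d]]] / keqD
  }
  params
}

#' Cycle product of equilibrium constants
#'
#' Diagnostic: prod(Keq^sign) for each constraint; equals 1 after
#' [applyConstraints()].
#' @param params named parameter vector.
#' @param model a constrained [OdeModel-class].
#' @export
cycleProducts <- function(params, model) {
  vapply(model@constraints, function(cn) {
    keq <- params[cn$kfNames] / params[cn$krNames]
    prod(keq ^ cn$exponents)
  }, numeric(1))
}

#' Plain-text constraint report
#'
#' One block per cycle: member reactions (by index and line number), the
#' elected derived parameter and its formula.
#' @param model a constrained [OdeModel-class].
#' @param file optional output path.
#' @export
constraintReport <- function(model, file = NULL) {
  stopifnot(is(model, "OdeModel"))
  if (!length(model@constraints)) {
    txt <- "No detailed-balance cycles detected."
  } else {
    blocks <- vapply(seq_along(model@constraints), function(i) {
      cn <- model@constraints[[i]]
      lines <- vapply(cn$reactions, function(j) model@reactions[[j]]$line, numeric(1))
      paste0(sprintf("Cycle %d: reactions %s (lines %s), traversal %s\n", i,
                     paste0("r", cn$reactions, collapse = ", "),
                     paste(lines, collapse = ", "),
                     paste(ifelse(cn$exponents > 0, "+", "-"), collapse = "")),
             sprintf("  derived: %s", cn$formula))
    }, character(1))
    txt <- paste(blocks, collapse = "\n")
  }
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}
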