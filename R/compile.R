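# Compile a parsed model into an executable ODE system.

slotDefaults <- function(tpl, slot) {
  if (!is.null(tpl$defaults) && slot %in% names(tpl$defaults))
    tpl$defaults[[slot]] else 1
}

slotBounds <- function(tpl, slot) {
  if (!is.null(tpl$bounds) && slot %in% names(tpl$bounds))
    tpl$bounds[[slot]] else c(1e-3, 1e3)
}

#' Compile a parsed model to an ODE model
#'
#' Enumerates species in first-appearance order, creates one reaction-scoped
#' parameter per rate-law slot (named `slot_rI` with I the 1-based reaction
#' index), builds the stoichiometric matrix (enzymes and the mRNA template
#' of translation are catalysts and get no stoichiometric entry), and
#' applies `@init`, `@obs`, `@sim_condition` and `@param_bound` directives.
#' Compilation is deterministic: the same model yields identical species
#' order, parameter names and matrix.
#'
#' @param model an [RxnModel-class]; must validate without errors.
#' @param registry a rate-law registry, by default [defaultRateLaws()].
#' @return an [OdeModel-class].
#' @examples
#' m <- compileModel(parseRxnModel("A binds B --> AB\n@init A = 1\n@init B = 1"))
#' speciesNames(m)
#' @export
compileModel <- function(model, registry = defaultRateLaws()) {
  stopifnot(is(model, "RxnModel"))
  issues <- validateRxnModel(model)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("model has validation errors:\n  ",
         paste(sprintf("line %s: %s", errs$line, errs$message), collapse = "\n  "),
         call. = FALSE)

  species <- modelSpecies(model)
  nsp <- length(species)
  spIdx <- function(x) match(x, species)

  parName <- character(0); parVal <- numeric(0)
  parLo <- numeric(0); parHi <- numeric(0); parRxn <- integer(0)
  rxns <- vector("list", length(model@reactions))
  stoich <- matrix(0L, nsp, length(model@reactions),
                   dimnames = list(species, NULL))

  for (j in seq_along(model@reactions)) {
    r <- model@reactions[[j]]
    tpl <- tryCatch(lookupRateLaw(registry, r$type), error = function(e)
      stop(sprintf("line %d: %s", r$line, conditionMessage(e)), call. = FALSE))
    slots <- tpl$slots
    if (identical(tpl$family, "mass_action") && !r$reversible)
      slots <- setdiff(slots, "kr")
    if (any(slots %in% species))
      stop(sprintf("line %d: rate-law slots clash with species names: %s",
                   r$line, paste(intersect(slots, species), collapse = ", ")),
           call. = FALSE)
    bad <- setdiff(names(r$overrides), slots)
    if (length(bad))
      stop(sprintf("line %d: unknown parameter override(s) %s for %s rate law (slots: %s)",
                   r$line, paste(sQuote(bad), collapse = ", "), tpl$family,
                   paste(slots, collapse = ", ")), call. = FALSE)

    pn <- setNames(paste0(slots, "_r", j), slots)
    for (s in slots) {
      v <- if (s %in% names(r$overrides)) r$overrides[[s]] else slotDefaults(tpl, s)
      b <- slotBounds(tpl, s)
      # widen the default box if an override sits outside it
      b[1] <- min(b[1], v); b[2] <- max(b[2], v)
      parName <- c(parName, pn[[s]]); parVal <- c(parVal, v)
      parLo <- c(parLo, b[1]); parHi <- c(parHi, b[2]); parRxn <- c(parRxn, j)
    }

    consumed <- if (r$type == "translate") character(0) else r$reactants
    produced <- r$products
    driversF <- if (length(r$reactants)) r$reactants
                else if (!is.na(r$enzyme)) r$enzyme else character(0)
    rx <- list(
      index = j, type = r$type, family = tpl$family, reversible = r$reversible,
      consumed = spIdx(consumed), produced = spIdx(produced),
      enzyme = if (is.na(r$enzyme)) NA_integer_ else spIdx(r$enzyme),
      driversF = spIdx(driversF), driversR = spIdx(produced),
      substrate = if (length(r$reactants)) spIdx(r$reactants[1]) else NA_integer_,
      regulator = if (!is.na(r$enzyme)) spIdx(r$enzyme)
                  else if (length(r$reactants)) spIdx(r$reactants[1]) else NA_integer_,
      parNames = pn, rateFun = tpl$rate, line = r$line
    )
    rx$expr <- if (is.function(tpl$expr)) tpl$expr(rx, pn, species)
               else sprintf("%s(%s)", tpl$family, paste(pn, collapse = ", "))
    rxns[[j]] <- rx
    for (i in rx$consumed) stoich[i, j] <- stoich[i, j] - 1L
    for (i in rx$produced) stoich[i, j] <- stoich[i, j] + 1L
  }

  initials <- setNames(numeric(nsp), species)
  obs <- list()
  conds <- list()
  boundDirs <- list()
  for (d in model@directives) {
    switch(d$keyword,
      init = { initials[[d$species]] <- d$amount },
      obs = { obs[[d$name]] <- d$coef },
      sim_condition = { conds[[d$name]] <- d$overrides },
      param_bound = { boundDirs[[length(boundDirs) + 1L]] <- d })
  }

  params <- data.frame(name = parName, value = parVal, lower = parLo,
                       upper = parHi, status = "free", reaction = parRxn,
                       stringsAsFactors = FALSE)
  for (d in boundDirs) {
    i <- match(d$param, params$name)
    if (is.na(i))
      stop(sprintf("line %d: @param_bound references unknown parameter '%s'",
                   d$line, d$param), call. = FALSE)
    params$lower[i] <- d$lower; params$upper[i] <- d$upper
    params$value[i] <- min(max(params$value[i], d$lower), d$upper)
  }

  # attach parameter indices now that the table is final
  for (j in seq_along(rxns))
    rxns[[j]]$parIdx <- match(rxns[[j]]$parNames, params$name)

  new("OdeModel", species = species, initials = initials, parameters = params,
      reactions = rxns, stoich = stoich, observables = obs, conditions = conds,
      constraints = list(), fastRate = buildFastRate(rxns))
}

# Index-based rate expression for the built-in families, e.g.
# "p[1]*x[1]*x[2] - p[2]*x[3]"; NULL for families without one (custom
# templates evaluate through their closure instead).
fastRateExpr <- function(rx) {
  pi <- rx$parIdx
  names(pi) <- names(rx$parNames)
  xs <- function(idx) paste(sprintf("x[%d]", idx), collapse = "*")
  switch(rx$family,
    mass_action = {
      fwd <- if (length(rx$driversF)) sprintf("p[%d]*%s", pi[["kf"]], xs(rx$driversF))
             else sprintf("p[%d]", pi[["kf"]])
      if (rx$reversible)
        sprintf("%s - p[%d]*%s", fwd, pi[["kr"]], xs(rx$driversR))
      else fwd
    },
    zeroth_order = sprintf("p[%d]", pi[["kf"]]),
    michaelis_menten = {
      e <- if (!is.na(rx$enzyme)) sprintf("x[%d]*", rx$enzyme) else ""
      sprintf("p[%d]*%sx[%d]/(p[%d] + x[%d])", pi[["V"]], e, rx$substrate,
              pi[["K"]], rx$substrate)
    },
    hill = sprintf("p[%d]*x[%d]^p[%d]/(p[%d]^p[%d] + x[%d]^p[%d])",
                   pi[["V"]], rx$regulator, pi[["n"]], pi[["K"]], pi[["n"]],
                   rx$regulator, pi[["n"]]),
    NULL)
}

# Vectorized rate evaluator over all reactions; empty list when any
# reaction needs its closure (user-registered kinetics).
buildFastRate <- function(rxns) {
  exprs <- lapply(rxns, fastRateExpr)
  if (any(vapply(exprs, is.null, logical(1)))) return(list())
  src <- sprintf("function(x, p) c(%s)", paste(unlist(exprs), collapse = ", "))
  list(eval(parse(text = src)[[1]], envir = baseenv()))
}

#' Current parameter vector of a model
#'
#' Named numeric vector of parameter values from the model table, with
#' detailed-balance constraints applied when present.
#' @param model an [OdeModel-class].
#' @export
modelParams <- function(model) {
  p <- setNames(model@parameters$value, model@parameters$name)
  if (length(model@constraints)) p <- applyConstraints(p, model)
  p
}

rhsCore <- function(model, x, p, rateScale = NULL) {
  x <- pmax(x, 0)
  v <- if (length(model@fastRate)) {
    model@fastRate[[1]](x, p)
  } else {
    vapply(model@reactions, function(rx) {
      pv <- p[rx$parIdx]
      names(pv) <- names(rx$parNames)
      rx$rateFun(x, pv, rx)
    }, numeric(1))
  }
  if (!is.null(rateScale)) v <- v * rateScale
  drop(model@stoich %*% v)
}

#' Evaluate the right-hand side d(state)/dt = S v(state, params)
#'
#' @param model an [OdeModel-class].
#' @param state numeric vector, one nonnegative concentration per species.
#' @param params named or positional numeric vector over all model
#'   parameters; defaults to [modelParams()].
#' @return the derivative vector, named by species.
#' @export
rhs <- function(model, state, params = modelParams(model)) {
  stopifnot(is(model, "OdeModel"))
  if (length(state) != length(model@species))
    stop(sprintf("state has length %d but the model has %d species",
                 length(state), length(model@species)), call. = FALSE)
  if (length(params) != nrow(model@parameters))
    stop(sprintf("params has length %d but the model has %d parameters",
                 length(params), nrow(model@parameters)), call. = FALSE)
  if (!is.null(names(params)))
    params <- params[model@parameters$name]
  setNames(rhsCore(model, state, params), model@species)
}

#' Conserved moieties of a compiled model
#'
#' Integer basis of the left null space of the stoichiometric matrix:
#' weighted sums of species invariant under the dynamics (e.g. total
#' A + AB for a binding reaction). Basis vectors are combined greedily
#' toward nonnegative weights where possible; the rows span the full left
#' null space either way.
#'
#' @param model an [OdeModel-class].
#' @return integer matrix with one conserved vector per row, columns named
#'   by species; zero rows when no conservation law exists.
#' @export
conservedMoieties <- function(model) {
  stopifnot(is(model, "OdeModel"))
  basis <- intKernel(t(model@stoich))
  basis <- Filter(function(v) max(abs(crossprod(v, model@stoich))) < 1e-9, basis)
  if (!length(basis)) {
    return(matrix(0L, 0, length(model@species),
                  dimnames = list(NULL, model@species)))
  }
  # prefer conservation-style (nonnegative) vectors: for each mixed-sign
  # basis vector, search small integer combinations with the other raw
  # basis vectors (coefficients 0..3); the span is unchanged either way
  k <- length(basis)
  raw <- basis
  for (i in seq_len(k)) {
    v <- raw[[i]]
    if (all(v >= 0)) next
    if (all(-v >= 0)) { basis[[i]] <- -v; next }
    others <- raw[-i]
    if (length(others) >= 1L && length(others) <= 5L) {
      grid <- as.matrix(expand.grid(rep(list(0:3), length(others))))
      found <- FALSE
      for (g in seq_len(nrow(grid))) {
        cand <- v
        for (j in seq_along(others)) cand <- cand + grid[g, j] * others[[j]]
        if (all(cand >= 0) && any(cand != 0)) {
          basis[[i]] <- cand; found <- TRUE; break
        }
      }
      if (!found) basis[[i]] <- v
    }
  }
  out <- do.call(rbind, basis)
  colnames(out) <- model@species
  storage.mode(out) <- "integer"
  out
}

#' Plain-text report of a compiled model
#'
#' Species table, parameter table and reaction list with symbolic rate
#' expressions, for human inspection.
#' @param model an [OdeModel-class].
#' @param file optional path to write to.
#' @return the report text, invisibly when `file` is given.
#' @export
modelReport <- function(model, file = NULL) {
  stopifnot(is(model, "OdeModel"))
  p <- model@parameters
  lines <- c(
    sprintf("Model: %d species, %d reactions, %d parameters (%d free)",
            length(model@species), length(model@reactions), nrow(p),
            sum(p$status == "free")),
    "", "Species (index, name, initial):",
    sprintf("  %3d  %-20s %s", seq_along(model@species), model@species,
            fmtNum(model@initials)),
    "", "Parameters (name, value, bounds, status):",
    sprintf("  %-12s %-12s [%s, %s] %s", p$name, fmtNum(p$value),
            fmtNum(p$lower), fmtNum(p$upper), p$status),
    "", "Reactions:",
    vapply(model@reactions, function(rx)
      sprintf("  r%-3d v = %s", rx$index, rx$expr), character(1)))
  if (length(model@observables)) {
    lines <- c(lines, "", "Observables:",
               vapply(names(model@observables), function(nm) {
                 cf <- model@observables[[nm]]
                 sprintf("  %s = %s", nm,
                         paste(sprintf("%s*%s", fmtNum(cf), names(cf)), collapse = " + "))
               }, character(1)))
  }
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}
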