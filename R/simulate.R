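# Integration of the compiled ODE system and observable evaluation.

#' Define a simulation condition
#'
#' A named stimulus condition: initial-amount overrides applied at t = 0
#' (e.g. setting a growth-factor ligand), plus the time window. Stimuli are
#' modeled as initial amounts, matching ligand-addition experiments.
#'
#' @param name condition label (e.g. "EGF").
#' @param overrides named nonnegative numeric vector of species initial
#'   amounts to override.
#' @param duration positive simulation length.
#' @param nTimepoints number of output timepoints (>= 2), evenly spaced
#'   from 0 to `duration`.
#' @return list of class "sim_condition".
#' @export
simCondition <- function(name, overrides = numeric(0), duration = 10,
                         nTimepoints = 101L) {
  stopifnot(is.character(name), length(name) == 1L, duration > 0,
            nTimepoints >= 2L)
  if (length(overrides) && (is.null(names(overrides)) || any(overrides < 0)))
    stop("overrides must be a named nonnegative numeric vector", call. = FALSE)
  structure(list(name = name, overrides = overrides, duration = duration,
                 nTimepoints = as.integer(nTimepoints)),
            class = "sim_condition")
}

conditionTimes <- function(condition) {
  seq(0, condition$duration, length.out = condition$nTimepoints)
}

#' Integrate a model under a condition
#'
#' Solves d(state)/dt = S v(state, params) with a stiff-capable solver
#' (deSolve's lsoda), relative tolerance 1e-8 and absolute tolerance 1e-10
#' by default. Detailed-balance constraints are (re-)applied to the
#' parameter vector before integration. Tiny negative states in
#' [-1e-8, 0) are clipped to 0; larger negatives are treated as solver
#' failures.
#'
#' @param model an [OdeModel-class].
#' @param params named parameter vector; defaults to [modelParams()].
#' @param condition a [simCondition()]; `NULL` simulates the plain initial
#'   state.
#' @param times increasing time vector starting at 0; defaults to the
#'   condition's grid.
#' @param rtol,atol solver tolerances.
#' @param rateScale optional per-reaction rate multipliers (used by
#'   reaction-level sensitivity analysis).
#' @return list of class "trajectory": `times`, `states` (timepoints x
#'   species matrix), `condition`.
#' @examples
#' m <- compileModel(parseRxnModel("A is degraded | kf=0.5\n@init A = 1"))
#' tr <- integrateModel(m, times = c(0, 2))
#' tr$states[2, "A"]  # exp(-1)
#' @export
integrateModel <- function(model, params = NULL, condition = NULL, times = NULL,
                           rtol = 1e-8, atol = 1e-10, rateScale = NULL) {
  stopifnot(is(model, "OdeModel"))
  if (is.null(params)) params <- modelParams(model)
  if (is.null(names(params))) names(params) <- model@parameters$name
  params <- params[model@parameters$name]
  if (any(is.na(params))) stop("missing parameter values", call. = FALSE)
  if (length(model@constraints)) params <- applyConstraints(params, model)

  x0 <- model@initials
  condName <- "default"
  if (!is.null(condition)) {
    stopifnot(inherits(condition, "sim_condition"))
    unknown <- setdiff(names(condition$overrides), model@species)
    if (length(unknown))
      stop("condition overrides unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    x0[names(condition$overrides)] <- condition$overrides
    condName <- condition$name
    if (is.null(times)) times <- conditionTimes(condition)
  }
  if (is.null(times)) times <- seq(0, 10, length.out = 101)
  if (times[1] != 0 || is.unsorted(times, strictly = length(times) > 1L))
    stop("times must be increasing and start at 0", call. = FALSE)

  if (length(times) == 1L) {
    states <- matrix(x0, 1L, dimnames = list(NULL, model@species))
    return(structure(list(times = times, states = states, condition = condName),
                     class = "trajectory"))
  }

  dfun <- function(t, y, p) list(rhsCore(model, y, p, rateScale))
  # solver diagnostics are re-raised as errors below (istate / negativity
  # checks), so the raw warnings only add noise, e.g. during fitting where
  # failed parameter sets are penalized
  out <- suppressWarnings(
    deSolve::lsoda(y = x0, times = times, func = dfun, parms = params,
                   rtol = rtol, atol = atol))
  attrs <- attributes(out)
  if (!is.null(attrs$istate) && attrs$istate[1] < 0) {
    lastT <- out[nrow(out), 1]
    stop(sprintf("ODE solver failed; last successful time %.6g", lastT),
         call. = FALSE)
  }
  states <- unname(out[, -1, drop = FALSE])
  colnames(states) <- model@species
  if (any(!is.finite(states)))
    stop("ODE solver failed: non-finite state reached", call. = FALSE)
  if (any(states < -1e-8)) {
    bad <- which(states < -1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("ODE solver failed: %s reached %.3g at t = %.6g",
                 model@species[bad[2]], states[bad[1], bad[2]], times[bad[1]]),
         call. = FALSE)
  }
  states[states < 0] <- 0
  structure(list(times = times, states = states, condition = condName),
            class = "trajectory")
}

#' Evaluate observables along a trajectory
#'
#' Observable value at each time = linear combination of the state row.
#'
#' @param trajectory output of [integrateModel()].
#' @param model the model that produced it (supplies the observable
#'   definitions), or a named list of coefficient vectors.
#' @return tidy data.frame: observable, condition, time, value.
#' @export
observableSeries <- function(trajectory, model) {
  stopifnot(inherits(trajectory, "trajectory"))
  obs <- if (is(model, "OdeModel")) model@observables else model
  if (!length(obs)) stop("model defines no observables", call. = FALSE)
  species <- colnames(trajectory$states)
  out <- lapply(names(obs), function(nm) {
    cf <- obs[[nm]]
    unknown <- setdiff(names(cf), species)
    if (length(unknown))
      stop(sprintf("observable '%s' references unknown species %s", nm,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    vals <- as.numeric(trajectory$states[, names(cf), drop = FALSE] %*% cf)
    data.frame(observable = nm, condition = trajectory$condition,
               time = trajectory$times, value = vals, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalize observable series to a shared [0, 1] scale
#'
#' Immunoblot-style normalization: within each normalization group -- one
#' observable across all conditions present -- every value is divided by
#' the group maximum over all times and conditions, so the group maximum
#' becomes exactly 1. Mirrors how relative band intensities are comparable
#' within one blot but not across targets.
#'
#' @param series data.frame with columns observable, condition, time,
#'   value (e.g. rbind of [observableSeries()] results across conditions).
#' @return the input with a `normalized` column added.
#' @export
normalizeSeries <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("observable", "value") %in% names(series)))
  series$normalized <- NA_real_
  for (nm in unique(series$observable)) {
    i <- series$observable == nm
    mx <- max(series$value[i])
    if (!is.finite(mx) || mx <= 0)
      stop(sprintf("cannot normalize: observable '%s' has no positive value", nm),
           call. = FALSE)
    series$normalized[i] <- series$value[i] / mx
  }
  series
}

#' Simulate conditions and return tidy normalized observables
#'
#' Convenience wrapper: integrates each condition, evaluates observables
#' and normalizes across conditions.
#'
#' @param model an [OdeModel-class] with observables.
#' @param conditions list of [simCondition()]s.
#' @param params optional parameter vector.
#' @param times optional shared time grid.
#' @return data.frame: observable, condition, time, value, normalized.
#' @export
simulateConditions <- function(model, conditions, params = NULL, times = NULL) {
  stopifnot(length(conditions) >= 1L)
  rows <- lapply(conditions, function(cond) {
    tr <- integrateModel(model, params = params, condition = cond, times = times)
    observableSeries(tr, model)
  })
  normalizeSeries(do.call(rbind, rows))
}
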