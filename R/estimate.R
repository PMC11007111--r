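# Parameter estimation: seeded evolutionary multi-start fitting of free
# parameters (log10 space) to normalized time-course data, producing an
# ensemble of parameter sets.

#' Validate / coerce an experiment table
#'
#' @param x data.frame with columns observable, condition, time, value and
#'   optionally sd. (observable, condition, time) must be unique; values
#'   nonnegative.
#' @return the validated data.frame.
#' @export
asExperimentTable <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("observable", "condition", "time", "value")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("experiment table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(x$value < 0)) stop("experiment values must be nonnegative", call. = FALSE)
  if (any(x$time < 0)) stop("experiment times must be nonnegative", call. = FALSE)
  key <- paste(x$observable, x$condition, x$time, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (observable, condition, time) rows in experiment table",
         call. = FALSE)
  x
}

#' Read an experiment table from delimited text
#'
#' Expects a header with columns observable, condition, time, value and
#' optionally sd.
#' @param path file path.
#' @param sep field separator (default tab).
#' @export
readExperimentTable <- function(path, sep = "\t") {
  asExperimentTable(utils::read.table(path, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE))
}

# Simulate the model at exactly the data's (condition, time) points and
# return per-row simulated observable values, or NULL on solver failure.
simAtData <- function(model, params, data, conditions) {
  simVals <- numeric(nrow(data))
  for (cn in unique(data$condition)) {
    cond <- conditions[[cn]]
    rows <- which(data$condition == cn)
    tpts <- sort(unique(c(0, data$time[rows])))
    tr <- tryCatch(integrateModel(model, params = params, condition = cond,
                                  times = tpts),
                   error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    for (nm in unique(data$observable[rows])) {
      cf <- model@observables[[nm]]
      vals <- as.numeric(tr$states[, names(cf), drop = FALSE] %*% cf)
      rr <- rows[data$observable[rows] == nm]
      simVals[rr] <- vals[match(data$time[rr], tr$times)]
    }
  }
  simVals
}

checkFitInputs <- function(model, data, conditions) {
  data <- asExperimentTable(data)
  badObs <- setdiff(unique(data$observable), names(model@observables))
  if (length(badObs))
    stop("data references unknown observable(s): ",
         paste(badObs, collapse = ", "), call. = FALSE)
  badCond <- setdiff(unique(data$condition), names(conditions))
  if (length(badCond))
    stop("data references unknown condition(s): ",
         paste(badCond, collapse = ", "), call. = FALSE)
  for (cn in conditions)
    stopifnot(inherits(cn, "sim_condition"))
  data
}

#' Fitting objective: sum of squared normalized residuals
#'
#' cost = sum over (observable, condition, time) of
#' (normalized simulation - normalized data)^2. Both sides are normalized
#' per observable group (one observable across all conditions) by their
#' maximum over the data's (condition, time) points, matching
#' [normalizeSeries()]. When the data carry an `sd` column, residuals are
#' divided by the sd (scaled the same way as the values). Detailed-balance
#' constraints are re-applied before every simulation; a solver failure
#' returns a large finite penalty (1e10).
#'
#' @param freeParams named numeric vector over the model's free parameters
#'   (natural scale).
#' @param model a compiled (optionally constrained) [OdeModel-class].
#' @param data an experiment table (see [asExperimentTable()]).
#' @param conditions named list of [simCondition()]s covering every
#'   condition in the data.
#' @return a nonnegative cost.
#' @export
fitCost <- function(freeParams, model, data, conditions) {
  data <- checkFitInputs(model, data, conditions)
  p <- setNames(model@parameters$value, model@parameters$name)
  if (length(freeParams)) {
    if (is.null(names(freeParams))) names(freeParams) <- freeParameters(model)
    p[names(freeParams)] <- freeParams
  }
  fitCostPrepared(p, model, data, conditions)
}

# internal hot path: full named parameter vector in, no revalidation
fitCostPrepared <- function(p, model, data, conditions) {
  sim <- simAtData(model, p, data, conditions)
  if (is.null(sim)) return(1e10)
  cost <- 0
  hasSd <- "sd" %in% names(data)
  for (nm in unique(data$observable)) {
    i <- data$observable == nm
    dmax <- max(data$value[i])
    smax <- max(sim[i])
    if (smax <= 0 || !is.finite(smax)) return(1e10)
    dN <- if (dmax > 0) data$value[i] / dmax else data$value[i]
    sN <- sim[i] / smax
    res <- sN - dN
    if (hasSd && dmax > 0) {
      sdv <- data$sd[i]
      ok <- is.finite(sdv) & sdv > 0
      res[ok] <- res[ok] / (sdv[ok] / dmax)
    }
    cost <- cost + sum(res^2)
  }
  cost
}

#' Fitting configuration
#'
#' @param nSets number of independently seeded optimization runs (the
#'   ensemble size; default 10).
#' @param popSize differential-evolution population size.
#' @param maxEvaluations objective-evaluation budget per run (population
#'   initialization included).
#' @param seed base seed; run i uses seed + i - 1.
#' @param f DE mutation weight.
#' @param cr DE crossover rate.
#' @param polish run a local Nelder-Mead refinement (log10 space, clamped
#'   to the bounds) from the DE optimum; its evaluations are included in
#'   the reported evaluation counts.
#' @export
fitConfig <- function(nSets = 10L, popSize = 20L, maxEvaluations = 5000L,
                      seed = 1L, f = 0.8, cr = 0.9, polish = TRUE) {
  stopifnot(nSets >= 1L, popSize >= 5L, maxEvaluations >= popSize, seed >= 0)
  list(nSets = as.integer(nSets), popSize = as.integer(popSize),
       maxEvaluations = as.integer(maxEvaluations), seed = as.integer(seed),
       f = f, cr = cr, polish = isTRUE(polish))
}

# One seeded DE run (log10 space) + optional polish. fn must accept a
# numeric vector z (log10 parameters) and return a scalar cost.
runDE <- function(fn, lower, upper, config, seed) {
  d <- length(lower)
  evals <- 0L
  fwrap <- function(z) { evals <<- evals + 1L; fn(pmin(pmax(z, lower), upper)) }
  withSeed(seed, {
    np <- config$popSize
    pop <- matrix(stats::runif(np * d), np, d)
    pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
    cost <- apply(pop, 1, fwrap)
    gens <- max(0L, (config$maxEvaluations - np) %/% np)
    for (g in seq_len(gens)) {
      for (i in seq_len(np)) {
        r <- sample(setdiff(seq_len(np), i), 3L)
        mut <- pop[r[1], ] + config$f * (pop[r[2], ] - pop[r[3], ])
        jrand <- sample.int(d, 1L)
        cross <- stats::runif(d) < config$cr
        cross[jrand] <- TRUE
        trial <- ifelse(cross, mut, pop[i, ])
        trial <- pmin(pmax(trial, lower), upper)
        ct <- fwrap(trial)
        if (ct <= cost[i]) { pop[i, ] <- trial; cost[i] <- ct }
      }
    }
    best <- which.min(cost)
    z <- pop[best, ]; cz <- cost[best]
    if (config$polish) {
      # Nelder-Mead tolerates the kinks the max-normalization introduces;
      # fwrap clamps proposals into the bound box
      fit <- tryCatch(
        if (d == 1L)
          stats::optim(z, fwrap, method = "Brent", lower = lower, upper = upper,
                       control = list(reltol = 1e-15))
        else
          stats::optim(z, fwrap, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-15)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value <= cz) {
        z <- pmin(pmax(fit$par, lower), upper); cz <- fit$value
      }
    }
    list(par = z, cost = cz, evals = evals)
  })
}

#' Fit free parameters, producing a parameter ensemble
#'
#' Runs one seeded differential-evolution search in log10 space per
#' requested parameter set (multi-start, not a posterior sample), with
#' detailed-balance constraints re-applied at every objective evaluation.
#' Identical model, data and configuration give an identical ensemble.
#'
#' @inheritParams fitCost
#' @param config a [fitConfig()].
#' @return a [ParameterEnsemble-class], ordered by cost.
#' @export
fitEnsemble <- function(model, data, conditions, config = fitConfig()) {
  stopifnot(is(model, "OdeModel"))
  data <- checkFitInputs(model, data, conditions)
  free <- freeParameters(model)
  if (!length(free)) stop("nothing to fit: the model has no free parameters",
                          call. = FALSE)
  pt <- model@parameters
  fi <- match(free, pt$name)
  lower <- log10(pt$lower[fi]); upper <- log10(pt$upper[fi])
  base <- setNames(pt$value, pt$name)
  fn <- function(z) {
    p <- base
    p[free] <- 10^z
    if (length(model@constraints)) p <- applyConstraints(p, model)
    fitCostPrepared(p, model, data, conditions)
  }
  seeds <- config$seed + seq_len(config$nSets) - 1L
  runs <- lapply(seeds, function(s) runDE(fn, lower, upper, config, s))
  pars <- t(vapply(runs, function(r) {
    p <- base
    p[free] <- 10^r$par
    if (length(model@constraints)) p <- applyConstraints(p, model)
    p
  }, base))
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  evals <- vapply(runs, `[[`, numeric(1), "evals")
  ord <- order(costs)
  new("ParameterEnsemble", parameters = pars[ord, , drop = FALSE],
      costs = costs[ord], seeds = as.numeric(seeds[ord]),
      evaluations = evals[ord], freeNames = free)
}

#' Ensemble-mean observable trajectories
#'
#' Simulates every ensemble member over the requested conditions, applies
#' the shared-scale normalization per member, and returns the pointwise
#' mean and standard deviation across members (the "averaged across N
#' parameter sets" trajectory). Members that fail to integrate are
#' excluded with a warning; it is an error if all fail.
#'
#' @param ensemble a [ParameterEnsemble-class].
#' @param model the fitted model.
#' @param conditions named list of [simCondition()]s.
#' @param times optional shared time grid.
#' @return data.frame: observable, condition, time, mean, sd, n.
#' @export
ensembleSummary <- function(ensemble, model, conditions, times = NULL) {
  stopifnot(is(ensemble, "ParameterEnsemble"), is(model, "OdeModel"))
  n <- nrow(ensemble@parameters)
  per <- vector("list", n)
  for (i in seq_len(n)) {
    per[[i]] <- tryCatch({
      df <- simulateConditions(model, conditions,
                               params = ensemble@parameters[i, ], times = times)
      df$member <- i
      df
    }, error = function(e) {
      warning(sprintf("ensemble member %d failed to integrate: %s",
                      i, conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  per <- Filter(Negate(is.null), per)
  if (!length(per)) stop("every ensemble member failed to integrate", call. = FALSE)
  all <- do.call(rbind, per)
  key <- interaction(all$observable, all$condition, all$time, drop = TRUE)
  agg <- do.call(rbind, lapply(split(all, key), function(g) {
    data.frame(observable = g$observable[1], condition = g$condition[1],
               time = g$time[1], mean = mean(g$normalized),
               sd = if (nrow(g) > 1) stats::sd(g$normalized) else 0,
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$observable, agg$condition, agg$time), ]
  rownames(agg) <- NULL
  agg
}

#' Write an ensemble as delimited text
#'
#' One row per parameter set: seed, cost, evaluations, then parameters by
#' name.
#' @param ensemble a [ParameterEnsemble-class].
#' @param path output file.
#' @param sep separator.
#' @export
writeEnsemble <- function(ensemble, path, sep = "\t") {
  df <- data.frame(seed = ensemble@seeds, cost = ensemble@costs,
                   evaluations = ensemble@evaluations,
                   ensemble@parameters, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
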