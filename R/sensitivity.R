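# Local sensitivity analysis: normalized log-log finite-difference
# coefficients, the metabolic-control-analysis convention
#   s = ln(q(p * factor) / q(p)) / ln(factor).

#' Define a response metric
#'
#' A scalar summary of one observable under one condition: its time
#' integral, its maximum, or its value at a fixed time.
#'
#' @param name metric label.
#' @param reducer "integral", "max" or "value_at_time".
#' @param observable observable name defined in the model.
#' @param condition a [simCondition()].
#' @param time required for "value_at_time".
#' @export
responseMetric <- function(name, reducer = c("integral", "max", "value_at_time"),
                           observable, condition, time = NULL) {
  reducer <- match.arg(reducer)
  stopifnot(inherits(condition, "sim_condition"))
  if (reducer == "value_at_time" && is.null(time))
    stop("'value_at_time' needs a time", call. = FALSE)
  structure(list(name = name, reducer = reducer, observable = observable,
                 condition = condition, time = time),
            class = "response_metric")
}

evalMetric <- function(metric, model, params, rateScale = NULL) {
  tr <- integrateModel(model, params = params, condition = metric$condition,
                       rateScale = rateScale)
  cf <- model@observables[[metric$observable]]
  if (is.null(cf))
    stop(sprintf("metric '%s': unknown observable '%s'", metric$name,
                 metric$observable), call. = FALSE)
  vals <- as.numeric(tr$states[, names(cf), drop = FALSE] %*% cf)
  switch(metric$reducer,
         integral = trapz(tr$times, vals),
         max = max(vals),
         value_at_time = stats::approx(tr$times, vals, xout = metric$time)$y)
}

#' Local sensitivity coefficients
#'
#' For each free parameter p (or each reaction rate), the metric q is
#' recomputed with p multiplied by `factor` and the coefficient
#' `s = ln(q_perturbed / q) / ln(factor)` is reported. Derived
#' (detailed-balance) parameters are recomputed after every perturbation,
#' so each perturbed model stays thermodynamically consistent; reaction
#' sensitivities multiply that reaction's rate directly.
#'
#' @param model a compiled (optionally constrained) [OdeModel-class].
#' @param metrics a [responseMetric()] or list of them.
#' @param params optional named parameter vector (defaults to the model's).
#' @param factor multiplicative perturbation, > 1 (default 1.01).
#' @param target "parameters" (free parameters only) or "reactions".
#' @return matrix of coefficients, rows = parameters or reactions, columns
#'   = metrics; attribute "factor" records the perturbation used.
#' @examples
#' m <- compileModel(parseRxnModel("A is degraded\n@init A = 1\n@obs A: A"))
#' met <- responseMetric("A_at_2", "value_at_time", "A",
#'                       simCondition("base", duration = 2), time = 2)
#' sensitivityCoefficients(m, met)  # ~ -kT = -2
#' @export
sensitivityCoefficients <- function(model, metrics, params = NULL, factor = 1.01,
                                    target = c("parameters", "reactions")) {
  stopifnot(is(model, "OdeModel"), factor > 1)
  target <- match.arg(target)
  if (inherits(metrics, "response_metric")) metrics <- list(metrics)
  if (is.null(params)) params <- modelParams(model)
  params <- params[model@parameters$name]
  if (length(model@constraints)) params <- applyConstraints(params, model)

  q0 <- vapply(metrics, function(mt) {
    q <- evalMetric(mt, model, params)
    if (!is.finite(q) || q <= 0)
      stop(sprintf("baseline metric '%s' is not positive (q = %g)", mt$name, q),
           call. = FALSE)
    q
  }, numeric(1))

  if (target == "parameters") {
    rows <- freeParameters(model)
    perturb <- function(k) {
      p <- params
      p[[rows[k]]] <- p[[rows[k]]] * factor
      if (length(model@constraints)) p <- applyConstraints(p, model)
      list(params = p, scale = NULL)
    }
  } else {
    rows <- paste0("r", seq_along(model@reactions))
    perturb <- function(k) {
      sc <- rep(1, length(model@reactions))
      sc[k] <- factor
      list(params = params, scale = sc)
    }
  }

  s <- matrix(NA_real_, length(rows), length(metrics),
              dimnames = list(rows, vapply(metrics, `[[`, character(1), "name")))
  for (k in seq_along(rows)) {
    pert <- perturb(k)
    for (j in seq_along(metrics)) {
      qj <- evalMetric(metrics[[j]], model, pert$params, rateScale = pert$scale)
      s[k, j] <- log(qj / q0[j]) / log(factor)
    }
  }
  attr(s, "factor") <- factor
  class(s) <- c("sensitivity_result", class(s))
  s
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity coefficients (perturbation factor %g):\n",
              attr(x, "factor")))
  y <- x; attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(round(y, 4), ...)
  invisible(x)
}

#' Write sensitivity results with per-metric rankings
#'
#' Emits the coefficient matrix as delimited text followed by a ranked
#' list (by |s|, descending) per metric.
#' @param s a result of [sensitivityCoefficients()].
#' @param path output file.
#' @export
writeSensitivity <- function(s, path) {
  y <- s; attributes(y) <- attributes(s)[c("dim", "dimnames")]
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(data.frame(name = rownames(y), y, check.names = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  for (j in colnames(y)) {
    ord <- order(abs(y[, j]), decreasing = TRUE)
    writeLines(c("", sprintf("# ranking for %s", j),
                 sprintf("%s\t%.6g", rownames(y)[ord], y[ord, j])), con)
  }
  invisible(path)
}
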