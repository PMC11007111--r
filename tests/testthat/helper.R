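# Shared builders for small models used across the suite.

degradeModel <- function(k = 0.5, A0 = 1) {
  compileModel(parseRxnModel(sprintf(
    "A is degraded | kf=%s\n@init A = %s\n@obs A: A", k, A0)))
}

bindModel <- function(kf = 1, kr = 1, A0 = 1, B0 = 1) {
  compileModel(parseRxnModel(sprintf(paste(
    "A binds B --> AB | kf=%s, kr=%s",
    "@init A = %s", "@init B = %s",
    "@obs AB: AB", "@obs total_A: A + AB", sep = "\n"),
    kf, kr, A0, B0)))
}

diamondModel <- function(constrained = TRUE) {
  m <- compileModel(parseRxnModel(makeDiamondModel()))
  if (constrained) m <- assignConstraints(m)
  m
}

# diamond parameter vector with prescribed equilibrium constants
# (kf = Keq, kr = 1); kr_r4 left at 1 unless constraints are applied
diamondParams <- function(model, keq = c(2, 3, 4, 1)) {
  p <- setNames(model@parameters$value, model@parameters$name)
  for (i in 1:4) {
    p[sprintf("kf_r%d", i)] <- keq[i]
    p[sprintf("kr_r%d", i)] <- 1
  }
  if (length(model@constraints)) p <- applyConstraints(p, model)
  p
}

turnoverStudy <- function(noiseCv, nTimes = 13, seed = 11) {
  model <- compileModel(parseRxnModel(makeTurnoverModel()))
  conds <- list(basal = simCondition("basal", duration = 5, nTimepoints = 51),
                pulse = simCondition("pulse", c(A = 3), duration = 5,
                                     nTimepoints = 51))
  truth <- modelParams(model)
  syn <- makeSyntheticTimecourse(model, truth, conds, nTimes = nTimes,
                                 noiseCv = noiseCv, seed = seed)
  list(model = model, conditions = conds, truth = truth,
       table = syn$table)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), .Machine$double.eps)),
            tol)
}

# every conserved total stays within tol (relative to its own magnitude,
# with an absolute floor for totals that are exactly zero)
expect_conserved <- function(model, times, tol = 1e-6) {
  cm <- conservedMoieties(model)
  if (!nrow(cm)) return(invisible(NULL))
  tr <- integrateModel(model, times = times)
  tot <- tr$states %*% t(cm)
  for (j in seq_len(ncol(tot)))
    expect_lt(max(abs(tot[, j] - tot[1, j])) / max(abs(tot[1, j]), 1e-6), tol)
}
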