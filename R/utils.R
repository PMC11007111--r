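# Internal helpers shared across modules.

SPECIES_RX <- "[A-Za-z_][A-Za-z0-9_]*"

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded fixture generators are pure functions of
#' their arguments and never perturb user randomness.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Shortest decimal string that reparses to exactly the same double.
fmtNum <- function(x) {
  vapply(x, function(xi) {
    if (is.na(xi)) return("NA")
    if (xi == round(xi) && abs(xi) < 1e15) return(sprintf("%.0f", xi))
    for (d in 15:17) {
      s <- sprintf(paste0("%.", d, "g"), xi)
      if (as.numeric(s) == xi) return(s)
    }
    sprintf("%.17g", xi)
  }, character(1))
}

# Rationalize a numeric vector to the smallest integer multiple, if one
# exists with denominator <= maxDen; otherwise return the input unchanged.
intify <- function(v, maxDen = 720L, tol = 1e-7) {
  for (d in seq_len(maxDen)) {
    w <- v * d
    if (max(abs(w - round(w))) < tol) return(round(w))
  }
  v
}

#' Integer kernel (right null space) of a small integer matrix
#'
#' Reduced row echelon form with partial pivoting, then back-substitution
#' per free column; each basis vector is rationalized to integers. Entries
#' of stoichiometric matrices are small integers, so double arithmetic is
#' exact here.
#' @return list of integer vectors v with M %*% v = 0; one per free column,
#'   ordered by free-column index (deterministic).
#' @noRd
intKernel <- function(M) {
  M <- as.matrix(M)
  m <- nrow(M); n <- ncol(M)
  if (n == 0L) return(list())
  if (m == 0L) {
    return(lapply(seq_len(n), function(j) { v <- integer(n); v[j] <- 1L; v }))
  }
  A <- M * 1.0
  pivcols <- integer(0)
  r <- 0L
  for (j in seq_len(n)) {
    if (r == m) break
    rows <- (r + 1L):m
    best <- rows[which.max(abs(A[rows, j]))]
    if (abs(A[best, j]) < 1e-9) next
    if (best != r + 1L) A[c(r + 1L, best), ] <- A[c(best, r + 1L), ]
    r <- r + 1L
    A[r, ] <- A[r, ] / A[r, j]
    for (k in seq_len(m)) {
      if (k != r && abs(A[k, j]) > 1e-12) A[k, ] <- A[k, ] - A[k, j] * A[r, ]
    }
    pivcols <- c(pivcols, j)
  }
  free <- setdiff(seq_len(n), pivcols)
  lapply(free, function(f) {
    v <- numeric(n)
    v[f] <- 1
    for (k in seq_along(pivcols)) v[pivcols[k]] <- -A[k, f]
    intify(v)
  })
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

normText <- function(x) tolower(trimws(x))

edgeKey <- function(a, b) {
  paste(sort(c(a, b)), collapse = "|")
}

# Collapse runs of whitespace and trim; used to canonicalize DSL lines.
squeeze <- function(x) trimws(gsub("[[:space:]]+", " ", x))
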