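# Rate-law templates and the reaction-type -> template registry.
#
# A template supplies the parameter slots and a rate closure; the compiler
# decides which species drive the rate from the reaction's role structure
# (reactants, products, enzyme/template). Registered templates therefore
# work for any reaction type with compatible roles.

#' Construct a rate-law template
#'
#' @param family one of "mass_action", "michaelis_menten", "hill",
#'   "zeroth_order", or a user-chosen label for custom kinetics.
#' @param slots character vector of parameter slot names (e.g. `c("kf",
#'   "kr")`); for mass action the `kr` slot is dropped automatically for
#'   irreversible reactions.
#' @param rate function(x, p, rx) returning a scalar rate; `x` is the full
#'   state vector, `p` the named slot values, `rx` the compiled reaction
#'   descriptor (fields `driversF`, `driversR`, `substrate`, `enzyme`,
#'   `regulator`, `reversible` hold species indices).
#' @param expr function(rx, parNames, species) returning a human-readable
#'   rate expression string; optional.
#' @param defaults named numeric default slot values (default 1 each).
#' @param bounds named list of c(lower, upper) fitting bounds per slot;
#'   unlisted slots get c(1e-3, 1e3).
#' @return a list of class "rate_law_template".
#' @export
rateLawTemplate <- function(family, slots, rate, expr = NULL,
                            defaults = NULL, bounds = NULL) {
  stopifnot(is.character(family), is.character(slots), is.function(rate))
  structure(list(family = family, slots = slots, rate = rate, expr = expr,
                 defaults = defaults, bounds = bounds),
            class = "rate_law_template")
}

prodExpr <- function(idx, species) {
  if (!length(idx)) "1" else paste(species[idx], collapse = " * ")
}

maRate <- function(x, p, rx) {
  v <- p[["kf"]] * prod(x[rx$driversF])
  if (rx$reversible) v <- v - p[["kr"]] * prod(x[rx$driversR])
  v
}

maExpr <- function(rx, pn, species) {
  fwd <- if (length(rx$driversF)) paste(pn[["kf"]], "*", prodExpr(rx$driversF, species))
         else pn[["kf"]]
  if (rx$reversible)
    paste(fwd, "-", pn[["kr"]], "*", prodExpr(rx$driversR, species))
  else fwd
}

mmRate <- function(x, p, rx) {
  S <- x[rx$substrate]
  E <- if (!is.na(rx$enzyme)) x[rx$enzyme] else 1
  p[["V"]] * E * S / (p[["K"]] + S)
}

mmExpr <- function(rx, pn, species) {
  e <- if (!is.na(rx$enzyme)) paste0(" * ", species[rx$enzyme]) else ""
  sprintf("%s%s * %s / (%s + %s)", pn[["V"]], e, species[rx$substrate],
          pn[["K"]], species[rx$substrate])
}

hillRate <- function(x, p, rx) {
  X <- x[rx$regulator]
  Xn <- X^p[["n"]]
  p[["V"]] * Xn / (p[["K"]]^p[["n"]] + Xn)
}

hillExpr <- function(rx, pn, species) {
  X <- species[rx$regulator]
  sprintf("%s * %s^%s / (%s^%s + %s^%s)", pn[["V"]], X, pn[["n"]],
          pn[["K"]], pn[["n"]], X, pn[["n"]])
}

zeroRate <- function(x, p, rx) p[["kf"]]

#' Default rate-law registry
#'
#' Maps every built-in reaction type to its rate law: binding,
#' dissociation and state transitions use (reversible) mass action;
#' enzymatic modification uses Michaelis-Menten with the enzyme
#' concentration multiplying V, `v = V [E][S]/(K + [S])`; transcription
#' uses a Hill equation in the transcription factor, `v = V [TF]^n /
#' (K^n + [TF]^n)` with default n = 2 bounded [1, 4] for fitting;
#' translation and degradation are first-order mass action (the mRNA
#' template is not consumed by translation); synthesis is zeroth order.
#' Default parameter value 1 with fitting bounds [1e-3, 1e3].
#'
#' @return a registry of class "rate_law_registry".
#' @examples
#' reg <- defaultRateLaws()
#' lookupRateLaw(reg, "transcribe")$family
#' @export
defaultRateLaws <- function() {
  ma <- rateLawTemplate("mass_action", c("kf", "kr"), maRate, maExpr)
  mm <- rateLawTemplate("michaelis_menten", c("V", "K"), mmRate, mmExpr)
  hill <- rateLawTemplate("hill", c("V", "K", "n"), hillRate, hillExpr,
                          defaults = c(n = 2), bounds = list(n = c(1, 4)))
  zero <- rateLawTemplate("zeroth_order", "kf", zeroRate,
                          function(rx, pn, species) pn[["kf"]])
  templates <- list(bind = ma, dissociate = ma, state_transition = ma,
                    enzymatic_modify = mm, transcribe = hill,
                    translate = ma, degrade = ma, synthesize = zero)
  structure(list(templates = templates, builtin = names(templates)),
            class = "rate_law_registry")
}

#' Look up the template for a reaction type
#' @param registry a rate-law registry.
#' @param type reaction type name.
#' @export
lookupRateLaw <- function(registry, type) {
  stopifnot(inherits(registry, "rate_law_registry"))
  tpl <- registry$templates[[type]]
  if (is.null(tpl)) stop(sprintf("no rate law registered for reaction type '%s'", type),
                         call. = FALSE)
  tpl
}

#' Register or replace a rate law
#'
#' Adds a template for a new (custom) reaction type, or -- only with
#' `allowOverwrite = TRUE` -- replaces a built-in. Returns a new registry;
#' the input is unchanged.
#'
#' @param registry a rate-law registry.
#' @param type reaction type the template applies to.
#' @param template a [rateLawTemplate()].
#' @param allowOverwrite must be TRUE to replace a built-in entry.
#' @export
registerRateLaw <- function(registry, type, template, allowOverwrite = FALSE) {
  stopifnot(inherits(registry, "rate_law_registry"),
            inherits(template, "rate_law_template"))
  if (type %in% names(registry$templates) && !allowOverwrite)
    stop(sprintf("registering '%s' would overwrite a built-in rate law; set allowOverwrite = TRUE",
                 type), call. = FALSE)
  registry$templates[[type]] <- template
  registry
}
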