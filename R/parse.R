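# The plain-text reaction language: one statement per line.
#
#   A binds B --> AB
#   AB is dissociated into A and B
#   E phosphorylates S --> pS
#   E dephosphorylates pS --> S
#   S is phosphorylated --> pS
#   pS is dephosphorylated --> S
#   TF transcribes M
#   M is translated into P
#   X is degraded
#   X is synthesized
#
# Any reaction line may carry trailing parameter overrides: "| kf=2, kr=0.5".
# Directives start with "@"; comments with "#"; species names are
# case-sensitive identifiers.

rxnPatterns <- function(customVerbs = character()) {
  sp <- SPECIES_RX
  pats <- list(
    bind = list(
      rx = sprintf("^(%s) binds (%s) --> (%s)$", sp, sp, sp),
      make = function(g, line) newReaction("bind", reactants = g[1:2], products = g[3],
                                           reversible = TRUE, family = "mass_action",
                                           line = line, mentionOrder = g[1:3])),
    dissociate = list(
      rx = sprintf("^(%s) is dissociated into (%s) and (%s)$", sp, sp, sp),
      make = function(g, line) newReaction("dissociate", reactants = g[1], products = g[2:3],
                                           reversible = TRUE, family = "mass_action",
                                           line = line, mentionOrder = g[1:3])),
    enzymatic = list(
      rx = sprintf("^(%s) (phosphorylates|dephosphorylates) (%s) --> (%s)$", sp, sp, sp),
      make = function(g, line) newReaction("enzymatic_modify", reactants = g[3], products = g[4],
                                           enzyme = g[1], reversible = FALSE,
                                           family = "michaelis_menten", line = line,
                                           modification = g[2], mentionOrder = c(g[1], g[3], g[4]))),
    state_fwd = list(
      rx = sprintf("^(%s) is phosphorylated --> (%s)$", sp, sp),
      make = function(g, line) newReaction("state_transition", reactants = g[1], products = g[2],
                                           reversible = TRUE, family = "mass_action",
                                           line = line, mentionOrder = g[1:2])),
    state_rev = list(
      rx = sprintf("^(%s) is dephosphorylated --> (%s)$", sp, sp),
      make = function(g, line) newReaction("state_transition", reactants = g[1], products = g[2],
                                           reversible = FALSE, family = "mass_action",
                                           line = line, modification = "dephosphorylation",
                                           mentionOrder = g[1:2])),
    transcribe = list(
      rx = sprintf("^(%s) transcribes (%s)$", sp, sp),
      make = function(g, line) newReaction("transcribe", reactants = character(0), products = g[2],
                                           enzyme = g[1], reversible = FALSE, family = "hill",
                                           line = line, mentionOrder = g[1:2])),
    translate = list(
      rx = sprintf("^(%s) is translated into (%s)$", sp, sp),
      make = function(g, line) newReaction("translate", reactants = g[1], products = g[2],
                                           reversible = FALSE, family = "mass_action",
                                           line = line, mentionOrder = g[1:2])),
    degrade = list(
      rx = sprintf("^(%s) is degraded$", sp),
      make = function(g, line) newReaction("degrade", reactants = g[1], products = character(0),
                                           reversible = FALSE, family = "mass_action",
                                           line = line, mentionOrder = g[1])),
    synthesize = list(
      rx = sprintf("^(%s) is synthesized$", sp),
      make = function(g, line) newReaction("synthesize", reactants = character(0), products = g[1],
                                           reversible = FALSE, family = "zeroth_order",
                                           line = line, mentionOrder = g[1]))
  )
  for (verb in customVerbs) {
    local({
      v <- verb
      pats[[paste0("custom_", v)]] <<- list(
        rx = sprintf("^(%s) %s (%s) --> (%s)$", sp, v, sp, sp),
        make = function(g, line) newReaction(v, reactants = g[2], products = g[3],
                                             enzyme = g[1], reversible = FALSE,
                                             family = "custom", line = line,
                                             mentionOrder = g[1:3]))
    })
  }
  pats
}

newReaction <- function(type, reactants, products, enzyme = NA_character_,
                        reversible = FALSE, family, line, overrides = numeric(0),
                        modification = NA_character_, mentionOrder = character(0)) {
  structure(list(type = type, reactants = reactants, products = products,
                 enzyme = enzyme, reversible = reversible, family = family,
                 overrides = overrides, modification = modification,
                 line = line, mentionOrder = mentionOrder),
            class = "ParsedReaction")
}

parseError <- function(line, message, token = NULL) {
  cond <- structure(
    class = c("reactode_parse_error", "error", "condition"),
    list(message = sprintf("line %d: %s", line, message),
         call = NULL, line = line, token = token))
  stop(cond)
}

parseOverrides <- function(txt, line) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  out <- numeric(0)
  for (p in parts) {
    p <- trimws(p)
    m <- regmatches(p, regexec(sprintf("^(%s)[[:space:]]*=[[:space:]]*([-+0-9.eE]+)$",
                                       SPECIES_RX), p))[[1]]
    if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[3]))))
      parseError(line, sprintf("malformed parameter override '%s'", p), p)
    out[m[2]] <- as.numeric(m[3])
  }
  out
}

parseObsExpr <- function(txt, line) {
  terms <- strsplit(txt, "+", fixed = TRUE)[[1]]
  coef <- numeric(0)
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec(sprintf(
      "^(?:([0-9.eE+-]+)[[:space:]]*\\*[[:space:]]*)?(%s)$", SPECIES_RX), tm))[[1]]
    if (length(m) != 3L)
      parseError(line, sprintf("malformed observable term '%s'", tm), tm)
    k <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    if (is.na(k)) parseError(line, sprintf("malformed coefficient in '%s'", tm), tm)
    coef[m[3]] <- if (m[3] %in% names(coef)) coef[[m[3]]] + k else k
  }
  coef
}

parseDirective <- function(text, line) {
  m <- regmatches(text, regexec("^@([a-z_]+)[[:space:]]*(.*)$", text))[[1]]
  if (length(m) != 3L) parseError(line, "malformed directive", text)
  kw <- m[2]; rest <- trimws(m[3])
  d <- switch(kw,
    obs = {
      mm <- regmatches(rest, regexec(sprintf("^(%s)[[:space:]]*:[[:space:]]*(.+)$",
                                             SPECIES_RX), rest))[[1]]
      if (length(mm) != 3L) parseError(line, "expected '@obs NAME: expr'", rest)
      list(keyword = "obs", name = mm[2], coef = parseObsExpr(mm[3], line))
    },
    init = {
      mm <- regmatches(rest, regexec(sprintf(
        "^(%s)[[:space:]]*=[[:space:]]*([-+0-9.eE]+)$", SPECIES_RX), rest))[[1]]
      if (length(mm) != 3L) parseError(line, "expected '@init SPECIES = value'", rest)
      amt <- as.numeric(mm[3])
      if (is.na(amt) || amt < 0) parseError(line, "initial amount must be nonnegative", mm[3])
      list(keyword = "init", species = mm[2], amount = amt)
    },
    sim_condition = {
      mm <- regmatches(rest, regexec(sprintf("^(%s)[[:space:]]*:[[:space:]]*(.*)$",
                                             SPECIES_RX), rest))[[1]]
      if (length(mm) != 3L) parseError(line, "expected '@sim_condition NAME: SP=value, ...'", rest)
      ov <- if (nzchar(trimws(mm[3]))) parseOverrides(mm[3], line) else numeric(0)
      if (any(ov < 0)) parseError(line, "condition overrides must be nonnegative")
      list(keyword = "sim_condition", name = mm[2], overrides = ov)
    },
    param_bound = {
      mm <- regmatches(rest, regexec(sprintf(
        "^(%s)[[:space:]]*:[[:space:]]*([0-9.eE+-]+)[[:space:]]+([0-9.eE+-]+)$",
        SPECIES_RX), rest))[[1]]
      if (length(mm) != 4L) parseError(line, "expected '@param_bound NAME: lower upper'", rest)
      lo <- as.numeric(mm[3]); hi <- as.numeric(mm[4])
      if (is.na(lo) || is.na(hi) || lo <= 0 || hi < lo)
        parseError(line, "bounds must be positive with lower <= upper")
      list(keyword = "param_bound", param = mm[2], lower = lo, upper = hi)
    },
    parseError(line, sprintf("unknown directive '@%s'", kw), kw)
  )
  d$line <- line
  d
}

#' Parse one line of model text
#'
#' Classifies a single physical line as a reaction, directive, comment or
#' blank, and returns the classified statement with its payload. The raw
#' text is preserved for error reporting.
#'
#' @param text one physical line.
#' @param line its 1-based line number.
#' @param customVerbs optional character vector of additional enzymatic
#'   verbs (parsed as `E <verb> S --> P`), matching rate laws added with
#'   [registerRateLaw()].
#' @return a list with elements `kind` ("reaction", "directive", "comment"
#'   or "blank"), `raw`, `line`, and `reaction` or `directive` payloads.
#'   Signals a classed parse error (`reactode_parse_error`) naming the line
#'   and offending token on unparseable input.
#' @examples
#' parseStatement("A binds B --> AB", 1)$reaction$type
#' @export
parseStatement <- function(text, line = 1L, customVerbs = character()) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  # strip comment tail
  body <- sub("#.*$", "", text)
  body <- squeeze(body)
  if (!nzchar(body)) {
    kind <- if (grepl("^[[:space:]]*#", raw)) "comment"
            else if (nzchar(trimws(raw))) "comment" else "blank"
    return(list(kind = kind, raw = raw, line = line))
  }
  if (startsWith(body, "@")) {
    return(list(kind = "directive", raw = raw, line = line,
                directive = parseDirective(body, line)))
  }
  # split trailing override clause
  overrides <- numeric(0)
  if (grepl("|", body, fixed = TRUE)) {
    at <- regexpr("|", body, fixed = TRUE)
    ov <- trimws(substring(body, at + 1L))
    body <- trimws(substring(body, 1L, at - 1L))
    if (!nzchar(ov)) parseError(line, "empty override clause after '|'")
    overrides <- parseOverrides(ov, line)
  }
  pats <- rxnPatterns(customVerbs)
  for (p in pats) {
    m <- regmatches(body, regexec(p$rx, body))[[1]]
    if (length(m)) {
      r <- p$make(m[-1], line)
      r$overrides <- overrides
      return(list(kind = "reaction", raw = raw, line = line, reaction = r))
    }
  }
  words <- strsplit(body, " ", fixed = TRUE)[[1]]
  token <- if (length(words) >= 2L) {
    if (words[2] == "is" && length(words) >= 3L) words[3] else words[2]
  } else words[1]
  parseError(line, sprintf("unknown reaction pattern near '%s'", token), token)
}

#' Parse multi-line model text
#'
#' Parses every line, keeping reactions in file order. All line errors are
#' aggregated and reported together rather than stopping at the first.
#' Duplicate reaction lines (same reaction regardless of overrides or
#' spacing) and empty models are rejected.
#'
#' @param text a character scalar of model text, or a character vector of
#'   lines.
#' @param source name used in messages (defaults to "<text>").
#' @param customVerbs see [parseStatement()].
#' @return an [RxnModel-class].
#' @examples
#' m <- parseRxnModel("A binds B --> AB\nAB is degraded")
#' length(reactions(m))
#' @export
parseRxnModel <- function(text, source = "<text>", customVerbs = character()) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) == 0L) lines <- ""
  reacts <- list()
  dirs <- list()
  errs <- character(0)
  for (i in seq_along(lines)) {
    st <- tryCatch(parseStatement(lines[i], i, customVerbs),
                   reactode_parse_error = function(e) e)
    if (inherits(st, "error")) {
      errs <- c(errs, conditionMessage(st))
    } else if (st$kind == "reaction") {
      reacts[[length(reacts) + 1L]] <- st$reaction
    } else if (st$kind == "directive") {
      dirs[[length(dirs) + 1L]] <- st$directive
    }
  }
  # duplicate reactions (ignoring overrides)
  if (length(reacts) > 1L) {
    cores <- vapply(reacts, function(r) renderReaction(r, withOverrides = FALSE),
                    character(1))
    for (core in unique(cores[duplicated(cores)])) {
      at <- vapply(reacts[cores == core], function(r) r$line, numeric(1))
      errs <- c(errs, sprintf("duplicate reaction '%s' at lines %s",
                              core, paste(at, collapse = ", ")))
    }
  }
  if (length(reacts) == 0L)
    errs <- c(errs, sprintf("%s: no reactions", source))
  if (length(errs)) {
    cond <- structure(
      class = c("reactode_parse_error", "error", "condition"),
      list(message = paste0("cannot parse '", source, "':\n  ",
                            paste(errs, collapse = "\n  ")),
           call = NULL, issues = errs))
    stop(cond)
  }
  new("RxnModel", reactions = reacts, directives = dirs, source = source)
}

#' Read a model file
#'
#' @param path UTF-8 plain-text model file, one statement per line.
#' @param customVerbs see [parseStatement()].
#' @return an [RxnModel-class].
#' @export
readRxnModel <- function(path, customVerbs = character()) {
  if (!file.exists(path)) stop("cannot open model file: ", path, call. = FALSE)
  parseRxnModel(readLines(path, warn = FALSE), source = basename(path),
                customVerbs = customVerbs)
}

renderReaction <- function(r, withOverrides = TRUE) {
  core <- switch(r$type,
    bind = sprintf("%s binds %s --> %s", r$reactants[1], r$reactants[2], r$products[1]),
    dissociate = sprintf("%s is dissociated into %s and %s",
                         r$reactants[1], r$products[1], r$products[2]),
    enzymatic_modify = sprintf("%s %s %s --> %s", r$enzyme,
                               if (identical(r$modification, "dephosphorylation"))
                                 "dephosphorylates" else "phosphorylates",
                               r$reactants[1], r$products[1]),
    state_transition = if (r$reversible)
      sprintf("%s is phosphorylated --> %s", r$reactants[1], r$products[1])
    else
      sprintf("%s is dephosphorylated --> %s", r$reactants[1], r$products[1]),
    transcribe = sprintf("%s transcribes %s", r$enzyme, r$products[1]),
    translate = sprintf("%s is translated into %s", r$reactants[1], r$products[1]),
    degrade = sprintf("%s is degraded", r$reactants[1]),
    synthesize = sprintf("%s is synthesized", r$products[1]),
    # custom enzymatic verb
    sprintf("%s %s %s --> %s", r$enzyme, r$type, r$reactants[1], r$products[1])
  )
  if (withOverrides && length(r$overrides)) {
    core <- paste0(core, " | ", paste(sprintf("%s=%s", names(r$overrides),
                                              fmtNum(r$overrides)), collapse = ", "))
  }
  core
}

renderDirective <- function(d) {
  switch(d$keyword,
    obs = {
      terms <- vapply(seq_along(d$coef), function(i) {
        if (d$coef[[i]] == 1) names(d$coef)[i]
        else sprintf("%s*%s", fmtNum(d$coef[[i]]), names(d$coef)[i])
      }, character(1))
      sprintf("@obs %s: %s", d$name, paste(terms, collapse = " + "))
    },
    init = sprintf("@init %s = %s", d$species, fmtNum(d$amount)),
    sim_condition = sprintf("@sim_condition %s:%s", d$name,
                            if (length(d$overrides))
                              paste0(" ", paste(sprintf("%s=%s", names(d$overrides),
                                                        fmtNum(d$overrides)),
                                                collapse = ", "))
                            else ""),
    param_bound = sprintf("@param_bound %s: %s %s", d$param,
                          fmtNum(d$lower), fmtNum(d$upper))
  )
}

#' Render a model back to canonical text
#'
#' Emits the same dialect the parser reads; rendering and re-parsing yields
#' an identical model (round-trip stable), which the test suite relies on.
#'
#' @param model an [RxnModel-class].
#' @return a character scalar of model text.
#' @export
renderRxnModel <- function(model) {
  stopifnot(is(model, "RxnModel"))
  paste(c(vapply(model@reactions, renderReaction, character(1)),
          vapply(model@directives, renderDirective, character(1))),
        collapse = "\n")
}

modelSpecies <- function(model) {
  out <- character(0)
  for (r in model@reactions) out <- c(out, r$mentionOrder)
  unique(out)
}

#' Validate a parsed model
#'
#' Structural checks beyond the grammar: warns about species with no
#' source (never produced or synthesized and no `@init`), errors on
#' directives referencing species absent from every reaction, and on
#' duplicate observable names. A clean model yields an empty data frame.
#'
#' @param model an [RxnModel-class].
#' @return data.frame with columns severity ("error"/"warning"), line,
#'   message; zero rows when the model is clean.
#' @export
validateRxnModel <- function(model) {
  stopifnot(is(model, "RxnModel"))
  issues <- list()
  add <- function(severity, line, message)
    issues[[length(issues) + 1L]] <<- data.frame(severity = severity, line = line,
                                                 message = message)
  sp <- modelSpecies(model)
  produced <- character(0)
  inited <- character(0)
  for (r in model@reactions) produced <- c(produced, r$products)
  for (d in model@directives) if (d$keyword == "init") inited <- c(inited, d$species)
  for (s in setdiff(sp, union(produced, inited))) {
    ln <- NA_real_
    for (r in model@reactions) if (s %in% r$mentionOrder) { ln <- r$line; break }
    add("warning", ln, sprintf("%s has no source and no initial value", s))
  }
  obsNames <- character(0)
  for (d in model@directives) {
    refs <- switch(d$keyword,
                   obs = names(d$coef),
                   init = d$species,
                   sim_condition = names(d$overrides),
                   character(0))
    for (s in setdiff(refs, sp))
      add("error", d$line, sprintf("@%s references unknown species '%s'", d$keyword, s))
    if (d$keyword == "obs") {
      if (d$name %in% obsNames)
        add("error", d$line, sprintf("duplicate observable '%s'", d$name))
      obsNames <- c(obsNames, d$name)
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(severity = character(0), line = numeric(0), message = character(0))
}
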