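# Three-part prompt template for reconstructing model text from a passage
# with a large language model, and a validator for candidate output. No
# network call is made anywhere: building the prompt and checking the
# returned text are deliberately offline operations.

PROMPT_INSTRUCTION <- paste(
  "Extract the biochemical reactions mentioned in a given passage and",
  "list them in a specified format, one reaction per line, exactly as in",
  "the example below.")

#' Assemble a three-part model-extraction prompt
#'
#' Deterministic concatenation of (a) a task description, (b) an exemplar
#' passage with its reaction-format rendering (few-shot example), and
#' (c) the target passage. The exemplar model text must parse cleanly --
#' teaching a broken format is an error.
#'
#' @param taskDescription natural-language task framing, appended to the
#'   fixed extraction instruction.
#' @param exemplarPassage prose describing the exemplar reactions.
#' @param exemplarModel reaction-language rendering of the exemplar.
#' @param targetPassage the passage to extract a model from.
#' @return the prompt text (character scalar).
#' @export
buildLlmPrompt <- function(taskDescription, exemplarPassage, exemplarModel,
                           targetPassage) {
  parts <- list(taskDescription = taskDescription,
                exemplarPassage = exemplarPassage,
                exemplarModel = exemplarModel, targetPassage = targetPassage)
  for (nm in names(parts)) {
    p <- parts[[nm]]
    if (!is.character(p) || length(p) != 1L || !nzchar(trimws(p)))
      stop(sprintf("'%s' must be non-empty text", nm), call. = FALSE)
  }
  parseRxnModel(exemplarModel, source = "exemplar")  # errors if broken
  paste(c("## Task", PROMPT_INSTRUCTION, taskDescription, "",
          "## Example passage", exemplarPassage, "",
          "## Example output", exemplarModel, "",
          "## Passage", targetPassage),
        collapse = "\n")
}

#' Validate candidate model text (e.g. LLM output)
#'
#' Tolerant, line-by-line parse: unparseable lines become issues while the
#' rest of the model is still built. On the parsed part it runs
#' [validateRxnModel()] and adds structural warnings a curator should see:
#' species that are produced but never revert or degrade (no sink), and
#' thermodynamic cycles that would require detailed-balance constraints.
#'
#' @param text candidate model text.
#' @param customVerbs see [parseStatement()].
#' @return list with `model` (an [RxnModel-class], or NULL when no line
#'   parsed) and `issues` (data.frame severity, line, message).
#' @export
validateLlmOutput <- function(text, customVerbs = character()) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  good <- character(0)
  issues <- data.frame(severity = character(0), line = numeric(0),
                       message = character(0))
  add <- function(sev, line, msg)
    issues <<- rbind(issues, data.frame(severity = sev, line = line, message = msg))
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    st <- tryCatch(parseStatement(lines[i], i, customVerbs),
                   reactode_parse_error = function(e) e)
    if (inherits(st, "error")) add("error", i, conditionMessage(st))
    else keep[i] <- TRUE
  }
  model <- tryCatch(parseRxnModel(lines[keep], source = "<candidate>",
                                  customVerbs = customVerbs),
                    reactode_parse_error = function(e) {
                      add("error", NA, conditionMessage(e)); NULL
                    })
  if (is.null(model)) return(list(model = NULL, issues = issues))
  issues <- rbind(issues, validateRxnModel(model))

  # sink check: produced species that never revert, degrade or react further
  consumedOrModified <- unlist(lapply(model@reactions, function(r) r$reactants))
  produced <- unlist(lapply(model@reactions, function(r) r$products))
  for (s in setdiff(produced, consumedOrModified))
    add("warning", NA, sprintf("%s has no sink: it never reverts, degrades or reacts further", s))

  compiled <- tryCatch(compileModel(model), error = function(e) NULL)
  if (!is.null(compiled)) {
    ncyc <- length(cycleBasis(compiled))
    if (ncyc > 0)
      add("warning", NA,
          sprintf("%d unconstrained reversible cycle(s): apply detailed-balance constraints before fitting",
                  ncyc))
  }
  list(model = model, issues = issues)
}
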