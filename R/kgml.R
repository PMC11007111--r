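# KGML (KEGG Markup Language) pathway import: parse entries/relations,
# expand intermediate active states, and emit reaction-language text.

sanitizeName <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", x), paste0("X", x), x)
}

#' Parse a KGML pathway file
#'
#' Captures entries (with type and display name = first token of the
#' graphics name attribute, per the KEGG "GENE1, alias, ..." convention)
#' and typed, subtyped relations. Relations whose endpoints are missing
#' are dropped with a warning. Display names are sanitized to valid
#' species identifiers and de-duplicated by appending the entry id.
#'
#' @param x a file path or a KGML XML string.
#' @return a [PathwayNetwork-class] (not yet state-expanded).
#' @export
parseKgml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e)
    stop("malformed KGML XML: ", conditionMessage(e), call. = FALSE))
  if (xml2::xml_name(doc) != "pathway")
    stop("not a KGML document: root element is not <pathway>", call. = FALSE)

  ents <- xml2::xml_find_all(doc, "./entry")
  if (!length(ents)) stop("empty pathway: no entries", call. = FALSE)
  entries <- data.frame(
    id = xml2::xml_attr(ents, "id"),
    type = xml2::xml_attr(ents, "type"),
    display = vapply(ents, function(e) {
      g <- xml2::xml_find_first(e, "./graphics")
      nm <- if (inherits(g, "xml_missing")) NA_character_ else xml2::xml_attr(g, "name")
      if (is.na(nm) || !nzchar(nm)) NA_character_
      else trimws(sub("\\.\\.\\.$", "", strsplit(nm, ",")[[1]][1]))
    }, character(1)),
    members = vapply(ents, function(e) {
      comp <- xml2::xml_find_all(e, "./component")
      paste(xml2::xml_attr(comp, "id"), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  badType <- is.na(entries$type) |
    !entries$type %in% c("gene", "compound", "group", "map", "ortholog")
  entries$type[badType] <- "other"
  entries$display[is.na(entries$display)] <- paste0("entry", entries$id[is.na(entries$display)])
  entries$display <- sanitizeName(entries$display)
  dup <- duplicated(entries$display) | duplicated(entries$display, fromLast = TRUE)
  entries$display[dup] <- paste0(entries$display[dup], "_", entries$id[dup])

  rels <- xml2::xml_find_all(doc, "./relation")
  relations <- if (length(rels)) data.frame(
    source = xml2::xml_attr(rels, "entry1"),
    target = xml2::xml_attr(rels, "entry2"),
    type = xml2::xml_attr(rels, "type"),
    subtypes = vapply(rels, function(r) {
      st <- xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name")
      if (!length(st)) "other" else paste(st, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  ) else data.frame(source = character(0), target = character(0),
                    type = character(0), subtypes = character(0))
  if (nrow(relations)) {
    ok <- relations$source %in% entries$id & relations$target %in% entries$id
    if (any(!ok)) {
      warning(sprintf("dropped %d relation(s) with missing endpoint(s)", sum(!ok)),
              call. = FALSE)
      relations <- relations[ok, , drop = FALSE]
      rownames(relations) <- NULL
    }
  }
  new("PathwayNetwork", entries = entries, relations = relations,
      stateExpanded = FALSE,
      species = data.frame(species = character(0), entry = character(0),
                           form = character(0), baseOf = character(0)))
}

relationSubtypes <- function(net) strsplit(net@relations$subtypes, ";", fixed = TRUE)

# entries that generate model species (proteins/complexes)
speciesEntries <- function(net) net@entries$type %in% c("gene", "group")

entryBaseName <- function(net, i, groupPolicy = "complex_species") {
  e <- net@entries[i, ]
  if (e$type == "group" && nzchar(e$members)) {
    ids <- strsplit(e$members, ";", fixed = TRUE)[[1]]
    mem <- net@entries$display[match(ids, net@entries$id)]
    mem <- mem[!is.na(mem)]
    if (length(mem)) return(paste(mem, collapse = "_"))
  }
  e$display
}

#' Expand intermediate active states
#'
#' For every gene/group entry that is the target of at least one
#' activating relation (subtype activation or phosphorylation), adds an
#' active-form species named "p" + name when phosphorylation is among the
#' incoming subtypes, else "a" + name. Outgoing relations of an activated
#' entry are re-sourced from the active form. Entries never activated keep
#' their single species. Calling twice is an error.
#'
#' @param network a [PathwayNetwork-class] from [parseKgml()].
#' @param groupPolicy "complex_species" (a group becomes one complex
#'   species named by joining member names with "_") or "expand_members"
#'   (each member becomes its own species and group relations are
#'   duplicated across members -- applied later during conversion).
#' @return the network with `stateExpanded = TRUE` and the species map and
#'   relation species columns filled in.
#' @export
expandStates <- function(network, groupPolicy = c("complex_species", "expand_members")) {
  stopifnot(is(network, "PathwayNetwork"))
  groupPolicy <- match.arg(groupPolicy)
  if (network@stateExpanded) stop("already expanded", call. = FALSE)

  ent <- network@entries
  gen <- speciesEntries(network)
  base <- rep(NA_character_, nrow(ent))
  for (i in which(gen)) base[i] <- entryBaseName(network, i, groupPolicy)

  subs <- relationSubtypes(network)
  rel <- network@relations
  activatedBy <- vector("list", nrow(ent))
  names(activatedBy) <- ent$id
  if (nrow(rel)) for (k in seq_len(nrow(rel))) {
    st <- subs[[k]]
    if (any(st %in% c("activation", "phosphorylation"))) {
      tid <- rel$target[k]
      activatedBy[[tid]] <- union(activatedBy[[tid]], st)
    }
  }

  spRows <- list()
  active <- setNames(rep(NA_character_, nrow(ent)), ent$id)
  existing <- base[!is.na(base)]
  for (i in which(gen)) {
    spRows[[length(spRows) + 1L]] <- data.frame(
      species = base[i], entry = ent$id[i], form = "base", baseOf = base[i],
      stringsAsFactors = FALSE)
    inc <- activatedBy[[ent$id[i]]]
    if (length(inc)) {
      pfx <- if ("phosphorylation" %in% inc) "p" else "a"
      act <- paste0(pfx, base[i])
      if (act %in% c(existing, vapply(spRows, function(d) d$species, character(1))))
        stop(sprintf("active-form name collision: '%s' already exists", act),
             call. = FALSE)
      active[ent$id[i]] <- act
      spRows[[length(spRows) + 1L]] <- data.frame(
        species = act, entry = ent$id[i], form = "active", baseOf = base[i],
        stringsAsFactors = FALSE)
    }
  }
  species <- if (length(spRows)) do.call(rbind, spRows)
             else network@species

  if (nrow(rel)) {
    si <- match(rel$source, ent$id)
    ti <- match(rel$target, ent$id)
    rel$sourceSpecies <- ifelse(!is.na(active[rel$source]), active[rel$source],
                                base[si])
    rel$targetBase <- base[ti]
    rel$targetActive <- unname(active[rel$target])
  }
  network@relations <- rel
  network@species <- species
  network@stateExpanded <- TRUE
  network
}

#' Conversion options for KGML-to-text
#'
#' @param addReverse add a first-order reversion ("pT is dephosphorylated
#'   --> T") for every active form lacking an explicit deactivating
#'   relation (default TRUE).
#' @param degrade species names to append "X is degraded" lines for
#'   (the species must exist after conversion).
#' @param skip relation subtypes to drop silently (counted in the report);
#'   default "indirect effect".
#' @param groupPolicy see [expandStates()].
#' @export
conversionOptions <- function(addReverse = TRUE, degrade = character(0),
                              skip = "indirect effect",
                              groupPolicy = "complex_species") {
  list(addReverse = isTRUE(addReverse), degrade = degrade, skip = skip,
       groupPolicy = groupPolicy)
}

#' Convert a state-expanded pathway network to model text
#'
#' Subtype-to-line mapping: expression -> "SRC transcribes T";
#' binding/association -> "S1 binds S2 --> S1_S2"; activation with
#' phosphorylation -> "SRC phosphorylates T --> pT"; activation alone ->
#' "SRC phosphorylates T --> aT"; inhibition or dephosphorylation ->
#' "SRC dephosphorylates xT --> T" (skipped with a reason when the target
#' was never activated, so no active form exists). Relations whose
#' subtypes all fall in `options$skip`, or that touch non-protein entries
#' (compound/map), are skipped and counted. Unmapped subtypes are an
#' error. With `addReverse`, every active form lacking an explicit
#' deactivator gains a first-order reversion line; `degrade` species each
#' append a degradation line. The output parses cleanly with
#' [parseRxnModel()].
#'
#' @param network a state-expanded [PathwayNetwork-class].
#' @param options a [conversionOptions()].
#' @return list of class "kgml_conversion": `text` (model text),
#'   `provenance` (data.frame line, text, origin, relation), `report`
#'   (counts).
#' @export
networkToText <- function(network, options = conversionOptions()) {
  stopifnot(is(network, "PathwayNetwork"))
  if (!network@stateExpanded)
    stop("expand states first (expandStates)", call. = FALSE)
  rel <- network@relations
  subs <- relationSubtypes(network)
  gen <- setNames(speciesEntries(network), network@entries$id)

  lines <- character(0)
  origin <- character(0)
  relid <- integer(0)
  skipped <- 0L
  skippedReasons <- character(0)
  deactivated <- character(0)  # active-form species with an explicit deactivator

  emit <- function(text, org, k) {
    lines[length(lines) + 1L] <<- text
    origin[length(origin) + 1L] <<- org
    relid[length(relid) + 1L] <<- k
  }
  skip <- function(reason) {
    skipped <<- skipped + 1L
    skippedReasons[length(skippedReasons) + 1L] <<- reason
  }

  if (nrow(rel)) for (k in seq_len(nrow(rel))) {
    st <- subs[[k]]
    live <- setdiff(st, options$skip)
    if (!length(live)) { skip(sprintf("relation %d: subtypes all skipped", k)); next }
    if (!gen[[rel$source[k]]] || !gen[[rel$target[k]]]) {
      skip(sprintf("relation %d: non-protein endpoint", k)); next
    }
    src <- rel$sourceSpecies[k]
    tb <- rel$targetBase[k]
    ta <- rel$targetActive[k]
    if ("expression" %in% live) {
      emit(sprintf("%s transcribes %s", src, tb), "relation", k)
    } else if ("binding/association" %in% live) {
      emit(sprintf("%s binds %s --> %s_%s", src, tb, src, tb), "relation", k)
    } else if (all(c("activation", "phosphorylation") %in% live) ||
               "phosphorylation" %in% live) {
      emit(sprintf("%s phosphorylates %s --> %s", src, tb, ta), "relation", k)
    } else if ("activation" %in% live) {
      emit(sprintf("%s phosphorylates %s --> %s", src, tb, ta), "relation", k)
    } else if (any(c("inhibition", "dephosphorylation") %in% live)) {
      if (is.na(ta)) {
        skip(sprintf("relation %d: deactivation of never-activated target '%s'", k, tb))
      } else {
        emit(sprintf("%s dephosphorylates %s --> %s", src, ta, tb), "relation", k)
        deactivated <- c(deactivated, ta)
      }
    } else {
      stop(sprintf("relation %d (%s -> %s): unmapped subtype(s) %s", k,
                   rel$source[k], rel$target[k],
                   paste(sQuote(live), collapse = ", ")), call. = FALSE)
    }
  }

  reverseAdded <- 0L
  if (options$addReverse) {
    act <- network@species[network@species$form == "active", , drop = FALSE]
    for (i in seq_len(nrow(act))) {
      if (act$species[i] %in% deactivated) next
      emit(sprintf("%s is dephosphorylated --> %s", act$species[i], act$baseOf[i]),
           "reverse", NA_integer_)
      reverseAdded <- reverseAdded + 1L
    }
  }

  allSpecies <- unique(unlist(regmatches(lines,
    gregexpr(SPECIES_RX, lines))))
  for (sp in options$degrade) {
    if (!sp %in% allSpecies)
      stop(sprintf("degradation species '%s' does not exist after conversion", sp),
           call. = FALSE)
    emit(sprintf("%s is degraded", sp), "degradation", NA_integer_)
  }

  structure(list(
    text = paste(lines, collapse = "\n"),
    provenance = data.frame(line = seq_along(lines), text = lines,
                            origin = origin, relation = relid,
                            stringsAsFactors = FALSE),
    report = list(entries = nrow(network@entries), relations = nrow(rel),
                  lines = length(lines), skipped = skipped,
                  skippedReasons = skippedReasons,
                  reverseAdded = reverseAdded,
                  degradationAdded = length(options$degrade))),
    class = "kgml_conversion")
}

#' @export
print.kgml_conversion <- function(x, ...) {
  r <- x$report
  cat(sprintf("KGML conversion: %d entries, %d relations -> %d lines (%d skipped, %d reverse, %d degradation)\n",
              r$entries, r$relations, r$lines, r$skipped, r$reverseAdded,
              r$degradationAdded))
  invisible(x)
}
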