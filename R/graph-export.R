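# DOT / GraphML export of models and pathway networks.

dotQuote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# nodes: data.frame(id, size); edges: data.frame(from, to, style, width)
graphText <- function(nodes, edges, format, name = "G") {
  if (format == "dot") {
    lines <- c(sprintf("digraph %s {", name),
               sprintf("  %s [size=%s];", dotQuote(nodes$id), fmtNum(nodes$size)),
               if (nrow(edges)) sprintf("  %s -> %s [style=%s, width=%s];",
                                        dotQuote(edges$from), dotQuote(edges$to),
                                        edges$style, fmtNum(edges$width)),
               "}")
    return(paste(lines, collapse = "\n"))
  }
  header <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<graphml xmlns="http://graphml.graphdrawing.org/xmlns" ',
           'xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" ',
           'xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns ',
           'http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">'),
    '  <key id="size" for="node" attr.name="size" attr.type="double"/>',
    '  <key id="width" for="edge" attr.name="width" attr.type="double"/>',
    '  <key id="style" for="edge" attr.name="style" attr.type="string"/>',
    sprintf('  <graph id="%s" edgedefault="directed">', xmlEscape(name)))
  nodeLines <- sprintf('    <node id="%s"><data key="size">%s</data></node>',
                       xmlEscape(nodes$id), fmtNum(nodes$size))
  edgeLines <- if (nrow(edges))
    sprintf(paste0('    <edge source="%s" target="%s">',
                   '<data key="width">%s</data>',
                   '<data key="style">%s</data></edge>'),
            xmlEscape(edges$from), xmlEscape(edges$to),
            fmtNum(edges$width), xmlEscape(edges$style))
  else character(0)
  paste(c(header, nodeLines, edgeLines, "  </graph>", "</graphml>"),
        collapse = "\n")
}

finishGraph <- function(txt, file) {
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

weightFor <- function(weights, slot, key) {
  if (is.null(weights) || is.null(weights[[slot]])) return(1)
  w <- weights[[slot]]
  if (key %in% names(w)) unname(w[[key]]) else 1
}

#' @describeIn exportGraph species nodes; one edge from every reactant to
#'   every product of each reaction (solid "conversion" edges) and a dashed
#'   "catalysis" edge from the enzyme/template/regulator to each product.
#' @export
setMethod("exportGraph", "OdeModel",
  function(x, format = c("dot", "graphml"), weights = NULL, file = NULL, ...) {
    format <- match.arg(format)
    nodes <- data.frame(id = x@species,
                        size = vapply(x@species, function(s)
                          weightFor(weights, "nodes", s), numeric(1)),
                        stringsAsFactors = FALSE)
    rows <- list()
    for (rx in x@reactions) {
      for (pp in rx$produced) {
        for (ss in rx$consumed)
          rows[[length(rows) + 1L]] <- data.frame(
            from = x@species[ss], to = x@species[pp], style = "solid",
            stringsAsFactors = FALSE)
        drv <- setdiff(union(rx$driversF,
                             if (!is.na(rx$enzyme)) rx$enzyme else integer(0)),
                       rx$consumed)
        for (ee in drv)
          rows[[length(rows) + 1L]] <- data.frame(
            from = x@species[ee], to = x@species[pp], style = "dashed",
            stringsAsFactors = FALSE)
      }
    }
    edges <- if (length(rows)) unique(do.call(rbind, rows))
             else data.frame(from = character(0), to = character(0),
                             style = character(0))
    edges$width <- if (nrow(edges))
      vapply(seq_len(nrow(edges)), function(i)
        weightFor(weights, "edges", edgeKey(edges$from[i], edges$to[i])),
        numeric(1)) else numeric(0)
    finishGraph(graphText(nodes, edges, format, "model"), file)
  })

#' @describeIn exportGraph entry nodes (display names); one edge per
#'   relation, styled dashed for inhibitory subtypes.
#' @export
setMethod("exportGraph", "PathwayNetwork",
  function(x, format = c("dot", "graphml"), weights = NULL, file = NULL, ...) {
    format <- match.arg(format)
    ent <- x@entries
    nodes <- data.frame(id = ent$display,
                        size = vapply(ent$display, function(s)
                          weightFor(weights, "nodes", s), numeric(1)),
                        stringsAsFactors = FALSE)
    rel <- x@relations
    if (nrow(rel)) {
      from <- ent$display[match(rel$source, ent$id)]
      to <- ent$display[match(rel$target, ent$id)]
      inhib <- vapply(strsplit(rel$subtypes, ";", fixed = TRUE), function(st)
        any(st %in% c("inhibition", "repression", "dephosphorylation")),
        logical(1))
      edges <- data.frame(from = from, to = to,
                          style = ifelse(inhib, "dashed", "solid"),
                          stringsAsFactors = FALSE)
      edges$width <- vapply(seq_len(nrow(edges)), function(i)
        weightFor(weights, "edges", edgeKey(from[i], to[i])), numeric(1))
    } else {
      edges <- data.frame(from = character(0), to = character(0),
                          style = character(0), width = numeric(0))
    }
    finishGraph(graphText(nodes, edges, format, "pathway"), file)
  })
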