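# Literature co-occurrence weighting of pathway nodes and edges:
# document-level occurrence counts of genes / gene pairs in an annotated
# corpus, compared between a query-filtered subset and the background.

#' Read an annotated corpus
#'
#' Delimited text with one entity mention per row and a header:
#' document_id, entity_text, entity_type. The shape of PubTator-style
#' annotation exports.
#'
#' @param path file path.
#' @param sep separator (default tab).
#' @return data.frame with those three columns.
#' @export
readCorpus <- function(path, sep = "\t") {
  x <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                         stringsAsFactors = FALSE, comment.char = "")
  need <- c("document_id", "entity_text", "entity_type")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("corpus lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x
}

corpusDocs <- function(corpus) {
  split(normText(corpus$entity_text), corpus$document_id)
}

#' Count node and edge document weights
#'
#' Document-level counting: a gene counts once per document no matter how
#' often it is mentioned; an unordered gene pair counts in a document
#' mentioning both. Matching is exact on case-folded entity text (no
#' synonym expansion).
#'
#' @param corpus annotated corpus data.frame (see [readCorpus()]).
#' @param genes non-empty character vector of gene names.
#' @param edges gene pairs as a 2-column matrix/data.frame, or NULL for all
#'   unordered pairs of `genes`.
#' @return a [WeightTable-class].
#' @examples
#' corp <- data.frame(document_id = c("d1", "d1", "d2", "d3", "d3"),
#'                    entity_text = c("EGFR", "AKT1", "EGFR", "AKT1", "TP53"),
#'                    entity_type = "gene")
#' countWeights(corp, c("EGFR", "AKT1"))
#' @export
countWeights <- function(corpus, genes, edges = NULL) {
  stopifnot(is.character(genes), length(genes) >= 1L)
  if (is.null(edges)) {
    edges <- if (length(genes) >= 2L) t(utils::combn(genes, 2L))
             else matrix(character(0), 0, 2)
  }
  edges <- as.matrix(edges)
  if (nrow(edges) && !all(edges %in% genes))
    stop("edges must connect genes in 'genes'", call. = FALSE)

  docs <- corpusDocs(corpus)
  geneNorm <- normText(genes)
  nodeCounts <- setNames(numeric(length(genes)), genes)
  edgeNames <- if (nrow(edges)) apply(edges, 1, function(e) edgeKey(e[1], e[2]))
               else character(0)
  edgeCounts <- setNames(numeric(length(edgeNames)), edgeNames)
  for (d in docs) {
    present <- geneNorm %in% d
    nodeCounts <- nodeCounts + present
    if (nrow(edges)) {
      p1 <- present[match(edges[, 1], genes)]
      p2 <- present[match(edges[, 2], genes)]
      edgeCounts <- edgeCounts + (p1 & p2)
    }
  }
  new("WeightTable", nDocs = as.numeric(length(docs)), nodes = nodeCounts,
      edges = edgeCounts)
}

#' Filter a corpus by a query term
#'
#' Keeps documents having at least one mention whose case-folded text
#' equals the case-folded query (any entity type). Idempotent; the result
#' is a subset of the input.
#'
#' @param corpus annotated corpus data.frame.
#' @param query non-empty query term (e.g. a cell line name).
#' @export
filterCorpus <- function(corpus, query) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query))
  hit <- normText(corpus$entity_text) == normText(query)
  keep <- corpus$document_id %in% unique(corpus$document_id[hit])
  corpus[keep, , drop = FALSE]
}

#' Co-occurrence enrichment of query vs background weights
#'
#' Pseudocounted rate ratio per node and per edge:
#' `fold = ((cq + pi) / (Nq + 2 pi)) / ((cb + pi) / (Nb + 2 pi))` with
#' pseudocount `pi` (default 0.5). Comparing a table against itself gives
#' fold exactly 1 everywhere.
#'
#' @param background [WeightTable-class] over the full corpus.
#' @param query [WeightTable-class] over the query-filtered corpus; must
#'   have at least one document and no more than the background.
#' @param pseudocount `pi` above.
#' @return list of class "enrichment_result": `nodes` and `edges`
#'   data.frames (name, backgroundCount, queryCount, fold), plus corpus
#'   sizes and the pseudocount.
#' @export
cooccurrenceEnrichment <- function(background, query, pseudocount = 0.5) {
  stopifnot(is(background, "WeightTable"), is(query, "WeightTable"),
            pseudocount > 0)
  if (query@nDocs < 1) stop("query matched no documents", call. = FALSE)
  if (background@nDocs < query@nDocs)
    stop("background corpus smaller than query corpus", call. = FALSE)
  fold <- function(cq, cb) {
    ((cq + pseudocount) / (query@nDocs + 2 * pseudocount)) /
      ((cb + pseudocount) / (background@nDocs + 2 * pseudocount))
  }
  mk <- function(bg, qr) {
    nms <- names(bg)
    qv <- qr[nms]
    qv[is.na(qv)] <- 0
    data.frame(name = nms, backgroundCount = unname(bg), queryCount = unname(qv),
               fold = unname(fold(qv, bg)), stringsAsFactors = FALSE)
  }
  structure(list(nodes = mk(background@nodes, query@nodes),
                 edges = mk(background@edges, query@edges),
                 backgroundN = background@nDocs, queryN = query@nDocs,
                 pseudocount = pseudocount),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: %d query docs vs %d background docs (pseudocount %g)\n",
              x$queryN, x$backgroundN, x$pseudocount))
  top <- x$nodes[order(-x$nodes$fold), ][seq_len(min(5, nrow(x$nodes))), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-12s fold %.3g\n", top$name[i], top$fold[i]))
  invisible(x)
}

#' Overlay enrichment weights on a pathway network graph
#'
#' Exports the network with node `size` = node fold change and edge
#' `width` = edge fold change; genes without data get 1.0. Matching is on
#' case-folded display names; an empty intersection is an error.
#'
#' @param network a [PathwayNetwork-class].
#' @param result an [cooccurrenceEnrichment()] result.
#' @param format "dot" or "graphml".
#' @param file optional output path.
#' @return the graph text (invisibly when `file` is given).
#' @export
annotateNetwork <- function(network, result, format = c("dot", "graphml"),
                            file = NULL) {
  stopifnot(is(network, "PathwayNetwork"), inherits(result, "enrichment_result"))
  format <- match.arg(format)
  disp <- network@entries$display
  hit <- normText(result$nodes$name) %in% normText(disp)
  if (!any(hit)) stop("no genes matched the network", call. = FALSE)
  nodeW <- setNames(result$nodes$fold,
                    disp[match(normText(result$nodes$name), normText(disp))])
  nodeW <- nodeW[!is.na(names(nodeW))]
  edgeW <- numeric(0)
  if (nrow(result$edges)) {
    for (i in seq_len(nrow(result$edges))) {
      gh <- strsplit(result$edges$name[i], "|", fixed = TRUE)[[1]]
      m <- disp[match(normText(gh), normText(disp))]
      if (!anyNA(m)) edgeW[edgeKey(m[1], m[2])] <- result$edges$fold[i]
    }
  }
  exportGraph(network, format = format,
              weights = list(nodes = nodeW, edges = edgeW), file = file)
}
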