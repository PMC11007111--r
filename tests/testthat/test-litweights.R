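# Literature co-occurrence weighting and enrichment.

miniCorpus <- function() {
  data.frame(
    document_id = c("d1", "d1", "d2", "d3", "d3"),
    entity_text = c("EGFR", "AKT1", "EGFR", "AKT1", "TP53"),
    entity_type = c("gene", "gene", "gene", "gene", "gene"),
    stringsAsFactors = FALSE)
}

test_that("document-level counts match the worked example", {
  wt <- countWeights(miniCorpus(), c("EGFR", "AKT1"))
  expect_identical(wt@nDocs, 3)
  expect_equal(wt@nodes, c(EGFR = 2, AKT1 = 2))
  expect_equal(unname(wt@edges["AKT1|EGFR"]), 1)
})

test_that("an empty corpus gives N = 0 and zero counts", {
  empty <- miniCorpus()[0, ]
  wt <- countWeights(empty, c("EGFR", "AKT1"))
  expect_identical(wt@nDocs, 0)
  expect_true(all(wt@nodes == 0) && all(wt@edges == 0))
})

test_that("matching is case-folded and repeated mentions count once per document", {
  corp <- data.frame(document_id = c("d1", "d1", "d1"),
                     entity_text = c("egfr", "EGFR", "Egfr"),
                     entity_type = "gene")
  wt <- countWeights(corp, "EGFR")
  expect_equal(unname(wt@nodes), 1)
})

test_that("counts agree with a naive double-loop recount on random corpora", {
  genes <- paste0("G", 1:6)
  set.seed(99)
  for (rep in 1:20) {
    nd <- sample(2:50, 1)
    rows <- do.call(rbind, lapply(seq_len(nd), function(i) {
      k <- sample(0:4, 1)
      if (k == 0) return(data.frame(document_id = paste0("d", i),
                                    entity_text = "filler", entity_type = "other"))
      data.frame(document_id = paste0("d", i),
                 entity_text = sample(genes, k), entity_type = "gene")
    }))
    wt <- countWeights(rows, genes)
    # naive recount
    ids <- unique(rows$document_id)
    naiveNode <- setNames(numeric(length(genes)), genes)
    naiveEdge <- wt@edges * 0
    for (d in ids) {
      ment <- tolower(rows$entity_text[rows$document_id == d])
      for (g in genes) if (tolower(g) %in% ment)
        naiveNode[g] <- naiveNode[g] + 1
      for (k in names(naiveEdge)) {
        gh <- strsplit(k, "|", fixed = TRUE)[[1]]
        if (all(tolower(gh) %in% ment)) naiveEdge[k] <- naiveEdge[k] + 1
      }
    }
    expect_equal(wt@nodes, naiveNode)
    expect_equal(wt@edges, naiveEdge)
    expect_true(all(wt@edges <= pmin(
      wt@nodes[vapply(strsplit(names(wt@edges), "|", fixed = TRUE), `[`, "", 1)],
      wt@nodes[vapply(strsplit(names(wt@edges), "|", fixed = TRUE), `[`, "", 2)])))
  }
})

test_that("adding a document mentioning g and h increments its counts by exactly 1", {
  corp <- miniCorpus()
  wt <- countWeights(corp, c("EGFR", "AKT1"))
  corp2 <- rbind(corp, data.frame(document_id = "d9",
                                  entity_text = c("EGFR", "AKT1"),
                                  entity_type = "gene"))
  wt2 <- countWeights(corp2, c("EGFR", "AKT1"))
  expect_equal(wt2@nodes, wt@nodes + 1)
  expect_equal(wt2@edges, wt@edges + 1)
  expect_identical(wt2@nDocs, wt@nDocs + 1)
})

test_that("query filtering keeps exactly the documents mentioning the query, idempotently", {
  corp <- rbind(miniCorpus(),
                data.frame(document_id = "d4", entity_text = "MCF-7",
                           entity_type = "cellline"))
  sub <- filterCorpus(corp, "MCF-7")
  expect_identical(unique(sub$document_id), "d4")
  expect_identical(filterCorpus(sub, "MCF-7"), sub)
  expect_identical(nrow(filterCorpus(corp, "missing-term")), 0L)
})

test_that("enrichment follows the pseudocounted rate ratio", {
  bg <- new("WeightTable", nDocs = 8, nodes = c(g = 2), edges = numeric(0))
  qt <- new("WeightTable", nDocs = 4, nodes = c(g = 2), edges = numeric(0))
  enr <- cooccurrenceEnrichment(bg, qt, pseudocount = 0.5)
  # (2.5/5) / (2.5/9) = 1.8
  expect_equal(enr$nodes$fold, 1.8, tolerance = 1e-12)

  # self-comparison is exactly 1 for nodes and edges
  wt <- countWeights(miniCorpus(), c("EGFR", "AKT1", "TP53"))
  self <- cooccurrenceEnrichment(wt, wt)
  expect_true(all(self$nodes$fold == 1))
  expect_true(all(self$edges$fold == 1))

  # gene absent from both corpora: fold > 1 iff background is larger
  bg0 <- new("WeightTable", nDocs = 8, nodes = c(g = 0), edges = numeric(0))
  qt0 <- new("WeightTable", nDocs = 4, nodes = c(g = 0), edges = numeric(0))
  expect_gt(cooccurrenceEnrichment(bg0, qt0)$nodes$fold, 1)

  empty <- new("WeightTable", nDocs = 0, nodes = c(g = 0), edges = numeric(0))
  expect_error(cooccurrenceEnrichment(bg, empty), "no documents")
})

test_that("network annotation attaches fold changes and defaults to 1.0", {
  net <- parseKgml(makeToyKgml(3, 2, seed = 5))
  enr <- list(nodes = data.frame(name = "G1", backgroundCount = 5,
                                 queryCount = 5, fold = 2.0),
              edges = data.frame(name = character(0), backgroundCount = numeric(0),
                                 queryCount = numeric(0), fold = numeric(0)),
              backgroundN = 10, queryN = 5, pseudocount = 0.5)
  class(enr) <- "enrichment_result"
  txt <- annotateNetwork(net, enr, format = "dot")
  expect_match(txt, '"G1" \\[size=2\\]')
  expect_match(txt, '"G2" \\[size=1\\]')
  badEnr <- enr
  badEnr$nodes$name <- "ZZZ"
  expect_error(annotateNetwork(net, badEnr), "no genes matched")

  # two queries over the same network give distinct, deterministic overlays
  corp <- makeToyCorpus(paste0("G", 1:3), 150, "queryA",
                        enrichedGenes = "G1", seed = 21)
  corp$entity_text[corp$entity_text == "Homo_sapiens"][1:30] <- "queryB"
  bg <- countWeights(corp, paste0("G", 1:3))
  ea <- cooccurrenceEnrichment(bg, countWeights(filterCorpus(corp, "queryA"),
                                                paste0("G", 1:3)))
  eb <- cooccurrenceEnrichment(bg, countWeights(filterCorpus(corp, "queryB"),
                                                paste0("G", 1:3)))
  ta <- annotateNetwork(net, ea)
  tb <- annotateNetwork(net, eb)
  expect_false(identical(ta, tb))
  expect_identical(ta, annotateNetwork(net, ea))
  # attributes strictly positive
  expect_true(all(ea$nodes$fold > 0) && all(ea$edges$fold > 0))
})
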