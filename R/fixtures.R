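# Seeded generators of synthetic inputs: toy KGML pathways, annotated
# corpora, noisy time courses and canonical loop models. All are pure
# functions of their arguments and seed (the caller's RNG state is left
# untouched), so every other module is testable without any download.

TOY_SUBTYPES <- c("activation", "activation+phosphorylation", "inhibition",
                  "binding/association", "expression")

#' Generate a toy KGML pathway
#'
#' Well-formed KGML with `pathway`/`entry`/`graphics`/`relation`/`subtype`
#' elements: `nGenes` gene entries named G1..Gn (with a dummy alias, as in
#' KEGG's comma-separated graphics names) and `nRelations` relations over
#' distinct ordered gene pairs, subtypes drawn from `subtypeMix`.
#' Expression relations get type GErel, everything else PPrel. Same
#' arguments and seed give identical bytes.
#'
#' @param nGenes number of gene entries (>= 2).
#' @param nRelations number of relations; at most nGenes*(nGenes-1).
#' @param subtypeMix named numeric vector of sampling weights over
#'   `r toString(TOY_SUBTYPES)`; default uniform.
#' @param seed RNG seed.
#' @return KGML XML text.
#' @export
makeToyKgml <- function(nGenes, nRelations, subtypeMix = NULL, seed = 1L) {
  stopifnot(nGenes >= 2L, nRelations >= 0L)
  if (nRelations > nGenes * (nGenes - 1L))
    stop("infeasible: more relations than ordered gene pairs", call. = FALSE)
  if (is.null(subtypeMix))
    subtypeMix <- setNames(rep(1, length(TOY_SUBTYPES)), TOY_SUBTYPES)
  if (!all(names(subtypeMix) %in% TOY_SUBTYPES))
    stop("unknown subtype in subtypeMix", call. = FALSE)
  withSeed(seed, {
    genes <- paste0("G", seq_len(nGenes))
    pairs <- expand.grid(src = seq_len(nGenes), tgt = seq_len(nGenes))
    pairs <- pairs[pairs$src != pairs$tgt, , drop = FALSE]
    sel <- pairs[sample.int(nrow(pairs), nRelations), , drop = FALSE]
    subs <- sample(names(subtypeMix), nRelations, replace = TRUE,
                   prob = subtypeMix)
    entryLines <- sprintf(paste0(
      '  <entry id="%d" name="hsa:%d" type="gene">\n',
      '    <graphics name="%s, %s_alias" type="rectangle" x="%d" y="%d"/>\n',
      '  </entry>'),
      seq_len(nGenes), 1000L + seq_len(nGenes), genes, genes,
      40L * seq_len(nGenes), 60L + 10L * seq_len(nGenes))
    relLines <- vapply(seq_len(nRelations), function(k) {
      stNames <- strsplit(subs[k], "+", fixed = TRUE)[[1]]
      stXml <- paste(sprintf('    <subtype name="%s" value="--&gt;"/>', stNames),
                     collapse = "\n")
      rtype <- if (identical(subs[k], "expression")) "GErel" else "PPrel"
      sprintf('  <relation entry1="%d" entry2="%d" type="%s">\n%s\n  </relation>',
              sel$src[k], sel$tgt[k], rtype, stXml)
    }, character(1))
    paste(c('<?xml version="1.0"?>',
            '<pathway name="path:toy0001" org="toy" number="0001" title="Toy pathway">',
            entryLines, relLines, '</pathway>'),
          collapse = "\n")
  })
}

#' Generate a toy annotated corpus
#'
#' Documents mention the query term with probability `pQuery`; each gene is
#' mentioned with probability `pEnriched` (default 0.8) in query documents
#' when it belongs to `enrichedGenes`, and `pBackground` (default 0.2)
#' otherwise. Written in the corpus format (document_id, entity_text,
#' entity_type).
#'
#' @param genes gene names.
#' @param nDocs number of documents (>= 2).
#' @param queryTerm the planted query entity (annotated as a cell line).
#' @param enrichedGenes subset of `genes` co-mentioned with the query.
#' @param seed RNG seed.
#' @param pQuery,pEnriched,pBackground mention probabilities.
#' @return corpus data.frame.
#' @export
makeToyCorpus <- function(genes, nDocs, queryTerm, enrichedGenes = character(0),
                          seed = 1L, pQuery = 0.3, pEnriched = 0.8,
                          pBackground = 0.2) {
  if (nDocs < 2L) stop("need at least 2 documents", call. = FALSE)
  if (!all(enrichedGenes %in% genes))
    stop("enrichedGenes must be a subset of genes", call. = FALSE)
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nDocs)) {
      id <- sprintf("d%04d", i)
      hasQuery <- stats::runif(1) < pQuery
      if (hasQuery)
        rows[[length(rows) + 1L]] <- data.frame(
          document_id = id, entity_text = queryTerm, entity_type = "cellline",
          stringsAsFactors = FALSE)
      for (g in genes) {
        p <- if (hasQuery && g %in% enrichedGenes) pEnriched else pBackground
        if (stats::runif(1) < p)
          rows[[length(rows) + 1L]] <- data.frame(
            document_id = id, entity_text = g, entity_type = "gene",
            stringsAsFactors = FALSE)
      }
      # every document carries at least a neutral marker mention so it is
      # represented in the corpus even when no gene fires
      rows[[length(rows) + 1L]] <- data.frame(
        document_id = id, entity_text = "Homo_sapiens", entity_type = "species",
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate a noisy synthetic time course with hidden truth
#'
#' Simulates the model at the given parameters, evaluates and normalizes
#' the observables at `nTimes` evenly spaced points per condition
#' (excluding t = 0), and multiplies each value by seeded lognormal noise
#' with coefficient of variation `noiseCv` (mean 1). Lognormal noise
#' matches positive, heteroscedastic immunoblot intensities. The returned
#' truth record enables parameter-recovery tests.
#'
#' @param model a compiled (optionally constrained) [OdeModel-class] with
#'   observables.
#' @param trueParams named parameter vector used as ground truth.
#' @param conditions named list of [simCondition()]s.
#' @param nTimes data points per (observable, condition).
#' @param noiseCv coefficient of variation of the multiplicative noise
#'   (0 = exact).
#' @param seed RNG seed.
#' @return list: `table` (experiment table), `truth` (the full parameter
#'   vector after constraints).
#' @export
makeSyntheticTimecourse <- function(model, trueParams, conditions, nTimes = 25L,
                                    noiseCv = 0.05, seed = 1L) {
  stopifnot(is(model, "OdeModel"), nTimes >= 2L, noiseCv >= 0)
  p <- trueParams[model@parameters$name]
  if (any(is.na(p))) stop("trueParams must cover every model parameter", call. = FALSE)
  if (length(model@constraints)) p <- applyConstraints(p, model)
  rows <- lapply(conditions, function(cond) {
    tpts <- seq(0, cond$duration, length.out = nTimes + 1L)[-1L]
    tr <- integrateModel(model, params = p, condition = cond,
                         times = c(0, tpts))
    df <- observableSeries(tr, model)
    df[df$time > 0, , drop = FALSE]
  })
  tab <- normalizeSeries(do.call(rbind, rows))
  tab$value <- tab$normalized
  tab$normalized <- NULL
  if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    noise <- withSeed(seed, stats::rlnorm(nrow(tab), meanlog = -sdlog^2 / 2,
                                          sdlog = sdlog))
    tab$value <- tab$value * noise
  }
  rownames(tab) <- NULL
  list(table = asExperimentTable(tab), truth = p)
}

#' Canonical four-reaction binding diamond
#'
#' Two assembly routes to the ternary complex ABC (via AB and via AC);
#' the loop of four reversible bindings is the minimal thermodynamic
#' cycle: compiled, it has 6 species and 8 rate constants, one of which
#' detailed balance derives.
#'
#' @return model text.
#' @export
makeDiamondModel <- function() {
  paste(c("A binds B --> AB",
          "AB binds C --> ABC",
          "A binds C --> AC",
          "AC binds B --> ABC",
          "@init A = 1", "@init B = 1", "@init C = 1"),
        collapse = "\n")
}

#' Three-reaction protein-turnover model for recovery benchmarks
#'
#' Synthesis of A, reversible activation A <-> pA, degradation of pA, with
#' both forms observed. The activation, deactivation and degradation rates
#' shape the normalized time courses and are identifiable from them; the
#' synthesis rate only sets the absolute scale, which normalization
#' removes.
#'
#' @return model text.
#' @export
makeTurnoverModel <- function() {
  paste(c("A is synthesized | kf=0.5",
          "A is phosphorylated --> pA | kf=2, kr=1",
          "pA is degraded | kf=0.8",
          "@init A = 1",
          "@obs A: A",
          "@obs pA: pA"),
        collapse = "\n")
}
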