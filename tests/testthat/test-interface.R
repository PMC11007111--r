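# Graph export, prompt construction, candidate-output validation, CLI.

test_that("DOT export of the bind model has 3 nodes and 2 conversion edges", {
  txt <- exportGraph(bindModel(), format = "dot")
  expect_match(txt, '"A" -> "AB" \\[style=solid')
  expect_match(txt, '"B" -> "AB" \\[style=solid')
  expect_identical(length(grep("->", strsplit(txt, "\n")[[1]], fixed = TRUE)), 2L)
})

test_that("enzymatic edges are styled distinctly from conversion edges", {
  m <- compileModel(parseRxnModel(
    "E phosphorylates S --> pS\n@init E = 1\n@init S = 1"))
  txt <- exportGraph(m, format = "dot")
  expect_match(txt, '"S" -> "pS" \\[style=solid')
  expect_match(txt, '"E" -> "pS" \\[style=dashed')
})

test_that("the diamond model's exported graph contains a cycle", {
  skip_if_not_installed("igraph")
  f <- withr::local_tempfile(fileext = ".graphml")
  exportGraph(diamondModel(), format = "graphml", file = f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 6)
  expect_gt(igraph::girth(igraph::as_undirected(g))$girth, 2)
})

test_that("GraphML output is well-formed XML that igraph can read, with weights attached", {
  skip_if_not_installed("igraph")
  txt <- exportGraph(bindModel(), format = "graphml",
                     weights = list(nodes = c(AB = 2.5)))
  doc <- xml2::read_xml(txt)  # errors if malformed
  expect_identical(xml2::xml_name(doc), "graphml")
  f <- withr::local_tempfile(fileext = ".graphml")
  writeLines(txt, f)
  g <- igraph::read_graph(f, format = "graphml")
  va <- igraph::vertex_attr(g)
  ids <- if (!is.null(va$name)) va$name else va$id
  expect_equal(va$size[match("AB", ids)], 2.5)
  expect_error(exportGraph(bindModel(), format = "svg"))
})

test_that("prompts contain the three parts in order and reject broken exemplars", {
  prompt <- buildLlmPrompt("Model the passage faithfully.",
                           "Kinase K phosphorylates substrate S.",
                           "K phosphorylates S --> pS",
                           "Receptor R binds ligand L.")
  sections <- c("## Task", "## Example passage", "## Example output", "## Passage")
  pos <- vapply(sections, function(s) regexpr(s, prompt, fixed = TRUE)[1],
                numeric(1))
  expect_true(all(diff(pos) > 0))
  expect_match(prompt, "K phosphorylates S --> pS", fixed = TRUE)
  expect_match(prompt, "Extract the biochemical reactions", fixed = TRUE)
  # identical template -> identical bytes
  prompt2 <- buildLlmPrompt("Model the passage faithfully.",
                            "Kinase K phosphorylates substrate S.",
                            "K phosphorylates S --> pS",
                            "Receptor R binds ligand L.")
  expect_identical(prompt, prompt2)
  expect_error(buildLlmPrompt("t", "p", "K frobnicates S", "x"),
               "frobnicates")
  expect_error(buildLlmPrompt("t", "p", "K phosphorylates S --> pS", "  "),
               "non-empty")
})

test_that("candidate model text is validated tolerantly with structural warnings", {
  out <- validateLlmOutput(paste(
    "R binds L --> RL",
    "RL phosphorylates S --> pS",
    "@init R = 1", "@init L = 1", "@init S = 1", sep = "\n"))
  expect_s4_class(out$model, "RxnModel")
  # pS never reverts or degrades -> sink warning
  expect_true(any(grepl("pS has no sink", out$issues$message)))

  out2 <- validateLlmOutput("R binds L --> RL\nthis is not a reaction\nRL is degraded\n@init R = 1\n@init L = 1")
  expect_length(reactions(out2$model), 2)
  expect_true(any(out2$issues$severity == "error" & grepl("line 2", out2$issues$message)))

  clean <- validateLlmOutput("A binds B --> AB\nAB is degraded\n@init A = 1\n@init B = 1")
  expect_identical(nrow(clean$issues), 0L)

  # an unconstrained cycle is flagged so the curator can constrain it
  out3 <- validateLlmOutput(makeDiamondModel())
  expect_true(any(grepl("detailed-balance", out3$issues$message)))
})

test_that("the CLI compiles, converts and reports errors with nonzero status", {
  dir <- withr::local_tempdir()
  modelFile <- file.path(dir, "model.txt")
  writeLines(makeDiamondModel(), modelFile)
  rep <- file.path(dir, "report.txt")
  expect_identical(cliMain(c("compile", modelFile, "--constrain", "--out", rep)), 0L)
  expect_match(paste(readLines(rep), collapse = "\n"), "kr_r4")

  kgml <- file.path(dir, "toy.xml")
  writeLines(makeToyKgml(4, 3, seed = 2), kgml)
  out <- file.path(dir, "model_from_kgml.txt")
  expect_identical(
    suppressMessages(cliMain(c("kgml2text", kgml, "--out", out))), 0L)
  expect_silent(m <- parseRxnModel(readLines(out)))

  expect_identical(suppressMessages(cliMain(c("compile", file.path(dir, "absent.txt")))), 1L)
  expect_identical(suppressMessages(cliMain(character(0))), 1L)
  expect_identical(suppressMessages(cliMain("not-a-command")), 1L)
})

test_that("the CLI pipeline is byte-identical across repeated seeded runs", {
  dir <- withr::local_tempdir()
  modelFile <- file.path(dir, "model.txt")
  writeLines(makeTurnoverModel(), modelFile)
  st <- turnoverStudy(noiseCv = 0.05)
  dataFile <- file.path(dir, "data.tsv")
  utils::write.table(st$table, dataFile, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  run <- function(tag) {
    outs <- file.path(dir, paste0(c("sim", "ens", "sens"), tag, ".tsv"))
    cliMain(c("simulate", modelFile, "--condition", "basal:",
              "--condition", "pulse:A=3", "--duration", "5", "--n", "21",
              "--out", outs[1]))
    suppressMessages(cliMain(c("fit", modelFile, "--data", dataFile,
              "--condition", "basal:", "--condition", "pulse:A=3",
              "--duration", "5", "--n-sets", "2", "--pop", "8",
              "--max-eval", "48", "--seed", "7", "--out", outs[2])))
    cliMain(c("sensitivity", modelFile, "--condition", "basal:",
              "--metric", "peak:max:pA", "--duration", "5", "--out", outs[3]))
    lapply(outs, readLines)
  }
  expect_identical(run("a"), run("b"))
})
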