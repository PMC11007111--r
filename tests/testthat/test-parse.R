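# Reaction-language parser: grammar, aggregation, round trip, totality.

test_that("each grammar form parses to the expected reaction structure", {
  cases <- list(
    list("A binds B --> AB", "bind", c("A", "B"), "AB", TRUE, "mass_action"),
    list("AB is dissociated into A and B", "dissociate", "AB", c("A", "B"),
         TRUE, "mass_action"),
    list("E phosphorylates S --> pS", "enzymatic_modify", "S", "pS", FALSE,
         "michaelis_menten"),
    list("E dephosphorylates pS --> S", "enzymatic_modify", "pS", "S", FALSE,
         "michaelis_menten"),
    list("S is phosphorylated --> pS", "state_transition", "S", "pS", TRUE,
         "mass_action"),
    list("pS is dephosphorylated --> S", "state_transition", "pS", "S", FALSE,
         "mass_action"),
    list("TF transcribes M", "transcribe", character(0), "M", FALSE, "hill"),
    list("M is translated into P", "translate", "M", "P", FALSE, "mass_action"),
    list("EGFR_dimer is degraded", "degrade", "EGFR_dimer", character(0),
         FALSE, "mass_action"),
    list("X is synthesized", "synthesize", character(0), "X", FALSE,
         "zeroth_order"))
  for (cs in cases) {
    st <- parseStatement(cs[[1]], 1)
    expect_identical(st$kind, "reaction")
    r <- st$reaction
    expect_identical(r$type, cs[[2]], info = cs[[1]])
    expect_identical(r$reactants, cs[[3]], info = cs[[1]])
    expect_identical(r$products, cs[[4]], info = cs[[1]])
    expect_identical(r$reversible, cs[[5]], info = cs[[1]])
    expect_identical(r$family, cs[[6]], info = cs[[1]])
  }
})

test_that("enzyme, overrides, comments and blanks are captured", {
  r <- parseStatement("E phosphorylates S --> pS | V=2, K=0.5", 3)$reaction
  expect_identical(r$enzyme, "E")
  expect_equal(r$overrides, c(V = 2, K = 0.5))
  expect_identical(parseStatement("# a comment", 1)$kind, "comment")
  expect_identical(parseStatement("   ", 1)$kind, "blank")
  expect_identical(parseStatement("", 1)$kind, "blank")
  # trailing comments are stripped
  r2 <- parseStatement("A is degraded  # auto-added", 2)$reaction
  expect_identical(r2$type, "degrade")
})

test_that("unknown verbs and malformed overrides raise classed errors naming the token", {
  err <- tryCatch(parseStatement("A frobnicates B", 7),
                  reactode_parse_error = function(e) e)
  expect_s3_class(err, "reactode_parse_error")
  expect_match(conditionMessage(err), "line 7")
  expect_match(conditionMessage(err), "frobnicates")
  expect_error(parseStatement("A is degraded | kf", 2), "override")
  expect_error(parseStatement("A is degraded | q==1", 2), "override")
})

test_that("directives parse with their payloads", {
  d <- parseStatement("@obs pTotal: pA + 2*pB", 1)$directive
  expect_identical(d$keyword, "obs")
  expect_equal(d$coef, c(pA = 1, pB = 2))
  d <- parseStatement("@init A = 1.5", 2)$directive
  expect_equal(d$amount, 1.5)
  d <- parseStatement("@sim_condition EGF: EGF=10, HRG=0", 3)$directive
  expect_equal(d$overrides, c(EGF = 10, HRG = 0))
  d <- parseStatement("@param_bound kf_r1: 0.01 100", 4)$directive
  expect_equal(c(d$lower, d$upper), c(0.01, 100))
  expect_error(parseStatement("@init A = -1", 1), "nonnegative")
  expect_error(parseStatement("@nonsense x", 1), "unknown directive")
})

test_that("multi-line parse keeps order, aggregates errors, rejects duplicates and empty input", {
  m <- parseRxnModel("A binds B --> AB\nE phosphorylates S --> pS\nAB is degraded")
  expect_length(reactions(m), 3)
  expect_identical(vapply(reactions(m), `[[`, character(1), "type"),
                   c("bind", "enzymatic_modify", "degrade"))
  expect_identical(vapply(reactions(m), `[[`, numeric(1), "line"), c(1, 2, 3))

  err <- tryCatch(parseRxnModel("A frobnicates B\nC blorps D\nA is degraded"),
                  reactode_parse_error = function(e) e)
  expect_match(conditionMessage(err), "line 1")
  expect_match(conditionMessage(err), "line 2")

  err <- tryCatch(parseRxnModel("A binds B --> AB\nX is degraded\nA binds B --> AB"),
                  reactode_parse_error = function(e) e)
  expect_match(conditionMessage(err), "duplicate")
  expect_match(conditionMessage(err), "1, 3")

  expect_error(parseRxnModel(""), "no reactions")
  expect_error(parseRxnModel("# only a comment"), "no reactions")
})

test_that("rendering a model and re-parsing yields an identical model", {
  txt <- paste("A binds B --> AB | kf=2.5, kr=0.125",
               "E phosphorylates AB --> pAB",
               "pAB is degraded | kf=0.3333333333333333",
               "TF transcribes M",
               "M is translated into P",
               "@obs signal: pAB + 2*P",
               "@init A = 1", "@init B = 0.5", "@init E = 0.1", "@init TF = 1",
               "@sim_condition stim: A=10",
               "@param_bound kf_r1: 0.001 10", sep = "\n")
  m1 <- parseRxnModel(txt)
  canon <- renderRxnModel(m1)
  m2 <- parseRxnModel(canon)
  expect_identical(renderRxnModel(m2), canon)
  expect_equal(reactions(m2), reactions(m1), ignore_attr = FALSE)
  expect_equal(directives(m2), directives(m1))
})

test_that("parsing is total: arbitrary byte strings give one statement or one recorded error", {
  set.seed(42)
  alphabet <- c(letters, LETTERS, 0:9, " ", "-", ">", "|", "=", "@", "#", "_",
                ".", "(", ")", "*", "&", "\t")
  for (i in 1:200) {
    txt <- paste(sample(alphabet, sample(0:30, 1), replace = TRUE), collapse = "")
    res <- tryCatch(parseStatement(txt, i), reactode_parse_error = function(e) e)
    ok <- inherits(res, "reactode_parse_error") ||
      (is.list(res) && res$kind %in% c("reaction", "directive", "comment", "blank"))
    expect_true(ok, info = txt)
  }
})

test_that("validation flags sourceless species and unknown observable references", {
  m <- parseRxnModel("C phosphorylates S --> pS\n@init S = 1")
  iss <- validateRxnModel(m)
  expect_identical(iss$severity, "warning")
  expect_match(iss$message, "C has no source and no initial value")

  m <- parseRxnModel("A is degraded\n@init A = 1\n@obs q: Q")
  iss <- validateRxnModel(m)
  expect_true(any(iss$severity == "error" & grepl("'Q'", iss$message)))

  m <- parseRxnModel(paste("A binds B --> AB", "AB is degraded",
                           "@init A = 1", "@init B = 1", sep = "\n"))
  expect_identical(nrow(validateRxnModel(m)), 0L)
})
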