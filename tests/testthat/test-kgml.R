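# KGML import: parsing, state expansion, conversion to model text.

twoEntryKgml <- function(subtypes = c("activation", "phosphorylation")) {
  st <- paste(sprintf('    <subtype name="%s" value="--&gt;"/>', subtypes),
              collapse = "\n")
  paste0('<?xml version="1.0"?>\n<pathway name="path:test" org="hsa" number="1">\n',
         '  <entry id="1" name="hsa:1956" type="gene">\n',
         '    <graphics name="EGFR, ERBB1" type="rectangle"/>\n  </entry>\n',
         '  <entry id="2" name="hsa:207" type="gene">\n',
         '    <graphics name="AKT1, PKB" type="rectangle"/>\n  </entry>\n',
         '  <relation entry1="1" entry2="2" type="PPrel">\n', st,
         '\n  </relation>\n</pathway>')
}

test_that("entries and subtyped relations are captured; display = first name token", {
  net <- parseKgml(twoEntryKgml())
  expect_identical(nrow(net@entries), 2L)
  expect_identical(net@entries$display, c("EGFR", "AKT1"))
  expect_identical(nrow(net@relations), 1L)
  expect_identical(net@relations$subtypes, "activation;phosphorylation")
  expect_false(net@stateExpanded)
})

test_that("malformed XML, wrong root and empty pathways are errors", {
  expect_error(parseKgml("<pathway><entry id='1'"), "malformed")
  expect_error(parseKgml("<notapathway/>"), "not a KGML")
  expect_error(parseKgml("<pathway name='p'/>"), "empty pathway")
})

test_that("relations with missing endpoints are dropped with a warning", {
  xml <- sub('entry1="1"', 'entry1="99"', twoEntryKgml())
  expect_warning(net <- parseKgml(xml), "missing endpoint")
  expect_identical(nrow(net@relations), 0L)
})

test_that("state expansion adds p/a-prefixed active forms and re-sources outgoing edges", {
  # A -activation+phosphorylation-> B, B -activation-> C
  xml <- paste0(
    '<pathway name="p">',
    '<entry id="1" type="gene"><graphics name="A"/></entry>',
    '<entry id="2" type="gene"><graphics name="B"/></entry>',
    '<entry id="3" type="gene"><graphics name="C"/></entry>',
    '<relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="activation" value="--&gt;"/>',
    '<subtype name="phosphorylation" value="--&gt;"/></relation>',
    '<relation entry1="2" entry2="3" type="PPrel">',
    '<subtype name="activation" value="--&gt;"/></relation>',
    '</pathway>')
  net <- expandStates(parseKgml(xml))
  expect_setequal(net@species$species, c("A", "B", "pB", "C", "aC"))
  expect_identical(net@relations$sourceSpecies, c("A", "pB"))
  expect_identical(net@relations$targetActive, c("pB", "aC"))
  expect_error(expandStates(net), "already expanded")

  conv <- networkToText(net)
  expect_identical(strsplit(conv$text, "\n")[[1]],
                   c("A phosphorylates B --> pB",
                     "pB phosphorylates C --> aC",
                     "pB is dephosphorylated --> B",
                     "aC is dephosphorylated --> C"))
})

test_that("an isolated entry stays a single species", {
  xml <- '<pathway name="p"><entry id="1" type="gene"><graphics name="LONER"/></entry></pathway>'
  net <- expandStates(parseKgml(xml))
  expect_identical(net@species$species, "LONER")
})

test_that("conversion follows the subtype mapping table", {
  net <- expandStates(parseKgml(twoEntryKgml()))
  conv <- networkToText(net)
  expect_identical(strsplit(conv$text, "\n")[[1]],
                   c("EGFR phosphorylates AKT1 --> pAKT1",
                     "pAKT1 is dephosphorylated --> AKT1"))
  # degradation option appends a line; missing species is an error
  conv2 <- networkToText(net, conversionOptions(degrade = "pAKT1"))
  expect_identical(conv2$report$lines, 3L)
  expect_match(conv2$text, "pAKT1 is degraded")
  expect_error(networkToText(net, conversionOptions(degrade = "XX")),
               "does not exist")
  # binding is already reversible: no reverse line added
  net3 <- expandStates(parseKgml(twoEntryKgml("binding/association")))
  conv3 <- networkToText(net3)
  expect_identical(conv3$text, "EGFR binds AKT1 --> EGFR_AKT1")
  # expression maps to transcription
  net4 <- expandStates(parseKgml(sub("PPrel", "GErel",
                                     twoEntryKgml("expression"))))
  expect_identical(networkToText(net4)$text, "EGFR transcribes AKT1")
})

test_that("explicit deactivators suppress the auto reverse reaction", {
  xml <- paste0(
    '<pathway name="p">',
    '<entry id="1" type="gene"><graphics name="K"/></entry>',
    '<entry id="2" type="gene"><graphics name="S"/></entry>',
    '<entry id="3" type="gene"><graphics name="PP"/></entry>',
    '<relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="phosphorylation" value="+p"/></relation>',
    '<relation entry1="3" entry2="2" type="PPrel">',
    '<subtype name="dephosphorylation" value="-p"/></relation>',
    '</pathway>')
  conv <- networkToText(expandStates(parseKgml(xml)))
  expect_identical(conv$report$reverseAdded, 0L)
  expect_identical(strsplit(conv$text, "\n")[[1]],
                   c("K phosphorylates S --> pS",
                     "PP dephosphorylates pS --> S"))
})

test_that("skipped subtypes are counted; unmapped subtypes are errors", {
  net <- expandStates(parseKgml(twoEntryKgml("indirect effect")))
  conv <- networkToText(net)
  expect_identical(conv$report$skipped, 1L)
  expect_identical(conv$report$lines, 0L)
  net2 <- expandStates(parseKgml(twoEntryKgml("state change")))
  expect_error(networkToText(net2), "unmapped subtype")
  # but any subtype can be declared skippable
  conv2 <- networkToText(net2, conversionOptions(skip = "state change"))
  expect_identical(conv2$report$skipped, 1L)
})

test_that("map entries are retained but excluded from reaction generation", {
  xml <- paste0(
    '<pathway name="p">',
    '<entry id="1" type="gene"><graphics name="A"/></entry>',
    '<entry id="2" type="map"><graphics name="Other pathway"/></entry>',
    '<relation entry1="1" entry2="2" type="maplink">',
    '<subtype name="activation" value="--&gt;"/></relation>',
    '</pathway>')
  net <- expandStates(parseKgml(xml))
  expect_identical(nrow(net@entries), 2L)
  expect_identical(net@species$species, "A")
  conv <- networkToText(net)
  expect_identical(conv$report$lines, 0L)
  expect_identical(conv$report$skipped, 1L)
})

test_that("group entries become complex species joining member names", {
  xml <- paste0(
    '<pathway name="p">',
    '<entry id="1" type="gene"><graphics name="PIK3CA"/></entry>',
    '<entry id="2" type="gene"><graphics name="PIK3R1"/></entry>',
    '<entry id="3" type="group"><graphics name="undefined"/>',
    '<component id="1"/><component id="2"/></entry>',
    '<entry id="4" type="gene"><graphics name="AKT1"/></entry>',
    '<relation entry1="3" entry2="4" type="PPrel">',
    '<subtype name="activation" value="--&gt;"/>',
    '<subtype name="phosphorylation" value="+p"/></relation>',
    '</pathway>')
  conv <- networkToText(expandStates(parseKgml(xml)))
  expect_match(conv$text, "PIK3CA_PIK3R1 phosphorylates AKT1 --> pAKT1",
               fixed = TRUE)
})

test_that("generated text round-trips through the parser on randomized fixtures", {
  for (seed in 1:8) {
    xml <- makeToyKgml(6, 8, seed = seed)
    conv <- networkToText(expandStates(parseKgml(xml)))
    if (conv$report$lines == 0) next
    m <- parseRxnModel(conv$text)
    expect_length(reactions(m), conv$report$lines)
    # provenance is total and injective over generated lines
    expect_identical(conv$provenance$line, seq_len(conv$report$lines))
    rel <- conv$provenance$relation[conv$provenance$origin == "relation"]
    expect_false(anyDuplicated(rel) > 0)
  }
})
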