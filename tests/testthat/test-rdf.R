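test_that("an empty knowledge base exports the full schema", {
  doc <- export_rdf(kb_new())
  tr <- parse_turtle(doc)
  props <- stepcoach:::kb_schema_properties()
  for (p in props$property) {
    expect_true(any(tr$subject == paste0("sc:", p) &
                      tr$predicate == "rdf:type"))
    expect_true(any(tr$subject == paste0("sc:", p) &
                      tr$predicate == "rdfs:domain"))
    expect_true(any(tr$subject == paste0("sc:", p) &
                      tr$predicate == "rdfs:range"))
  }
  expect_equal(nrow(tr), 3 * nrow(props))
})

test_that("instance annotations round-trip with conserved triple counts", {
  kb <- kb_new()
  kb <- kb_add_level(kb, "P-1", "2023-01-01", 2)
  kb <- kb_add_prediction(kb, "P-1", "2023-01-07", 1, 3520, 1893, 5147)
  kb <- kb_add_stat(kb, "P-1", 1, "sc", 2)
  kb <- kb_add_recommendation(kb, "P-1", "2023-01-01", "A-8",
                              render_message("A-8", list(x = 1, x1 = 2)))
  doc <- export_rdf(kb)
  tr <- parse_turtle(doc)
  expect_equal(nrow(tr), kb_triple_count(kb))
  # write + reparse from file conserves the count too
  f <- tempfile(fileext = ".ttl")
  export_rdf(kb, f)
  expect_equal(nrow(parse_turtle(f)), nrow(tr))
  # timestamps ride along with recommendations and levels
  expect_true(any(tr$predicate == "sc:HasTimeStamp" &
                    grepl("2023-01-01", tr$object)))
})

test_that("recommendation queries return the fired variable ids", {
  kb <- kb_new()
  for (v in c("A-1", "A-7", "A-8", "A-10", "A-15")) {
    kb <- kb_add_recommendation(kb, "P-1", "2023-01-20", v, "msg")
  }
  tr <- parse_turtle(export_rdf(kb))
  nodes <- ttl_query(tr, "sc:HasReceivedPersonalRecommendation",
                     subject = "sc:P_1")
  expect_length(nodes, 5)
  ids <- vapply(nodes, function(n) {
    gsub('"', "", ttl_query(tr, "sc:variableId", subject = n))
  }, "")
  expect_setequal(unname(ids), c("A-1", "A-7", "A-8", "A-10", "A-15"))
})

test_that("undeclared variables cannot be annotated", {
  expect_error(kb_add_recommendation(kb_new(), "P-1", "2023-01-01",
                                     "A-99", "msg"), "undeclared")
})

test_that("the exported Turtle parses with a standard RDF parser", {
  py <- Sys.which("python")
  skip_if(py == "", "no python available for the rdflib oracle")
  has_rdflib <- system2(py, c("-c", shQuote("import rdflib")),
                        stdout = FALSE, stderr = FALSE) == 0
  skip_if(!has_rdflib, "python rdflib not available")
  kb <- kb_add_level(kb_new(), "P-1", "2023-01-01", 2)
  f <- tempfile(fileext = ".ttl")
  export_rdf(kb, f)
  script <- sprintf(
    "import rdflib; g = rdflib.Graph(); g.parse(%s, format='turtle'); print(len(g))",
    shQuote(f))
  n <- as.integer(system2(py, c("-c", shQuote(script)), stdout = TRUE))
  expect_equal(n, kb_triple_count(kb))
})
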