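# Semantic annotation: qualifiers, identifiers.org URIs, RDF embedding.

test_that("adding the calcium isVersionOf annotation stores the expected triple", {
  m <- parse_cellml(make_decay(), "decay.cellml")
  # model an intracellular-calcium-style subject on the state variable
  m <- add_annotation(m, "y", "bio:isVersionOf", "chebi:CHEBI:29108")
  df <- list_annotations(m)
  expect_identical(nrow(df), 1L)
  expect_identical(df$predicate,
                   "http://biomodels.net/biology-qualifiers/isVersionOf")
  expect_identical(df$object, "http://identifiers.org/chebi/CHEBI:29108")
})

test_that("adding the same triple twice is idempotent", {
  m <- parse_cellml(make_decay(), "decay.cellml")
  m <- add_annotation(m, "y", "bio:isVersionOf", "chebi:CHEBI:29108")
  m <- add_annotation(m, "y", "bio:isVersionOf", "chebi:CHEBI:29108")
  expect_identical(nrow(list_annotations(m)), 1L)
})

test_that("unknown qualifier terms are vocabulary errors listing valid terms", {
  m <- parse_cellml(make_decay())
  err <- expect_cellsim_error(
    add_annotation(m, "y", "bio:isKindaLike", "chebi:CHEBI:29108"),
    "vocabulary")
  expect_match(conditionMessage(err), "isVersionOf")
  expect_cellsim_error(add_annotation(m, "nope", "bio:is", "chebi:X"),
                       "missing-subject")
})

test_that("a fresh fixture model has no annotations; two adds list deterministically", {
  m <- parse_cellml(make_decay(), "decay.cellml")
  expect_identical(nrow(list_annotations(m)), 0L)
  m <- add_annotation(m, "y", "bio:isVersionOf", "chebi:CHEBI:29108")
  m <- add_annotation(m, "main", "model:is", "biomodels.db:BIOMD0000000001")
  df1 <- list_annotations(m)
  df2 <- list_annotations(parse_cellml(serialize_cellml(m), "decay.cellml"))
  expect_identical(df1, df2)
  expect_identical(nrow(df1), 2L)
  expect_identical(df1$subject, sort(df1$subject))
  expect_identical(nrow(list_annotations(m, cmeta_id = "y")), 1L)
})

test_that("MIRIAM URN conversion follows the decoding rule and round-trips", {
  expect_identical(urn_to_identifiers_uri("urn:miriam:obo.go:GO%3A0005248"),
                   "http://identifiers.org/obo.go/GO:0005248")
  expect_identical(urn_to_identifiers_uri("urn:miriam:uniprot:P12345"),
                   "http://identifiers.org/uniprot/P12345")
  expect_cellsim_error(urn_to_identifiers_uri("http://identifiers.org/x/y"),
                       "urn-format")
  # property: uri -> urn -> uri is the identity over a generated sample
  set.seed(7)
  colls <- c("chebi", "obo.go", "uniprot", "kegg.compound", "ensembl")
  for (k in 1:25) {
    id <- paste0(sample(c(LETTERS, 0:9, ":", "."), 8, replace = TRUE),
                 collapse = "")
    uri <- paste0("http://identifiers.org/", sample(colls, 1), "/", id)
    expect_identical(urn_to_identifiers_uri(identifiers_uri_to_urn(uri)), uri)
  }
})

test_that("a document hand-seeded with a MIRIAM URN lists converted and flagged deprecated", {
  rdf <- paste0(
    '  <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">\n',
    '    <rdf:Description rdf:about="#y">\n',
    '      <bqbiol:isVersionOf rdf:resource="urn:miriam:obo.go:GO%3A0005248"/>\n',
    '    </rdf:Description>\n',
    '  </rdf:RDF>')
  txt <- sub("</model>", paste0(rdf, "\n</model>"), make_decay(), fixed = TRUE)
  df <- list_annotations(parse_cellml(txt, "decay.cellml"))
  expect_identical(df$object, "http://identifiers.org/obo.go/GO:0005248")
  expect_true(df$deprecated)
  # objects are re-embedded exclusively in identifiers.org form
  m2 <- embed_rdf(parse_cellml(txt), extract_rdf(parse_cellml(txt)))
  expect_false(grepl("urn:miriam", serialize_cellml(m2), fixed = TRUE))
})

test_that("triple sets round-trip through full document serialization (random sets)", {
  set.seed(11)
  m <- parse_cellml(make_decay(), "decay.cellml")
  quals <- biology_qualifiers()
  for (k in 1:3) {
    m <- add_annotation(m, sample(c("y", "main"), 1),
                        c("biology", sample(quals, 1)),
                        paste0("chebi:CHEBI:", sample(10000:99999, 1)))
  }
  before <- extract_rdf(m)
  after <- extract_rdf(parse_cellml(serialize_cellml(m), "decay.cellml"))
  expect_identical(after, before)
})

test_that("a model with zero triples serializes without an RDF block", {
  m <- parse_cellml(make_decay())
  m <- embed_rdf(m, list())
  expect_false(grepl("rdf:RDF", serialize_cellml(m), fixed = TRUE))
})

test_that("a corrupted RDF block errors but leaves the model simulatable", {
  fx <- make_invalid_suite()[["corrupted-rdf"]]
  m <- parse_cellml(fx$text)
  expect_cellsim_error(extract_rdf(m), "corrupted-rdf")
  store <- run_simulation(build_runtime(m), simulation_setup(0, 1, 0.1))
  expect_length(store$voi, 11)
})

test_that("annotation never perturbs simulation output (bitwise)", {
  m <- parse_cellml(make_decay(), "decay.cellml")
  setup <- simulation_setup(0, 5, 0.1)
  before <- run_simulation(build_runtime(m), setup)
  m2 <- add_annotation(m, "y", "bio:isVersionOf", "chebi:CHEBI:29108")
  m3 <- parse_cellml(serialize_cellml(m2), "decay.cellml")
  expect_identical(nrow(list_annotations(m3)), 1L)  # survives the round trip
  after <- run_simulation(build_runtime(m3), setup)
  expect_identical(after$data, before$data)
  expect_identical(after$voi, before$voi)
})

test_that("metadata-id minting is deterministic and collision-free", {
  m <- parse_cellml(make_fhn())
  r1 <- ensure_cmeta_id(m, "main", "v")
  expect_identical(r1$id, "id_00001")
  r2 <- ensure_cmeta_id(r1$model, "main", "w")
  expect_identical(r2$id, "id_00002")
  # an element that already has an id keeps it
  md <- parse_cellml(make_decay())
  expect_identical(ensure_cmeta_id(md, "main", "y")$id, "y")
  # minted ids are usable annotation subjects
  m3 <- add_annotation(r2$model, "id_00001", "bio:is", "chebi:CHEBI:1")
  expect_identical(list_annotations(m3)$subject, "id_00001")
})
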