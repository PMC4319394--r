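# Parsing, serialization, and round-trip fidelity of CellML documents.

test_that("the decay fixture parses into the expected structure", {
  m <- parse_cellml(make_decay(), "decay.cellml")
  expect_s3_class(m, "cellml_model")
  expect_identical(m$version, "1.0")
  expect_length(m$components, 1)
  expect_named(m$components$main$variables, c("time", "y", "a"))
  expect_length(m$components$main$equations, 1)
  expect_identical(m$components$main$equations[[1]]$kind, "eq")
  expect_identical(m$components$main$equations[[1]]$lhs$kind, "diff")
})

test_that("a non-CellML root element is a format error", {
  expect_cellsim_error(parse_cellml("<html><body/></html>"), "not-cellml")
  expect_cellsim_error(detect_version("<foo xmlns='http://example.org/x'/>"),
                       "not-cellml")
})

test_that("malformed XML reports a parse error with a line number", {
  err <- expect_cellsim_error(parse_cellml("<a>\n<b>\n</a>"), "xml-parse")
  expect_gte(err$location$line, 2L)
})

test_that("version detection is namespace-driven", {
  expect_identical(detect_version(make_decay()), "1.0")
  pair <- make_import_pair()
  expect_identical(detect_version(pair$main), "1.1")
  m <- parse_cellml(pair$main, pair$main_base)
  expect_identical(m$version, "1.1")
  expect_length(m$imports, 1)
  expect_identical(m$imports[[1]]$href, "parts.cellml")
})

test_that("parse/serialize round trip is the structural identity on all valid fixtures", {
  for (nm in names(valid_fixture_texts())) {
    txt <- valid_fixture_texts()[[nm]]
    m <- parse_cellml(txt, "fixture.cellml")
    s <- serialize_cellml(m)
    m2 <- parse_cellml(s, "fixture.cellml")
    expect_identical(strip_locations(m2), strip_locations(m), label = nm)
    # serializing again is byte-idempotent
    expect_identical(serialize_cellml(m2), s, label = nm)
  }
})

test_that("recorded source locations point at lines containing the element's tag", {
  for (txt in list(make_decay(), make_fhn())) {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    m <- parse_cellml(txt)
    check <- function(loc, tag) {
      expect_gte(loc$line, 1L)
      expect_match(lines[loc$line], paste0("<", tag), fixed = TRUE)
    }
    check(m$location, "model")
    for (u in m$units) check(u$location, "units")
    for (comp in m$components) {
      check(comp$location, "component")
      for (v in comp$variables) check(v$location, "variable")
      for (eq in comp$equations) check(eq$location, "apply")
    }
  }
})

test_that("foreign-namespace children survive parse/serialize byte-equivalently", {
  txt <- sub("</model>",
             "  <ext:meta xmlns:ext=\"http://example.org/ext\"><ext:tag a=\"1\"/></ext:meta>\n</model>",
             make_decay(), fixed = TRUE)
  m <- parse_cellml(txt)
  expect_length(m$foreign, 1)
  m2 <- parse_cellml(serialize_cellml(m))
  expect_identical(m2$foreign, m$foreign)
})

test_that("an annotated model serializes with an RDF/XML block", {
  m <- parse_cellml(make_decay(), "decay.cellml")
  m <- add_annotation(m, "y", "bio:isVersionOf", "chebi:CHEBI:29108")
  expect_match(serialize_cellml(m), "<rdf:RDF", fixed = TRUE)
})

test_that("the MathML subset parser accepts an empty math element and rejects unknowns", {
  expect_identical(parse_mathml("<math xmlns='http://www.w3.org/1998/Math/MathML'/>"),
                   list())
  err <- expect_cellsim_error(
    parse_mathml(paste0("<math xmlns='http://www.w3.org/1998/Math/MathML'>",
                        "<apply><eq/><ci>x</ci>",
                        "<apply><vector/><ci>y</ci></apply>",
                        "</apply></math>")),
    "unsupported-operator")
  expect_match(conditionMessage(err), "vector")
  expect_cellsim_error(
    parse_mathml(paste0("<math xmlns='http://www.w3.org/1998/Math/MathML'>",
                        "<apply><eq/><ci>x</ci><cn>1</cn></apply></math>")),
    "cn-without-units")
})

test_that("piecewise, logbase and root degree are parsed and evaluated", {
  frag <- paste0(
    "<math xmlns='http://www.w3.org/1998/Math/MathML'>",
    "<apply><eq/><ci>r</ci>",
    "<piecewise>",
    "<piece><cn cellml:units='dimensionless' xmlns:cellml='http://www.cellml.org/cellml/1.0#'>1</cn>",
    "<apply><lt/><ci>x</ci><cn cellml:units='dimensionless' xmlns:cellml='http://www.cellml.org/cellml/1.0#'>0</cn></apply></piece>",
    "<otherwise><cn cellml:units='dimensionless' xmlns:cellml='http://www.cellml.org/cellml/1.0#'>2</cn></otherwise>",
    "</piecewise></apply></math>")
  eqs <- parse_mathml(frag)
  expect_length(eqs, 1)
  pw <- eqs[[1]]$rhs
  expect_identical(pw$kind, "piecewise")
  expect_length(pw$pieces, 1)
  expect_identical(pw$otherwise$value, 2)
  # rendered R expression evaluates both branches correctly
  code <- cellsim:::math_to_r(pw, function(nm) "x", function(nm) stop("no rates"))
  x <- -1; expect_equal(eval(parse(text = code)), 1)
  x <- 1;  expect_equal(eval(parse(text = code)), 2)
})
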