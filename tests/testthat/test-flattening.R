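# Import resolution (CellML 1.1 -> standalone 1.0).

test_that("the import pair flattens to a standalone 1.0 model with the decay census", {
  pair <- make_import_pair()
  m <- parse_cellml(pair$main, pair$main_base)
  flat <- resolve_imports(m, pair$locator)
  expect_identical(flat$version, "1.0")
  expect_length(flat$imports, 0)
  expect_length(flat$components, 2)
  expect_length(validate_cellml(flat), 0)
  expect_identical(classify_variables(flat)$counts,
                   classify_variables(parse_cellml(make_decay()))$counts)
})

test_that("a model without imports flattens to itself with version forced to 1.0", {
  m <- parse_cellml(make_decay())
  flat <- resolve_imports(m)
  expect_identical(flat$version, "1.0")
  expect_identical(strip_locations(flat), strip_locations(m))
})

test_that("flattened output re-flattened is byte-identical (idempotence)", {
  pair <- make_import_pair()
  m <- parse_cellml(pair$main, pair$main_base)
  once <- export_cellml10(m, pair$locator)
  expect_identical(detect_version(once), "1.0")
  twice <- export_cellml10(parse_cellml(once, "flat.cellml"))
  expect_identical(twice, once)
})

test_that("a self-importing document raises a cycle error listing the locator", {
  fx <- make_invalid_suite()[["circular-import"]]
  m <- parse_cellml(fx$text, fx$base)
  err <- expect_cellsim_error(resolve_imports(m, fx$locator), "circular-import")
  expect_match(conditionMessage(err), "loop.cellml")
})

test_that("an unresolvable href is a locator error naming the href", {
  pair <- make_import_pair()
  m <- parse_cellml(pair$main, pair$main_base)
  empty <- memory_locator(list())
  err <- expect_cellsim_error(resolve_imports(m, empty), "unresolvable-href")
  expect_match(conditionMessage(err), "parts.cellml")
})

test_that("an imported name missing from the target document is a reference error", {
  pair <- make_import_pair()
  bad_main <- sub('component_ref="rate_const"', 'component_ref="nope"',
                  pair$main, fixed = TRUE)
  m <- parse_cellml(bad_main, pair$main_base)
  loc <- memory_locator(list("parts.cellml" = pair$imported))
  expect_cellsim_error(resolve_imports(m, loc), "import-reference")
})

test_that("composite (1.1) and flattened (1.0) simulations agree to 1e-12", {
  pair <- make_import_pair()
  m <- parse_cellml(pair$main, pair$main_base)
  flat <- resolve_imports(m, pair$locator)
  reflat <- parse_cellml(export_cellml10(m, pair$locator), "flat.cellml")
  setup <- simulation_setup(0, 5, 0.1, ode_solver = "rk4")
  s1 <- run_simulation(build_runtime(flat), setup)
  s2 <- run_simulation(build_runtime(reflat), setup)
  expect_identical(ds_labels(s1), ds_labels(s2))
  expect_lt(max(abs(s1$data - s2$data)), 1e-12)
  # runtime classification census is preserved by flattening
  expect_identical(build_runtime(flat)$counts, build_runtime(reflat)$counts)
})

test_that("initial-value-by-variable-reference is rewritten to the literal", {
  txt <- sub('<variable name="a" units="per_second" initial_value="1"/>',
             '<variable name="a" units="per_second" initial_value="a0"/>\n    <variable name="a0" units="per_second" initial_value="2.5" public_interface="out"/>',
             make_decay(), fixed = TRUE)
  txt <- sub('cellml/1.0#', 'cellml/1.1#', txt)
  txt <- sub('cellml/1.0#', 'cellml/1.1#', txt) # both xmlns declarations
  m <- parse_cellml(txt)
  flat <- resolve_imports(m)
  expect_identical(flat$components$main$variables$a$initial_value, "2.5")
})

test_that("the filesystem locator refuses remote hrefs by default", {
  loc <- file_locator()
  expect_cellsim_error(loc$key("http://example.org/m.cellml", "base.cellml"),
                       "remote-refused")
})
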