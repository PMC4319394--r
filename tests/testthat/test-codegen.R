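# Source export: format descriptions and cross-language consistency.
# (python execution helpers live in helper-python.R)

test_that("emitted python reproduces the native runtime at 10 random points (both fixtures)", {
  set.seed(2026)
  for (nm in c("decay", "fhn")) {
    m <- parse_cellml(valid_fixture_texts()[[nm]])
    rt <- build_runtime(m)
    src <- export_source(m, "python")
    n_states <- rt$counts[["state"]]
    n_const <- rt$counts[["constant"]] + rt$counts[["computed_constant"]]
    points <- lapply(1:10, function(i) {
      list(voi = runif(1, 0, 10),
           states = runif(n_states, -2, 2),
           constants = runif(n_const, 0.1, 2))
    })
    got <- python_eval_points(src, points, n_states, n_const)
    for (i in seq_along(points)) {
      p <- points[[i]]
      ra <- rt$compute_rates(p$voi, p$states, p$constants)
      alg <- rt$compute_algebraic(p$voi, p$states, ra$rates, p$constants)
      expect_lt(max(abs(got[[i]] - c(ra$rates, alg))), 1e-12)
    }
  }
})

test_that("the emitted python reproduces compute_rates(0, [10], [1]) = [-10] for decay", {
  src <- export_source(parse_cellml(make_decay()), "python")
  # exactly one rate assignment statement
  expect_length(grep("^\\s*rates\\[0\\] =", strsplit(src, "\n")[[1]]), 1)
  out <- run_python_module(src, c(
    "import genmod as g",
    "r, alg = g.compute_rates(0.0, [10.0], [1.0])",
    "print('%.17g' % r[0])"))
  expect_identical(as.numeric(out), -10)
})

test_that("f77 output respects the 72-column limit and uses the ** power rendering", {
  src <- export_source(parse_cellml(make_fhn()), "f77")
  lines <- strsplit(src, "\n", fixed = TRUE)[[1]]
  expect_lte(max(nchar(lines)), 72)
  expect_true(any(grepl("**", lines, fixed = TRUE)))
})

test_that("all four shipped formats emit deterministic output with the category census header", {
  m <- parse_cellml(make_fhn())
  for (f in c("c", "f77", "matlab", "python")) {
    s1 <- export_source(m, f)
    s2 <- export_source(m, f)
    expect_identical(s1, s2, label = f)
    expect_match(s1, "2 state", ignore.case = TRUE)
    expect_match(s1, "1 computed constant", ignore.case = TRUE)
  }
})

test_that("a user format missing a needed operator rendering errors naming the operator", {
  # strip the power rendering from the shipped python format
  path <- system.file("formats", "python.fmt", package = "cellsim")
  crippled <- grep("^op\\.power", readLines(path), invert = TRUE, value = TRUE)
  tmp <- tempfile(fileext = ".fmt")
  writeLines(crippled, tmp)
  err <- expect_cellsim_error(
    export_source(parse_cellml(make_fhn()), tmp),  # FHN uses v^3
    "format-description")
  expect_match(conditionMessage(err), "power")
})

test_that("a user-supplied format file drives the emitted syntax", {
  fmt_lines <- c(
    "name = tiny", "comment = --", "assign = :=", "terminator = ;;",
    "index_base = 1", "block_style = matlab", "piecewise = call",
    "array.constants = K({i})", "array.states = S({i})",
    "array.rates = D({i})", "array.algebraic = G({i})", "scalar.voi = T",
    "op.plus = infix +", "op.minus = infix -", "op.times = infix *",
    "op.divide = infix /", "op.power = infix ^")
  tmp <- tempfile(fileext = ".fmt")
  writeLines(fmt_lines, tmp)
  src <- export_source(parse_cellml(make_decay()), tmp)
  expect_match(src, "D(1) := (-(K(1) * S(1)));;", fixed = TRUE)
})
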