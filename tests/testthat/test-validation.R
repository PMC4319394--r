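# Structural validation and dimensional (units) checking.

test_that("all valid fixtures validate with zero errors and zero warnings", {
  for (nm in c("decay", "fhn", "nla")) {
    m <- parse_cellml(valid_fixture_texts()[[nm]])
    expect_length(validate_cellml(m), 0)
  }
  pair <- make_import_pair()
  expect_length(validate_cellml(parse_cellml(pair$main, pair$main_base),
                                locator = pair$locator), 0)
  expect_length(validate_cellml(parse_cellml(pair$imported, "parts.cellml")), 0)
})

test_that("each invalid fixture yields exactly its constructed defect code at the right line", {
  suite <- make_invalid_suite()
  expect_length(suite, 8)
  for (nm in names(suite)) {
    fx <- suite[[nm]]
    m <- parse_cellml(fx$text, fx$base %||% "fixture.cellml")
    issues <- validate_cellml(m, locator = fx$locator)
    expect_length(issues, 1)
    expect_identical(issues[[1]]$code, fx$code, label = nm)
    expect_identical(issues[[1]]$location$line, as.integer(fx$line),
                     label = nm)
  }
})

test_that("a connection naming a nonexistent component is located at the connection", {
  fx <- make_invalid_suite()[["dangling-connection"]]
  m <- parse_cellml(fx$text)
  issues <- validate_structure(m)
  expect_gte(length(issues), 1)
  expect_identical(issues[[1]]$severity, "error")
  lines <- strsplit(fx$text, "\n", fixed = TRUE)[[1]]
  expect_match(lines[issues[[1]]$location$line], "<connection", fixed = TRUE)
})

test_that("dimensional rules: addition, mismatch, and prefix cancellation", {
  builtins <- cellsim:::builtin_units_table()
  ue <- function(name, loc = NULL) builtins[[name]]
  mk_ci <- function(nm) list(kind = "ci", name = nm, location = NULL)
  plus <- function(a, b) list(kind = "apply", op = "plus", args = list(a, b),
                              location = list(line = 1L, column = 1L))

  venv <- list(u = builtins$volt, v = builtins$volt, s = builtins$second)
  res <- dimension_of(plus(mk_ci("u"), mk_ci("v")), ue, venv)
  expect_length(res$issues, 0)
  expect_equal(unname(res$dim$d),
               unname(builtins$volt$d))  # m^2 kg s^-3 A^-1

  res2 <- dimension_of(plus(mk_ci("u"), mk_ci("s")), ue, venv)
  expect_null(res2$dim)
  expect_length(res2$issues, 1)
  expect_identical(res2$issues[[1]]$code, "mismatched-addition")
  expect_match(res2$issues[[1]]$message, "plus")

  # d(millivolt)/d(millisecond): the milli prefixes cancel
  milli <- function(base) {
    d <- builtins[[base]]; d$mult <- d$mult * 1e-3; d
  }
  venv2 <- list(vm = milli("volt"), tm = milli("second"))
  dexpr <- list(kind = "diff", var = "vm", bvar = "tm", location = NULL)
  res3 <- dimension_of(dexpr, ue, venv2)
  expect_equal(unname(res3$dim$d), unname(builtins$volt$d - builtins$second$d))
  expect_equal(res3$dim$mult, 1)
})

test_that("product dimensions equal elementwise exponent sums (random pairs vs oracle)", {
  builtins <- cellsim:::builtin_units_table()
  nm <- names(builtins)
  set.seed(42)
  for (rep in 1:25) {
    a <- sample(nm, 1); b <- sample(nm, 1)
    venv <- list(p = builtins[[a]], q = builtins[[b]])
    prod_expr <- list(kind = "apply", op = "times",
                      args = list(list(kind = "ci", name = "p"),
                                  list(kind = "ci", name = "q")),
                      location = NULL)
    res <- dimension_of(prod_expr, function(n, l) builtins[[n]], venv)
    # independent oracle: plain exponent-vector addition
    expect_equal(unname(res$dim$d),
                 unname(builtins[[a]]$d + builtins[[b]]$d),
                 label = paste(a, b))
    expect_equal(res$dim$mult, builtins[[a]]$mult * builtins[[b]]$mult)
  }
})

test_that("transcendental arguments and power exponents must be dimensionless", {
  builtins <- cellsim:::builtin_units_table()
  venv <- list(s = builtins$second, x = builtins$dimensionless)
  ue <- function(n, l = NULL) builtins[[n]]
  bad_exp <- list(kind = "apply", op = "exp",
                  args = list(list(kind = "ci", name = "s")), location = NULL)
  r <- dimension_of(bad_exp, ue, venv)
  expect_identical(r$issues[[1]]$code, "non-dimensionless-arg")
  bad_pow <- list(kind = "apply", op = "power",
                  args = list(list(kind = "ci", name = "x"),
                              list(kind = "ci", name = "s")), location = NULL)
  r2 <- dimension_of(bad_pow, ue, venv)
  expect_identical(r2$issues[[1]]$code, "bad-power-exponent")
})

test_that("issues are sorted by (line, column) and deterministic across runs", {
  # a model with two defects on different lines
  t2 <- sub('    <variable name="a" units="per_second" initial_value="1"/>',
            '    <variable name="a" units="bogus_units" initial_value="1"/>\n    <variable name="b" units="dimensionless"/>',
            make_decay(), fixed = TRUE)
  m <- parse_cellml(t2)
  i1 <- validate_cellml(m)
  i2 <- validate_cellml(m)
  expect_identical(i1, i2)
  lines <- vapply(i1, function(i) i$location$line, integer(1))
  expect_identical(lines, sort(lines))
  expect_setequal(issue_codes <- vapply(i1, `[[`, character(1), "code"),
                  c("dangling-units", "undefined-variable"))
})

test_that("units shadowing a built-in name is rejected", {
  txt <- sub('<units name="per_second">', '<units name="second">',
             make_decay(), fixed = TRUE)
  txt <- gsub('units="per_second"', 'units="second"', txt, fixed = TRUE)
  m <- parse_cellml(txt)
  codes <- vapply(validate_structure(m), `[[`, character(1), "code")
  expect_true("duplicate-units" %in% codes)
})
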