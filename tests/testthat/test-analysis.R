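# Variable classification, equation ordering, and runtime generation.

test_that("decay classifies to (1 VOI, 1 state, 1 rate, 1 constant, 0, 0)", {
  m <- parse_cellml(make_decay())
  cls <- classify_variables(m)
  expect_identical(unname(cls$counts[c("voi", "state", "rate", "constant",
                                       "computed_constant", "algebraic")]),
                   c(1L, 1L, 1L, 1L, 0L, 0L))
  expect_identical(unname(cls$category["main/time"]), "variable_of_integration")
  expect_identical(unname(cls$category["main/y"]), "state")
  expect_identical(unname(cls$category["main/a"]), "constant")
})

test_that("FHN classifies to (1, 2, 2, 4, 1, 1)", {
  cls <- classify_variables(parse_cellml(make_fhn()))
  expect_identical(unname(cls$counts[c("voi", "state", "rate", "constant",
                                       "computed_constant", "algebraic")]),
                   c(1L, 2L, 2L, 4L, 1L, 1L))
  expect_identical(unname(cls$category["main/eb"]), "computed_constant")
  expect_identical(unname(cls$category["main/u"]), "algebraic")
})

test_that("classification agrees with the brute-force dependency-closure oracle", {
  for (nm in c("decay", "fhn", "nla")) {
    m <- parse_cellml(valid_fixture_texts()[[nm]])
    cls <- classify_variables(m)
    oracle <- oracle_classify(m)
    expect_identical(cls$category[sort(names(cls$category))],
                     oracle[sort(names(oracle))], label = nm)
  }
})

test_that("every resolved variable gets exactly one category, stably across runs", {
  m <- parse_cellml(make_fhn())
  c1 <- classify_variables(m)
  c2 <- classify_variables(m)
  expect_identical(c1$category, c2$category)
  expect_false(anyNA(c1$category))
  expect_identical(sum(c1$counts[c("voi", "state", "constant",
                                   "computed_constant", "algebraic")]),
                   length(c1$category))
})

test_that("two distinct bound variables is a multiple-VOI error", {
  bad <- sub("</math>",
             paste0("      <apply><eq/>\n",
                    "        <apply><diff/><bvar><ci>y</ci></bvar><ci>a</ci></apply>\n",
                    "        <cn cellml:units=\"dimensionless\">1</cn>\n",
                    "      </apply>\n    </math>"),
             make_decay(), fixed = TRUE)
  expect_cellsim_error(classify_variables(parse_cellml(bad)), "multiple-voi")
})

test_that("a purely algebraic model (no derivative) is a no-VOI error", {
  txt <-
'<?xml version="1.0" encoding="UTF-8"?>
<model name="alg" xmlns="http://www.cellml.org/cellml/1.0#" xmlns:cellml="http://www.cellml.org/cellml/1.0#">
  <component name="main">
    <variable name="x" units="dimensionless"/>
    <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><eq/><ci>x</ci><cn cellml:units="dimensionless">1</cn></apply>
    </math>
  </component>
</model>
'
  expect_cellsim_error(classify_variables(parse_cellml(txt)), "no-voi")
})

test_that("a state without an initial value is a missing-initial-condition error", {
  bad <- sub(' initial_value="10"', '', make_decay(), fixed = TRUE)
  expect_cellsim_error(classify_variables(parse_cellml(bad)),
                       "missing-initial-condition")
})

test_that("equation plans: decay is one rate step; the NLA fixture has one 2x2 block", {
  plan_d <- order_equations(parse_cellml(make_decay()))
  kinds <- vapply(plan_d$steps, `[[`, character(1), "kind")
  expect_identical(kinds, "assign")
  expect_identical(plan_d$steps[[1]]$phase, "rates")

  plan_n <- order_equations(parse_cellml(make_nla()))
  kinds_n <- vapply(plan_n$steps, `[[`, character(1), "kind")
  expect_identical(sum(kinds_n == "nla"), 1L)
  blk <- plan_n$steps[[which(kinds_n == "nla")]]
  expect_length(blk$equations, 2)
  expect_length(blk$unknowns, 2)
  # the block precedes the rate step that consumes its unknowns
  expect_lt(which(kinds_n == "nla"), which(kinds_n == "assign"))
})

test_that("two equations targeting the same variable is a redefinition error", {
  bad <- sub("</math>",
             paste0("      <apply><eq/>\n",
                    "        <apply><diff/><bvar><ci>time</ci></bvar><ci>y</ci></apply>\n",
                    "        <cn cellml:units=\"per_second\">1</cn>\n",
                    "      </apply>\n    </math>"),
             make_decay(), fixed = TRUE)
  expect_cellsim_error(order_equations(parse_cellml(bad)), "redefinition")
})

test_that("an unbalanced implicit system is a structural singularity", {
  txt <- sub(paste0("      <apply><eq/>\n",
                    "        <apply><minus/><ci>x</ci><ci>y</ci></apply>\n",
                    "        <cn cellml:units=\"dimensionless\">1</cn>\n",
                    "      </apply>\n"), "", make_nla(), fixed = TRUE)
  expect_cellsim_error(order_equations(parse_cellml(txt)),
                       "structural-singularity")
})

test_that("the decay runtime reproduces its defining numbers", {
  rt <- decay_runtime()
  init <- rt$initialise()
  expect_identical(init$states, 10)
  expect_identical(init$constants, 1)
  cc <- rt$compute_computed_constants(init$constants)
  ra <- rt$compute_rates(0, init$states, cc)
  expect_identical(ra$rates, -10)
})

test_that("the FHN runtime matches hand-evaluated expressions to 1e-15", {
  rt <- build_runtime(parse_cellml(make_fhn()))
  init <- rt$initialise()
  cc <- rt$compute_computed_constants(init$constants)
  # independent hand evaluation of the fixture's expressions
  v <- -1; w <- 1; a <- 0.7; b <- 0.8; eps <- 0.08; I <- 0.5
  eb <- eps * b
  dv <- v - v^3 / 3 - w + I
  dw <- eps * v + eps * a - eb * w
  u <- v - w
  lbl <- rt$meta$label
  expect_equal(cc[rt$meta$index[match("main/eb", lbl)]], eb, tolerance = 1e-15)
  ra <- rt$compute_rates(0, init$states, cc)
  expect_equal(ra$rates[rt$meta$index[match("main/v'", lbl)]], dv,
               tolerance = 1e-15)
  expect_equal(ra$rates[rt$meta$index[match("main/w'", lbl)]], dw,
               tolerance = 1e-15)
  alg <- rt$compute_algebraic(0, init$states, ra$rates, cc)
  expect_equal(alg[rt$meta$index[match("main/u", lbl)]], u, tolerance = 1e-15)
})

test_that("the NLA runtime solves its block to (x, y) = (2, 1)", {
  rt <- build_runtime(parse_cellml(make_nla()))
  init <- rt$initialise()
  cc <- rt$compute_computed_constants(init$constants)
  nla <- rt$new_nla_env()
  ra <- rt$compute_rates(0, init$states, cc, nla)
  lbl <- rt$meta$label
  x <- ra$algebraic[rt$meta$index[match("main/x", lbl)]]
  y <- ra$algebraic[rt$meta$index[match("main/y", lbl)]]
  expect_equal(x, 2, tolerance = 1e-10)
  expect_equal(y, 1, tolerance = 1e-10)
  expect_lt(max(abs(c(x + y - 3, x - y - 1))), 1e-10)
  expect_identical(ra$rates, x)  # dz/dt = x
})

test_that("evaluators are pure: repeated calls give bitwise-identical output and never mutate inputs", {
  rt <- build_runtime(parse_cellml(make_fhn()))
  init <- rt$initialise()
  cc <- rt$compute_computed_constants(init$constants)
  states <- init$states
  before <- states
  r1 <- rt$compute_rates(0.3, states, cc)
  r2 <- rt$compute_rates(0.3, states, cc)
  expect_identical(r1, r2)
  expect_identical(states, before)
})
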