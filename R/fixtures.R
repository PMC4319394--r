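# Programmatic test-model generators.
#
# All test inputs are built here, in code, so the package tests end-to-end
# with no downloads: an exponential-decay model (the minimal ODE), a
# FitzHugh-Nagumo model populating all six variable categories, a model
# with a nonlinear-algebraic loop, a CellML 1.1 import pair, and an
# invalid-model suite with one known defect per file. Generators are
# deterministic: identical parameters give byte-identical text.

#' Exponential-decay fixture (CellML 1.0)
#'
#' One component; equation `dy/dt = -a*y` with consistent units
#' (`per_second` against a dimensionless state); category census
#' (1 VOI, 1 state, 1 rate, 1 constant, 0, 0). Closed form:
#' `y(t) = y0 * exp(-a t)`.
#'
#' @param a decay rate (1/s).
#' @param y0 initial value (dimensionless).
#' @return CellML text.
#' @export
make_decay <- function(a = 1, y0 = 10) {
  paste0(
'<?xml version="1.0" encoding="UTF-8"?>
<model name="decay" xmlns="http://www.cellml.org/cellml/1.0#" xmlns:cellml="http://www.cellml.org/cellml/1.0#" xmlns:cmeta="http://www.cellml.org/metadata/1.0#">
  <units name="per_second">
    <unit units="second" exponent="-1"/>
  </units>
  <component name="main" cmeta:id="main">
    <variable name="time" units="second"/>
    <variable name="y" units="dimensionless" initial_value="', fmt_num(y0), '" cmeta:id="y"/>
    <variable name="a" units="per_second" initial_value="', fmt_num(a), '"/>
    <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>y</ci></apply>
        <apply><minus/>
          <apply><times/><ci>a</ci><ci>y</ci></apply>
        </apply>
      </apply>
    </math>
  </component>
</model>
')
}

#' FitzHugh-Nagumo fixture (CellML 1.0)
#'
#' Two-state excitable model chosen to populate all six categories:
#' `v\' = v - v^3/3 - w + I_stim`, `w\' = eps*v + eps*a - eb*w` with the
#' computed constant `eb = eps*b` and the algebraic variable `u = v - w`.
#' Census (1 VOI, 2 states, 2 rates, 4 constants, 1 computed constant,
#' 1 algebraic). Conventional coefficients `eps = 0.08`, `a = 0.7`,
#' `b = 0.8`, `I_stim = 0.5`; initial `v = -1`, `w = 1`.
#'
#' @return CellML text.
#' @export
make_fhn <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<model name="fhn" xmlns="http://www.cellml.org/cellml/1.0#" xmlns:cellml="http://www.cellml.org/cellml/1.0#" xmlns:cmeta="http://www.cellml.org/metadata/1.0#">
  <component name="main">
    <variable name="time" units="dimensionless"/>
    <variable name="v" units="dimensionless" initial_value="-1"/>
    <variable name="w" units="dimensionless" initial_value="1"/>
    <variable name="a" units="dimensionless" initial_value="0.7"/>
    <variable name="b" units="dimensionless" initial_value="0.8"/>
    <variable name="eps" units="dimensionless" initial_value="0.08"/>
    <variable name="I_stim" units="dimensionless" initial_value="0.5"/>
    <variable name="eb" units="dimensionless"/>
    <variable name="u" units="dimensionless"/>
    <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><eq/>
        <ci>eb</ci>
        <apply><times/><ci>eps</ci><ci>b</ci></apply>
      </apply>
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>v</ci></apply>
        <apply><plus/>
          <apply><minus/>
            <apply><minus/>
              <ci>v</ci>
              <apply><divide/>
                <apply><power/><ci>v</ci><cn cellml:units="dimensionless">3</cn></apply>
                <cn cellml:units="dimensionless">3</cn>
              </apply>
            </apply>
            <ci>w</ci>
          </apply>
          <ci>I_stim</ci>
        </apply>
      </apply>
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>w</ci></apply>
        <apply><minus/>
          <apply><plus/>
            <apply><times/><ci>eps</ci><ci>v</ci></apply>
            <apply><times/><ci>eps</ci><ci>a</ci></apply>
          </apply>
          <apply><times/><ci>eb</ci><ci>w</ci></apply>
        </apply>
      </apply>
      <apply><eq/>
        <ci>u</ci>
        <apply><minus/><ci>v</ci><ci>w</ci></apply>
      </apply>
    </math>
  </component>
</model>
'
}

#' Nonlinear-algebraic loop fixture (CellML 1.0)
#'
#' Equations `x + y = 3` and `x - y = 1` (not in assignment form) feeding
#' `dz/dt = x`; the plan contains exactly one NLA block whose solution is
#' `x = 2`, `y = 1`, so `z(t) = z0 + 2 t` with `z0 = 1`.
#'
#' @return CellML text.
#' @export
make_nla <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<model name="nla_loop" xmlns="http://www.cellml.org/cellml/1.0#" xmlns:cellml="http://www.cellml.org/cellml/1.0#" xmlns:cmeta="http://www.cellml.org/metadata/1.0#">
  <component name="main">
    <variable name="time" units="dimensionless"/>
    <variable name="x" units="dimensionless"/>
    <variable name="y" units="dimensionless"/>
    <variable name="z" units="dimensionless" initial_value="1"/>
    <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><eq/>
        <apply><plus/><ci>x</ci><ci>y</ci></apply>
        <cn cellml:units="dimensionless">3</cn>
      </apply>
      <apply><eq/>
        <apply><minus/><ci>x</ci><ci>y</ci></apply>
        <cn cellml:units="dimensionless">1</cn>
      </apply>
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>z</ci></apply>
        <ci>x</ci>
      </apply>
    </math>
  </component>
</model>
'
}

#' CellML 1.1 import pair
#'
#' The main document imports a units definition and a component from the
#' second document and connects its own component to the imported one; the
#' flattened result is equivalent to [make_decay()] (same category census,
#' matching simulation).
#'
#' @param a,y0 decay parameters, as in [make_decay()].
#' @return list with `main` (CellML 1.1 text), `imported` (text), `locator`
#'   (a [memory_locator()] resolving the pair), and `main_base` (the main
#'   document's locator string).
#' @export
make_import_pair <- function(a = 1, y0 = 10) {
  imported <- paste0(
'<?xml version="1.0" encoding="UTF-8"?>
<model name="decay_parts" xmlns="http://www.cellml.org/cellml/1.1#" xmlns:cellml="http://www.cellml.org/cellml/1.1#" xmlns:cmeta="http://www.cellml.org/metadata/1.0#">
  <units name="per_second">
    <unit units="second" exponent="-1"/>
  </units>
  <component name="rate_const">
    <variable name="a_out" units="per_second" initial_value="', fmt_num(a), '" public_interface="out"/>
  </component>
</model>
')
  main <- paste0(
'<?xml version="1.0" encoding="UTF-8"?>
<model name="decay_import" xmlns="http://www.cellml.org/cellml/1.1#" xmlns:cellml="http://www.cellml.org/cellml/1.1#" xmlns:cmeta="http://www.cellml.org/metadata/1.0#" xmlns:xlink="http://www.w3.org/1999/xlink">
  <import xlink:href="parts.cellml">
    <units name="per_second" units_ref="per_second"/>
    <component name="rate_const" component_ref="rate_const"/>
  </import>
  <component name="main">
    <variable name="time" units="second"/>
    <variable name="y" units="dimensionless" initial_value="', fmt_num(y0), '"/>
    <variable name="a" units="per_second" public_interface="in"/>
    <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>y</ci></apply>
        <apply><minus/>
          <apply><times/><ci>a</ci><ci>y</ci></apply>
        </apply>
      </apply>
    </math>
  </component>
  <connection>
    <map_components component_1="main" component_2="rate_const"/>
    <map_variables variable_1="a" variable_2="a_out"/>
  </connection>
</model>
')
  list(main = main, imported = imported,
       locator = memory_locator(list("parts.cellml" = imported,
                                     "main.cellml" = main)),
       main_base = "main.cellml")
}

line_of <- function(text, pattern) {
  which(grepl(pattern, strsplit(text, "\n", fixed = TRUE)[[1]],
              fixed = TRUE))[1]
}

#' Invalid-model suite
#'
#' One file per defect code; each yields exactly its constructed code under
#' [validate_cellml()] and nothing else. The returned entries carry the
#' defect `code`, the expected `line`, the `base` locator string, and
#' (where import resolution is involved) a `locator`.
#'
#' @return named list (names = defect codes) of
#'   `list(text, code, line, base, locator)`.
#' @export
make_invalid_suite <- function() {
  suite <- list()

  t1 <- sub(
    '        <apply><minus/>\n          <apply><times/><ci>a</ci><ci>y</ci></apply>\n        </apply>',
    '        <apply><plus/>\n          <apply><minus/>\n            <apply><times/><ci>a</ci><ci>y</ci></apply>\n          </apply>\n          <ci>b</ci>\n        </apply>',
    make_decay(), fixed = TRUE)
  t1 <- sub('    <variable name="a" units="per_second" initial_value="1"/>',
            '    <variable name="a" units="per_second" initial_value="1"/>\n    <variable name="b" units="dimensionless"/>',
            t1, fixed = TRUE)
  suite[["undefined-variable"]] <- list(
    text = t1, code = "undefined-variable",
    line = line_of(t1, '<variable name="b"'))

  t2 <-
'<?xml version="1.0" encoding="UTF-8"?>
<model name="dup" xmlns="http://www.cellml.org/cellml/1.0#" xmlns:cellml="http://www.cellml.org/cellml/1.0#">
  <component name="main">
    <variable name="c" units="dimensionless" initial_value="1"/>
  </component>
  <component name="main">
    <variable name="d" units="dimensionless" initial_value="2"/>
  </component>
</model>
'
  suite[["duplicate-component"]] <- list(
    text = t2, code = "duplicate-component",
    line = which(grepl('<component name="main">',
                       strsplit(t2, "\n", fixed = TRUE)[[1]], fixed = TRUE))[2])

  t3 <- sub(
    '        <apply><minus/>\n          <apply><times/><ci>a</ci><ci>y</ci></apply>\n        </apply>',
    '        <apply><plus/>\n          <apply><minus/>\n            <apply><times/><ci>a</ci><ci>y</ci></apply>\n          </apply>\n          <ci>time</ci>\n        </apply>',
    make_decay(), fixed = TRUE)
  suite[["mismatched-addition"]] <- list(
    text = t3, code = "mismatched-addition",
    line = line_of(t3, "<apply><plus/>"))

  t4 <- sub('</model>',
'  <connection>
    <map_components component_1="main" component_2="ghost"/>
    <map_variables variable_1="y" variable_2="yy"/>
  </connection>
</model>', make_decay(), fixed = TRUE)
  suite[["dangling-connection"]] <- list(
    text = t4, code = "dangling-connection",
    line = line_of(t4, "<connection>"))

  t5 <-
'<?xml version="1.0" encoding="UTF-8"?>
<model name="circular" xmlns="http://www.cellml.org/cellml/1.0#" xmlns:cellml="http://www.cellml.org/cellml/1.0#">
  <units name="alpha">
    <unit units="beta"/>
  </units>
  <units name="beta">
    <unit units="alpha"/>
  </units>
  <component name="main">
    <variable name="q" units="alpha" initial_value="1"/>
  </component>
</model>
'
  suite[["circular-units"]] <- list(
    text = t5, code = "circular-units",
    line = line_of(t5, '<units name="alpha">'))

  t6 <-
'<?xml version="1.0" encoding="UTF-8"?>
<model name="loop" xmlns="http://www.cellml.org/cellml/1.1#" xmlns:cellml="http://www.cellml.org/cellml/1.1#" xmlns:xlink="http://www.w3.org/1999/xlink">
  <import xlink:href="loop.cellml">
    <units name="ps" units_ref="per_second"/>
  </import>
</model>
'
  suite[["circular-import"]] <- list(
    text = t6, code = "circular-import",
    line = line_of(t6, "<import "),
    base = "loop.cellml",
    locator = memory_locator(list("loop.cellml" = t6)))

  rdf_block <-
'  <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
    <rdf:Description>
      <bqbiol:isVersionOf rdf:resource="http://identifiers.org/chebi/CHEBI:29108"/>
    </rdf:Description>
  </rdf:RDF>'
  t7 <- sub('</model>', paste0(rdf_block, '\n</model>'), make_decay(),
            fixed = TRUE)
  suite[["corrupted-rdf"]] <- list(
    text = t7, code = "corrupted-rdf",
    line = line_of(t7, "<rdf:RDF"))

  t8 <- sub(
    '          <apply><times/><ci>a</ci><ci>y</ci></apply>',
    '          <apply><times/><ci>a</ci><ci>y</ci><cn>1</cn></apply>',
    make_decay(), fixed = TRUE)
  suite[["cn-without-units"]] <- list(
    text = t8, code = "cn-without-units",
    line = line_of(t8, "<cn>1</cn>"))

  suite
}

#' Materialize the fixture suite on disk
#'
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "invalid"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- character(0)
  put <- function(rel, text) {
    p <- file.path(dir, rel)
    write_atomically(p, text)
    paths <<- c(paths, p)
  }
  put("decay.cellml", make_decay())
  put("fhn.cellml", make_fhn())
  put("nla_loop.cellml", make_nla())
  pair <- make_import_pair()
  put("main.cellml", pair$main)
  put("parts.cellml", pair$imported)
  for (nm in names(make_invalid_suite())) {
    put(file.path("invalid", paste0(nm, ".cellml")),
        make_invalid_suite()[[nm]]$text)
  }
  invisible(paths)
}
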