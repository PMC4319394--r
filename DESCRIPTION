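Package: cellsim
Title: Scriptable Simulation Environment for CellML Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parse, validate, annotate, flatten, and simulate models of
    ordinary-differential and differential-algebraic equation systems
    encoded in CellML 1.0/1.1. Provides structural and dimensional
    (units) validation with line/column diagnostics, resolution of
    CellML 1.1 imports into standalone CellML 1.0 documents, variable
    classification into the six simulation categories (variable of
    integration, constant, computed constant, state, rate, algebraic),
    native runtime generation with support for nonlinear-algebraic
    equation blocks, fixed-step and adaptive ODE integration, source
    export to user-definable target languages (C, FORTRAN 77, MATLAB
    and Python formats ship with the package), element-level semantic
    annotation with biomodels.net qualifiers and identifiers.org URIs,
    a plugin registry, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
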