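# Test helpers: independent oracles and small crafted models.

# Brute-force variable classifier: enumerates dependency closures directly
# from the equation set (independent of the union-find/fixpoint path in
# classify_variables). Returns a named character vector over canonical
# "component/name" keys.
oracle_classify <- function(model) {
  # merge connected variables by repeated sweeps over the pairs
  key <- function(c, v) paste0(c, "/", v)
  rep_of <- list()
  for (comp in model$components) {
    for (v in comp$variables) rep_of[[key(comp$name, v$name)]] <- key(comp$name, v$name)
  }
  find <- function(k) {
    while (!identical(rep_of[[k]], k)) k <- rep_of[[k]]
    k
  }
  for (pass in 1:10) {
    for (cn in model$connections) {
      for (p in cn$variable_pairs) {
        a <- find(key(cn$component_1, p[[1]]))
        b <- find(key(cn$component_2, p[[2]]))
        if (!identical(a, b)) rep_of[[max(a, b)]] <- min(a, b)
      }
    }
  }
  keys <- unique(vapply(names(rep_of), find, character(1)))

  inits <- character(0)
  for (comp in model$components) {
    for (v in comp$variables) {
      if (!is.na(v$initial_value)) inits <- c(inits, find(key(comp$name, v$name)))
    }
  }

  # equations: targets, diffed states, bvars, and raw reference sets
  targets <- character(0); states <- character(0); bvars <- character(0)
  dep_edges <- list()
  implicit_refs <- character(0)
  for (comp in model$components) {
    for (eq in comp$equations) {
      refs <- unique(c(
        vapply(cellsim:::math_ci_names(eq), function(nm) find(key(comp$name, nm)), character(1)),
        vapply(cellsim:::math_diff_refs(eq), function(d) find(key(comp$name, d$var)), character(1))
      ))
      for (d in cellsim:::math_diff_refs(eq)) bvars <- c(bvars, find(key(comp$name, d$bvar)))
      tgt <- cellsim:::equation_target(eq)
      if (is.null(tgt)) {
        implicit_refs <- c(implicit_refs, refs)
        next
      }
      tk <- find(key(comp$name, tgt$name))
      if (identical(tgt$type, "rate")) {
        states <- c(states, tk)
      } else {
        targets <- c(targets, tk)
        dep_edges[[tk]] <- setdiff(refs, tk)
      }
    }
  }
  voi <- unique(bvars)
  stopifnot(length(voi) == 1)
  states <- unique(states)
  constants <- setdiff(intersect(inits, keys), c(targets, states, voi))

  # full transitive closure per target, by saturation
  closure <- dep_edges
  repeat {
    changed <- FALSE
    for (k in names(closure)) {
      ext <- unique(unlist(c(closure[[k]],
                             lapply(intersect(closure[[k]], names(closure)),
                                    function(d) closure[[d]]))))
      if (length(ext) > length(closure[[k]])) {
        closure[[k]] <- ext
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  out <- stats::setNames(rep(NA_character_, length(keys)), keys)
  out[voi] <- "variable_of_integration"
  out[states] <- "state"
  out[constants] <- "constant"
  nla_unknowns <- setdiff(unique(implicit_refs),
                          c(targets, states, constants, voi))
  for (k in targets) {
    cl <- closure[[k]]
    bad <- c(voi, states, nla_unknowns,
             setdiff(cl, c(constants, targets)))
    out[k] <- if (length(intersect(cl, bad)) == 0 &&
                  all(vapply(intersect(cl, targets), function(d) {
                    length(intersect(closure[[d]],
                                     c(voi, states, nla_unknowns))) == 0
                  }, logical(1)))) "computed_constant" else "algebraic"
  }
  out[is.na(out)] <- "algebraic"
  out
}

oracle_counts <- function(model) {
  cats <- oracle_classify(model)
  c(voi = sum(cats == "variable_of_integration"),
    state = sum(cats == "state"),
    rate = sum(cats == "state"),
    constant = sum(cats == "constant"),
    computed_constant = sum(cats == "computed_constant"),
    algebraic = sum(cats == "algebraic"))
}

# Two-state conservation probe: y1' = -k y1, y2' = +k y1 (the sum y1+y2 is
# invariant).
make_conservation_model <- function(k = 0.3, y1 = 5, y2 = 1) {
  paste0(
'<?xml version="1.0" encoding="UTF-8"?>
<model name="conserve" xmlns="http://www.cellml.org/cellml/1.0#" xmlns:cellml="http://www.cellml.org/cellml/1.0#">
  <component name="main">
    <variable name="time" units="dimensionless"/>
    <variable name="y1" units="dimensionless" initial_value="', format(y1), '"/>
    <variable name="y2" units="dimensionless" initial_value="', format(y2), '"/>
    <variable name="k" units="dimensionless" initial_value="0.3"/>
    <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>y1</ci></apply>
        <apply><minus/><apply><times/><ci>k</ci><ci>y1</ci></apply></apply>
      </apply>
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>y2</ci></apply>
        <apply><times/><ci>k</ci><ci>y1</ci></apply>
      </apply>
    </math>
  </component>
</model>
')
}

valid_fixture_texts <- function() {
  pair <- make_import_pair()
  list(decay = make_decay(), fhn = make_fhn(), nla = make_nla(),
       import_main = pair$main, import_parts = pair$imported)
}

decay_runtime <- function() build_runtime(parse_cellml(make_decay()))

expect_cellsim_error <- function(expr, code) {
  err <- tryCatch({ expr; NULL }, cellsim_error = function(e) e)
  expect_false(is.null(err), label = sprintf("expected a '%s' error", code))
  expect_identical(err$code, code)
  invisible(err)
}
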