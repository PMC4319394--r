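# Structural and dimensional validation with line/column diagnostics.
#
# Structural faults are errors; dimensional inconsistencies are warnings so
# that repository-grade models with imperfect units can still simulate.
# Issues are returned sorted by (line, column) and are deterministic.

#' Structural validation of a CellML model
#'
#' Checks: duplicate component / variable / units names, dangling units
#' references, connections naming missing components or variables, interface
#' direction mismatches (an `out` side must map to an `in` side), a variable
#' that both has an initial value and is computed by an equation, a
#' non-state variable that is never defined, and `ci` references to
#' undeclared variables. Mathematics problems recorded at parse time
#' (unsupported operators, numbers without units) are surfaced here too.
#'
#' @param model a `cellml_model`.
#' @return list of issues (empty when structurally valid), sorted by
#'   location.
#' @export
validate_structure <- function(model) {
  issues <- list()
  push <- function(severity, code, msg, loc) {
    issues[[length(issues) + 1]] <<- new_issue(severity, code, msg, loc)
  }
  for (mi in model$math_issues) issues <- c(issues, list(mi))

  comp_names <- vapply(model$components, `[[`, character(1), "name")
  dup <- duplicated(comp_names)
  for (i in which(dup)) {
    push("error", "duplicate-component",
         sprintf("component name '%s' is declared more than once", comp_names[i]),
         model$components[[i]]$location)
  }

  units_names <- vapply(model$units, `[[`, character(1), "name")
  for (i in which(duplicated(units_names))) {
    push("error", "duplicate-units",
         sprintf("units name '%s' is defined more than once", units_names[i]),
         model$units[[i]]$location)
  }
  builtin <- names(builtin_units_table())
  for (i in which(units_names %in% builtin)) {
    push("error", "duplicate-units",
         sprintf("units definition '%s' shadows a built-in unit", units_names[i]),
         model$units[[i]]$location)
  }

  imported_units <- unlist(lapply(model$imports, function(im)
    vapply(im$units, `[[`, character(1), "name")))
  imported_comps <- unlist(lapply(model$imports, function(im)
    vapply(im$components, `[[`, character(1), "name")))
  known_units <- c(builtin, units_names, imported_units)
  known_comps <- c(comp_names, imported_comps)

  # Variables with an incoming value through a connection.
  has_incoming <- character(0)
  for (cn in model$connections) {
    c1 <- cn$component_1; c2 <- cn$component_2
    missing_comp <- FALSE
    for (cc in c(c1, c2)) {
      if (!cc %in% known_comps) {
        push("error", "dangling-connection",
             sprintf("connection references unknown component '%s'", cc),
             cn$location)
        missing_comp <- TRUE
      }
    }
    if (missing_comp) next
    comp1 <- model$components[[c1]]; comp2 <- model$components[[c2]]
    for (p in cn$variable_pairs) {
      v1 <- if (!is.null(comp1)) comp1$variables[[p[[1]]]] else NULL
      v2 <- if (!is.null(comp2)) comp2$variables[[p[[2]]]] else NULL
      if (!is.null(comp1) && is.null(v1)) {
        push("error", "dangling-connection",
             sprintf("connection references unknown variable '%s' in component '%s'",
                     p[[1]], c1), cn$location)
        next
      }
      if (!is.null(comp2) && is.null(v2)) {
        push("error", "dangling-connection",
             sprintf("connection references unknown variable '%s' in component '%s'",
                     p[[2]], c2), cn$location)
        next
      }
      if (is.null(v1) || is.null(v2)) next # imported side: checked post-flattening
      i1 <- v1$public_interface; i2 <- v2$public_interface
      ok <- (identical(i1, "out") && identical(i2, "in")) ||
        (identical(i1, "in") && identical(i2, "out"))
      if (!ok) {
        push("error", "interface-mismatch",
             sprintf("mapped pair %s/%s (%s) and %s/%s (%s) must link an 'out' to an 'in' interface",
                     c1, p[[1]], i1, c2, p[[2]], i2), cn$location)
      } else {
        sink_side <- if (identical(i1, "in")) paste0(c1, "/", p[[1]]) else paste0(c2, "/", p[[2]])
        has_incoming <- c(has_incoming, sink_side)
      }
    }
  }

  # Per-component checks.
  for (comp in model$components) {
    var_names <- vapply(comp$variables, `[[`, character(1), "name")
    for (i in which(duplicated(var_names))) {
      push("error", "duplicate-variable",
           sprintf("variable '%s' declared twice in component '%s'",
                   var_names[i], comp$name), comp$variables[[i]]$location)
    }
    for (v in comp$variables) {
      if (!v$units %in% known_units) {
        push("error", "dangling-units",
             sprintf("variable '%s' uses unresolvable units '%s'",
                     v$name, v$units), v$location)
      }
    }
    targets <- character(0)     # variables assigned by an equation
    constrained <- character(0) # variables appearing in non-assignment equations
    diffed <- character(0)
    for (eq in comp$equations) {
      for (u in math_cn_units(eq)) {
        if (!u %in% known_units) {
          push("error", "dangling-units",
               sprintf("number uses unresolvable units '%s'", u), eq$location)
        }
      }
      for (nm in c(math_ci_names(eq),
                   unlist(lapply(math_diff_refs(eq), unlist)))) {
        if (!nm %in% var_names) {
          push("error", "undeclared-variable",
               sprintf("'%s' is not declared in component '%s'", nm, comp$name),
               eq$location)
        }
      }
      tgt <- equation_target(eq)
      if (!is.null(tgt)) {
        if (identical(tgt$type, "var")) targets <- c(targets, tgt$name)
        if (identical(tgt$type, "rate")) diffed <- c(diffed, tgt$name)
      } else {
        constrained <- c(constrained, math_ci_names(eq))
      }
    }
    for (v in comp$variables) {
      has_init <- !is.na(v$initial_value)
      if (has_init && v$name %in% targets) {
        push("error", "overdefined-variable",
             sprintf("variable '%s' has an initial value and is also computed by an equation",
                     v$name), v$location)
      }
      defined <- has_init || v$name %in% targets || v$name %in% diffed ||
        v$name %in% constrained ||
        paste0(comp$name, "/", v$name) %in% has_incoming ||
        is_bvar_somewhere(comp, v$name) ||
        identical(v$public_interface, "in") && length(model$imports) > 0
      if (!defined) {
        push("error", "undefined-variable",
             sprintf("variable '%s' in component '%s' is never defined (no initial value, no equation, no incoming connection)",
                     v$name, comp$name), v$location)
      }
    }
  }
  sort_issues(issues)
}

# Assignment-form target of an equation: a bare ci or a bare derivative on
# one side. Prefers the left side.
equation_target <- function(eq) {
  side <- function(s) {
    if (identical(s$kind, "ci")) return(list(type = "var", name = s$name))
    if (identical(s$kind, "diff")) {
      return(list(type = "rate", name = s$var, bvar = s$bvar))
    }
    NULL
  }
  side(eq$lhs) %||% side(eq$rhs)
}

is_bvar_somewhere <- function(comp, name) {
  for (eq in comp$equations) {
    for (d in math_diff_refs(eq)) if (identical(d$bvar, name)) return(TRUE)
  }
  FALSE
}

#' Units (dimensional) checking of a CellML model
#'
#' Expands user units definitions over the SI base dimensions (reporting
#' circular definitions as errors), then applies [dimension_of()] to every
#' equation and compares connected variable pairs. Dimensional
#' inconsistencies and dimension-preserving scale mismatches are warnings
#' with distinct codes.
#'
#' @param model a `cellml_model` that passed [validate_structure()] with no
#'   errors.
#' @return list of issues sorted by location.
#' @export
check_units <- function(model) {
  exp <- expand_model_units(model)
  issues <- list()

  for (comp in model$components) {
    var_env <- lapply(comp$variables, function(v) exp$resolve(v$units, v$location))
    names(var_env) <- vapply(comp$variables, `[[`, character(1), "name")
    for (eq in comp$equations) {
      res <- dimension_of(eq, exp$resolve, var_env)
      issues <- c(issues, res$issues)
    }
  }

  for (cn in model$connections) {
    comp1 <- model$components[[cn$component_1]]
    comp2 <- model$components[[cn$component_2]]
    if (is.null(comp1) || is.null(comp2)) next
    for (p in cn$variable_pairs) {
      v1 <- comp1$variables[[p[[1]]]]; v2 <- comp2$variables[[p[[2]]]]
      if (is.null(v1) || is.null(v2)) next
      d1 <- exp$resolve(v1$units, cn$location)
      d2 <- exp$resolve(v2$units, cn$location)
      if (is.null(d1) || is.null(d2)) next
      if (!dim_equal(d1, d2)) {
        issues <- c(issues, list(new_issue(
          "warning", "connection-units",
          sprintf("connected pair %s/%s (%s) and %s/%s (%s) are dimensionally incompatible",
                  cn$component_1, p[[1]], format_dim(d1),
                  cn$component_2, p[[2]], format_dim(d2)), cn$location)))
      } else if (!dim_mult_equal(d1, d2)) {
        issues <- c(issues, list(new_issue(
          "warning", "scale-mismatch",
          sprintf("connected pair %s/%s and %s/%s share a dimension but differ in scale; values pass through unscaled",
                  cn$component_1, p[[1]], cn$component_2, p[[2]]), cn$location)))
      }
    }
  }
  sort_issues(c(exp$get_issues(), issues))
}

#' Full validation report
#'
#' Concatenates [validate_structure()] and -- when the structure is clean --
#' [check_units()]. When the model embeds an RDF block that cannot be read,
#' a `corrupted-rdf` error is included (the model remains usable for
#' simulation). When a locator is supplied and the model has imports, import
#' resolution problems (unresolvable hrefs, circular chains) are reported
#' instead of raised.
#'
#' @param model a `cellml_model`.
#' @param locator optional locator (see [memory_locator()]) enabling import
#'   checks.
#' @return list of issues sorted by location.
#' @export
validate_cellml <- function(model, locator = NULL) {
  issues <- validate_structure(model)
  has_error <- any(vapply(issues, function(i) identical(i$severity, "error"),
                          logical(1)))
  rdf_issue <- tryCatch({ extract_rdf(model); NULL }, cellsim_error = function(e) {
    new_issue("error", e$code, conditionMessage(e),
              e$location %||%
                (if (length(model$rdf_locations)) model$rdf_locations[[1]]) %||%
                new_location())
  })
  if (!is.null(rdf_issue)) {
    issues <- c(issues, list(rdf_issue))
    has_error <- TRUE
  }
  units_model <- model
  if (length(model$imports) > 0) {
    if (is.null(locator)) {
      # imported units cannot be resolved without a locator; dimensional
      # checking happens post-flattening
      units_model <- NULL
    } else {
      flat <- tryCatch(resolve_imports(model, locator),
                       cellsim_error = function(e) {
        new_issue("error", e$code, conditionMessage(e),
                  e$location %||% model$imports[[1]]$location)
      })
      if (is.list(flat) && !inherits(flat, "cellml_model")) {
        issues <- c(issues, list(flat))
        has_error <- TRUE
        units_model <- NULL
      } else {
        units_model <- flat
      }
    }
  }
  if (!has_error && !is.null(units_model)) {
    issues <- c(issues, check_units(units_model))
  }
  sort_issues(issues)
}
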