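# Variable classification.
#
# Connected variables are merged into resolved variables via union-find; each
# resolved variable falls into exactly one of the six categories: variable of
# integration (VOI), constant, computed constant, state, rate, or algebraic.
#
#   state    -- its derivative with respect to the VOI is an equation target
#   rate     -- that derivative
#   constant -- has an initial value and is never computed by an equation
#   computed constant -- equation target whose transitive dependencies
#                        exclude the VOI, states, rates, and algebraic
#                        variables
#   algebraic -- every remaining computed variable (including the unknowns
#                of nonlinear-algebraic blocks)

# -- union-find over (component, variable) keys ------------------------------

uf_new <- function() new.env(parent = emptyenv())

uf_find <- function(uf, x) {
  p <- uf[[x]]
  if (is.null(p) || identical(p, x)) return(x)
  root <- uf_find(uf, p)
  uf[[x]] <- root
  root
}

uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (!identical(ra, rb)) uf[[max(ra, rb)]] <- min(ra, rb)
  invisible(uf)
}

var_key <- function(component, name) paste0(component, "/", name)

#' Classify every resolved variable of a flattened model
#'
#' @param model a valid `cellml_model` without imports.
#' @return a `cellml_classification`: resolved-variable table, category map,
#'   and category counts `(voi, state, rate, constant, computed_constant,
#'   algebraic)`.
#' @export
classify_variables <- function(model) {
  if (length(model$imports) > 0) {
    stop_cellsim("not-flattened",
                 "classification requires a flattened model; resolve imports first")
  }
  uf <- uf_new()
  all_keys <- character(0)
  for (comp in model$components) {
    for (v in comp$variables) {
      k <- var_key(comp$name, v$name)
      uf[[k]] <- k
      all_keys <- c(all_keys, k)
    }
  }
  for (cn in model$connections) {
    for (p in cn$variable_pairs) {
      uf_union(uf, var_key(cn$component_1, p[[1]]),
               var_key(cn$component_2, p[[2]]))
    }
  }

  # group members per representative
  reps <- vapply(all_keys, function(k) uf_find(uf, k), character(1))
  groups <- split(all_keys, reps)

  lookup_var <- function(key) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    model$components[[parts[1]]]$variables[[parts[2]]]
  }

  # equations with component context
  equations <- list()
  for (comp in model$components) {
    for (eq in comp$equations) {
      equations <- c(equations, list(list(component = comp$name, expr = eq)))
    }
  }
  canon <- function(component, name) uf_find(uf, var_key(component, name))

  # targets and derivative references
  target_of <- lapply(equations, function(e) {
    tgt <- equation_target(e$expr)
    if (is.null(tgt)) return(NULL)
    tgt$key <- canon(e$component, tgt$name)
    if (identical(tgt$type, "rate")) tgt$bvar_key <- canon(e$component, tgt$bvar)
    tgt
  })

  bvars <- character(0)
  for (i in seq_along(equations)) {
    for (d in math_diff_refs(equations[[i]]$expr)) {
      bvars <- c(bvars, canon(equations[[i]]$component, d$bvar))
    }
  }
  bvars <- unique(bvars)
  if (length(bvars) == 0) {
    stop_cellsim("no-voi",
                 "model contains no derivative: at least one ODE is required")
  }
  if (length(bvars) > 1) {
    stop_cellsim("multiple-voi",
                 sprintf("more than one distinct bound variable of integration: %s",
                         paste(bvars, collapse = ", ")))
  }
  voi <- bvars[[1]]

  states <- unique(unlist(Filter(Negate(is.null), lapply(target_of, function(t)
    if (!is.null(t) && identical(t$type, "rate")) t$key else NULL))))
  var_targets <- unique(unlist(lapply(target_of, function(t)
    if (!is.null(t) && identical(t$type, "var")) t$key else NULL)))

  # group-level attributes
  group_info <- lapply(groups, function(members) {
    vars <- lapply(members, lookup_var)
    inits <- vapply(vars, `[[`, character(1), "initial_value")
    with_init <- which(!is.na(inits))
    if (length(unique(inits[with_init])) > 1) {
      stop_cellsim("conflicting-initial-values",
                   sprintf("connected variables %s carry conflicting initial values",
                           paste(members, collapse = ", ")))
    }
    # canonical member: the declaration carrying the initial value, else the
    # out-interface (defining) site, else the first in document order
    canon_i <- if (length(with_init) > 0) with_init[1] else {
      outs <- which(vapply(vars, function(v)
        identical(v$public_interface, "out"), logical(1)))
      if (length(outs) > 0) outs[1] else 1L
    }
    list(members = members,
         canonical = members[[canon_i]],
         initial_value = if (length(with_init) > 0)
           as.numeric(inits[with_init[1]]) else NA_real_,
         units = vars[[canon_i]]$units)
  })

  has_init <- vapply(group_info, function(g) !is.na(g$initial_value), logical(1))
  rep_keys <- names(groups)

  # dependency map: target group -> referenced groups (rates referenced via
  # derivatives count as dependencies on the rate, i.e. on the state's ODE)
  deps <- list()
  for (i in seq_along(equations)) {
    t <- target_of[[i]]
    if (is.null(t)) next
    e <- equations[[i]]
    refs <- unique(c(
      vapply(math_ci_names(e$expr), function(nm) canon(e$component, nm), character(1)),
      vapply(math_diff_refs(e$expr), function(d) canon(e$component, d$var), character(1))
    ))
    refs <- setdiff(refs, t$key)
    deps[[t$key]] <- unique(c(deps[[t$key]] %||% character(0), refs))
  }

  category <- setNames(rep(NA_character_, length(rep_keys)), rep_keys)
  category[voi] <- "variable_of_integration"
  category[states] <- "state"
  for (k in rep_keys) {
    if (!is.na(category[k])) next
    if (has_init[[k]] && !k %in% var_targets) category[k] <- "constant"
  }
  for (s in states) {
    if (!has_init[[s]]) {
      stop_cellsim("missing-initial-condition",
                   sprintf("state variable %s has no initial value",
                           group_info[[s]]$canonical))
    }
  }

  # fixpoint: computed constant iff all transitive deps are constants or
  # computed constants
  repeat {
    changed <- FALSE
    for (k in rep_keys) {
      if (!is.na(category[k])) next
      if (!k %in% var_targets) next  # NLA unknowns handled below
      dk <- deps[[k]] %||% character(0)
      if (all(category[dk] %in% c("constant", "computed_constant"), na.rm = FALSE) &&
          !anyNA(category[dk])) {
        category[k] <- "computed_constant"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  category[is.na(category)] <- "algebraic"

  counts <- c(
    voi = 1L,
    state = length(states),
    rate = length(states),
    constant = sum(category == "constant"),
    computed_constant = sum(category == "computed_constant"),
    algebraic = sum(category == "algebraic")
  )

  structure(list(
    uf = uf,
    canon = canon,
    groups = group_info,
    category = category,
    voi = voi,
    states = states,
    counts = counts,
    equations = equations,
    target_of = target_of
  ), class = "cellml_classification")
}

#' @export
print.cellml_classification <- function(x, ...) {
  cat("<cellml_classification>\n")
  print(x$counts)
  invisible(x)
}
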