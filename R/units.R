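# Dimensional analysis.
#
# Every quantity in a model carries units; units reduce to a dimension
# vector of rational exponents over the seven SI base dimensions
# (metre, kilogram, second, ampere, kelvin, mole, candela) plus a scale
# multiplier and an optional linear offset. Booleans are a pseudo-dimension
# incompatible with every physical dimension.

DIM_NAMES <- c("m", "kg", "s", "A", "K", "mol", "cd")

dim_new <- function(m = 0, kg = 0, s = 0, A = 0, K = 0, mol = 0, cd = 0,
                    mult = 1, offset = 0, boolean = FALSE) {
  list(d = c(m = m, kg = kg, s = s, A = A, K = K, mol = mol, cd = cd),
       mult = mult, offset = offset, boolean = boolean)
}

DIM_DIMENSIONLESS <- dim_new()
DIM_BOOLEAN <- dim_new(boolean = TRUE)

dim_equal <- function(a, b, tol = 1e-9) {
  if (a$boolean || b$boolean) return(a$boolean && b$boolean)
  all(abs(a$d - b$d) < tol)
}

dim_mult_equal <- function(a, b, tol = 1e-9) {
  abs(a$mult / b$mult - 1) < tol
}

dim_is_dimensionless <- function(a, tol = 1e-9) {
  !a$boolean && all(abs(a$d) < tol)
}

dim_product <- function(a, b) {
  out <- dim_new()
  out$d <- a$d + b$d
  out$mult <- a$mult * b$mult
  out
}

dim_quotient <- function(a, b) {
  out <- dim_new()
  out$d <- a$d - b$d
  out$mult <- a$mult / b$mult
  out
}

dim_power <- function(a, p) {
  out <- dim_new()
  out$d <- a$d * p
  out$mult <- a$mult^p
  out
}

format_dim <- function(a) {
  if (a$boolean) return("boolean")
  nz <- which(abs(a$d) > 1e-12)
  if (length(nz) == 0) {
    body <- "dimensionless"
  } else {
    body <- paste(sprintf("%s^%g", DIM_NAMES[nz], a$d[nz]), collapse = "*")
  }
  if (abs(a$mult - 1) > 1e-12) body <- sprintf("%s (x%g)", body, a$mult)
  body
}

# The full CellML built-in units table.
builtin_units_table <- function() {
  list(
    ampere        = dim_new(A = 1),
    becquerel     = dim_new(s = -1),
    candela       = dim_new(cd = 1),
    celsius       = dim_new(K = 1, offset = 273.15),
    coulomb       = dim_new(s = 1, A = 1),
    dimensionless = dim_new(),
    farad         = dim_new(m = -2, kg = -1, s = 4, A = 2),
    gram          = dim_new(kg = 1, mult = 1e-3),
    gray          = dim_new(m = 2, s = -2),
    henry         = dim_new(m = 2, kg = 1, s = -2, A = -2),
    hertz         = dim_new(s = -1),
    joule         = dim_new(m = 2, kg = 1, s = -2),
    katal         = dim_new(s = -1, mol = 1),
    kelvin        = dim_new(K = 1),
    kilogram      = dim_new(kg = 1),
    liter         = dim_new(m = 3, mult = 1e-3),
    litre         = dim_new(m = 3, mult = 1e-3),
    lumen         = dim_new(cd = 1),
    lux           = dim_new(m = -2, cd = 1),
    meter         = dim_new(m = 1),
    metre         = dim_new(m = 1),
    mole          = dim_new(mol = 1),
    newton        = dim_new(m = 1, kg = 1, s = -2),
    ohm           = dim_new(m = 2, kg = 1, s = -3, A = -2),
    pascal        = dim_new(m = -1, kg = 1, s = -2),
    radian        = dim_new(),
    second        = dim_new(s = 1),
    siemens       = dim_new(m = -2, kg = -1, s = 3, A = 2),
    sievert       = dim_new(m = 2, s = -2),
    steradian     = dim_new(),
    tesla         = dim_new(kg = 1, s = -2, A = -1),
    volt          = dim_new(m = 2, kg = 1, s = -3, A = -1),
    watt          = dim_new(m = 2, kg = 1, s = -3),
    weber         = dim_new(m = 2, kg = 1, s = -2, A = -1)
  )
}

SI_PREFIXES <- c(yotta = 24, zetta = 21, exa = 18, peta = 15, tera = 12,
                 giga = 9, mega = 6, kilo = 3, hecto = 2, deka = 1, deca = 1,
                 deci = -1, centi = -2, milli = -3, micro = -6, nano = -9,
                 pico = -12, femto = -15, atto = -18, zepto = -21,
                 yocto = -24)

prefix_power <- function(prefix, location = NULL) {
  if (grepl("^-?[0-9]+$", prefix)) return(as.integer(prefix))
  p <- SI_PREFIXES[[prefix]]
  if (is.null(p)) {
    stop_cellsim("bad-prefix", sprintf("unknown SI prefix '%s'", prefix),
                 location)
  }
  as.integer(p)
}

# Expand the model's user units definitions into dimension vectors.
# Returns list(env = name -> dim, issues = list of circular-units /
# dangling-units issues). Cycles are reported once per cycle.
expand_model_units <- function(model) {
  builtins <- builtin_units_table()
  defs <- model$units
  env <- new.env(parent = emptyenv())
  issues <- list()
  seen_cycles <- character(0)
  visiting <- character(0)

  resolve <- function(name, location = NULL) {
    if (!is.null(builtins[[name]]) && is.null(defs[[name]])) {
      return(builtins[[name]])
    }
    if (!is.null(env[[name]])) return(env[[name]])
    def <- defs[[name]]
    if (is.null(def)) {
      issues[[length(issues) + 1]] <<- new_issue(
        "error", "dangling-units",
        sprintf("units reference '%s' does not resolve", name), location)
      return(NULL)
    }
    if (name %in% visiting) {
      cycle <- sort(unique(c(visiting[seq(match(name, visiting), length(visiting))], name)))
      key <- paste(cycle, collapse = ",")
      if (!key %in% seen_cycles) {
        seen_cycles <<- c(seen_cycles, key)
        issues[[length(issues) + 1]] <<- new_issue(
          "error", "circular-units",
          sprintf("units defined circularly: %s", paste(cycle, collapse = " -> ")),
          def$location)
      }
      return(NULL)
    }
    if (def$base) {
      # User-declared base unit: its own fresh dimension is not expressible
      # over SI; treat as dimensionless with unit scale (documented).
      env[[name]] <- dim_new()
      return(env[[name]])
    }
    visiting <<- c(visiting, name)
    on.exit(visiting <<- visiting[-length(visiting)], add = TRUE)
    acc <- dim_new()
    for (p in def$parts) {
      sub <- resolve(p$units, p$location)
      if (is.null(sub)) return(NULL)
      scaled <- sub
      scaled$mult <- scaled$mult * 10^p$prefix * p$multiplier
      acc <- dim_product(acc, dim_power(scaled, p$exponent))
      if (p$offset != 0) acc$offset <- p$offset
    }
    env[[name]] <- acc
    acc
  }

  for (u in defs) resolve(u$name, u$location)
  list(resolve = resolve, get_issues = function() issues)
}

# Constant-fold an expression made of cn / pi / arithmetic; NA when it is
# not constant-valued. Used for power exponents and root degrees.
const_value <- function(node) {
  if (is.null(node)) return(NA_real_)
  switch(node$kind,
    "cn" = node$value,
    "pi" = pi,
    "apply" = {
      vals <- vapply(node$args, const_value, numeric(1))
      if (anyNA(vals)) return(NA_real_)
      switch(node$op,
        "plus" = sum(vals),
        "minus" = if (length(vals) == 1) -vals else vals[1] - vals[2],
        "times" = prod(vals),
        "divide" = vals[1] / vals[2],
        "power" = vals[1]^vals[2],
        NA_real_)
    },
    NA_real_
  )
}

#' Dimension of a mathematical expression
#'
#' Applies the dimensional-consistency rules (addition-class operators need
#' equal dimension vectors; products/quotients combine exponent vectors and
#' multipliers; powers need constant dimensionless exponents; transcendental
#' functions need dimensionless arguments; a derivative divides the dependent
#' dimension by the bound dimension; piecewise branches must agree and
#' conditions must be boolean).
#'
#' @param expr an expression tree from [parse_mathml()].
#' @param units_env function mapping a units name to a dimension vector (or a
#'   named list of dimension vectors).
#' @param var_env named list mapping variable names to dimension vectors.
#' @return list with `dim` (a dimension vector, or `NULL` when inconsistent)
#'   and `issues` (inconsistency reports naming the operator, both dimension
#'   vectors, and the location).
#' @export
dimension_of <- function(expr, units_env, var_env) {
  issues <- list()
  push <- function(code, msg, loc) {
    issues[[length(issues) + 1]] <<- new_issue("warning", code, msg, loc)
  }
  lookup_units <- function(name, loc) {
    if (is.function(units_env)) return(units_env(name, loc))
    units_env[[name]] %||% builtin_units_table()[[name]]
  }

  walk <- function(node) {
    if (is.null(node)) return(NULL)
    switch(node$kind,
      "ci" = var_env[[node$name]],
      "cn" = {
        if (is.na(node$units)) DIM_DIMENSIONLESS
        else lookup_units(node$units, node$location) %||% DIM_DIMENSIONLESS
      },
      "pi" = DIM_DIMENSIONLESS,
      "bool" = DIM_BOOLEAN,
      "diff" = {
        dv <- var_env[[node$var]]; db <- var_env[[node$bvar]]
        if (is.null(dv) || is.null(db)) return(NULL)
        dim_quotient(dv, db)
      },
      "eq" = walk_nary("eq", list(node$lhs, node$rhs), node$location,
                       relation = TRUE),
      "apply" = walk_apply(node),
      "piecewise" = {
        dims <- list()
        for (p in node$pieces) {
          cd <- walk(p$cond)
          if (!is.null(cd) && !cd$boolean) {
            push("boolean-mismatch",
                 sprintf("piecewise condition has dimension %s, expected boolean",
                         format_dim(cd)), p$cond$location)
          }
          dims <- c(dims, list(walk(p$value)))
        }
        if (!is.null(node$otherwise)) dims <- c(dims, list(walk(node$otherwise)))
        dims <- Filter(Negate(is.null), dims)
        if (length(dims) == 0) return(NULL)
        for (d in dims[-1]) {
          if (!dim_equal(dims[[1]], d)) {
            push("mismatched-addition",
                 sprintf("piecewise branches disagree: %s vs %s",
                         format_dim(dims[[1]]), format_dim(d)), node$location)
            return(NULL)
          }
        }
        dims[[1]]
      },
      NULL
    )
  }

  walk_nary <- function(op, args, loc, relation = FALSE) {
    dims <- lapply(args, walk)
    if (any(vapply(dims, is.null, logical(1)))) return(NULL)
    for (d in dims[-1]) {
      if (!dim_equal(dims[[1]], d)) {
        push("mismatched-addition",
             sprintf("operands of <%s> have dimensions %s and %s",
                     op, format_dim(dims[[1]]), format_dim(d)), loc)
        return(NULL)
      }
      if (!dims[[1]]$boolean && !dim_mult_equal(dims[[1]], d)) {
        push("scale-mismatch",
             sprintf("operands of <%s> share a dimension but differ in scale (%s vs %s)",
                     op, format_dim(dims[[1]]), format_dim(d)), loc)
      }
    }
    if (relation) DIM_BOOLEAN else dims[[1]]
  }

  walk_apply <- function(node) {
    op <- node$op
    loc <- node$location
    if (op %in% c("plus", "minus")) {
      return(walk_nary(op, node$args, loc))
    }
    if (op %in% c("eq", "neq", "lt", "leq", "gt", "geq")) {
      return(walk_nary(op, node$args, loc, relation = TRUE))
    }
    if (op %in% c("and", "or", "not")) {
      for (a in node$args) {
        d <- walk(a)
        if (!is.null(d) && !d$boolean) {
          push("boolean-mismatch",
               sprintf("argument of <%s> has dimension %s, expected boolean",
                       op, format_dim(d)), loc)
          return(NULL)
        }
      }
      return(DIM_BOOLEAN)
    }
    if (identical(op, "times")) {
      dims <- lapply(node$args, walk)
      if (any(vapply(dims, is.null, logical(1)))) return(NULL)
      return(Reduce(dim_product, dims))
    }
    if (identical(op, "divide")) {
      a <- walk(node$args[[1]]); b <- walk(node$args[[2]])
      if (is.null(a) || is.null(b)) return(NULL)
      return(dim_quotient(a, b))
    }
    if (identical(op, "power")) {
      base <- walk(node$args[[1]])
      edim <- walk(node$args[[2]])
      if (is.null(base)) return(NULL)
      if (!is.null(edim) && !dim_is_dimensionless(edim)) {
        push("bad-power-exponent",
             sprintf("power exponent has dimension %s, expected dimensionless",
                     format_dim(edim)), loc)
        return(NULL)
      }
      p <- const_value(node$args[[2]])
      if (is.na(p)) {
        if (dim_is_dimensionless(base)) return(DIM_DIMENSIONLESS)
        push("bad-power-exponent",
             "non-constant exponent over a dimensional base; dimension not statically determinable",
             loc)
        return(NULL)
      }
      return(dim_power(base, p))
    }
    if (identical(op, "root")) {
      base <- walk(node$args[[1]])
      if (is.null(base)) return(NULL)
      d <- if (is.null(node$degree)) 2 else const_value(node$degree)
      if (is.na(d)) {
        push("bad-power-exponent", "non-constant root degree", loc)
        return(NULL)
      }
      return(dim_power(base, 1 / d))
    }
    if (op %in% c("abs", "floor", "ceiling")) {
      return(walk(node$args[[1]]))
    }
    # transcendental: exp ln log sin cos tan arcsin arccos arctan
    d <- walk(node$args[[1]])
    if (!is.null(d) && !dim_is_dimensionless(d)) {
      push("non-dimensionless-arg",
           sprintf("argument of <%s> has dimension %s, expected dimensionless",
                   op, format_dim(d)), loc)
      return(NULL)
    }
    DIM_DIMENSIONLESS
  }

  d <- walk(expr)
  list(dim = d, issues = issues)
}
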