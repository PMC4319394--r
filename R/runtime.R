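# Native runtime generation.
#
# The equation plan is rendered to R source (one function per phase), parsed
# and evaluated into closures. Computed constants live at the tail of the
# constants vector, so the evaluator signatures are
#   initialise()                               -> list(constants, states)
#   compute_computed_constants(constants)      -> constants
#   compute_rates(voi, states, constants, nla) -> list(rates, algebraic)
#   compute_algebraic(voi, states, rates, constants, nla) -> algebraic
# Evaluators are pure given their inputs; the only mutable element is the
# per-session NLA warm-start environment `nla`, created fresh by
# `new_nla_env()` so concurrent sessions share nothing.

#' Build an executable runtime from a flattened model
#'
#' @param model a valid `cellml_model` without imports.
#' @param classification,plan optionally precomputed analysis results.
#' @return a `cellml_runtime` with evaluator closures, category counts, and
#'   per-parameter metadata (canonical `component/name` label, units,
#'   category, array index).
#' @export
build_runtime <- function(model,
                          classification = classify_variables(model),
                          plan = order_equations(model, classification)) {
  cls <- classification

  keys <- names(cls$category)
  const_keys <- keys[cls$category == "constant"]
  ccons_keys <- keys[cls$category == "computed_constant"]
  state_keys <- cls$states
  alg_keys <- keys[cls$category == "algebraic"]
  # stable document order is preserved by names(cls$category)

  idx_const <- stats::setNames(seq_along(const_keys), const_keys)
  idx_ccons <- stats::setNames(length(const_keys) + seq_along(ccons_keys),
                               ccons_keys)
  idx_state <- stats::setNames(seq_along(state_keys), state_keys)
  idx_alg <- stats::setNames(seq_along(alg_keys), alg_keys)

  slot_of <- function(key) {
    cat0 <- cls$category[[key]]
    switch(cat0,
      "variable_of_integration" = "voi",
      "constant" = sprintf("constants[%d]", idx_const[[key]]),
      "computed_constant" = sprintf("constants[%d]", idx_ccons[[key]]),
      "state" = sprintf("states[%d]", idx_state[[key]]),
      "algebraic" = sprintf("algebraic[%d]", idx_alg[[key]]),
      stop_cellsim("internal", sprintf("no slot for %s (%s)", key, cat0))
    )
  }
  rate_slot <- function(state_key) sprintf("rates[%d]", idx_state[[state_key]])

  # resolver for an equation in a given component
  make_resolver <- function(component) {
    function(name) slot_of(cls$canon(component, name))
  }
  make_rate_resolver <- function(component) {
    function(var) rate_slot(cls$canon(component, var))
  }

  render_steps <- function(steps) {
    lines <- character(0)
    blk_id <- 0L
    for (s in steps) {
      if (identical(s$kind, "assign")) {
        resolve <- make_resolver(s$component)
        resolve_rate <- make_rate_resolver(s$component)
        rhs <- math_to_r(s$expr, resolve, resolve_rate)
        lhs <- if (identical(s$target$type, "rate")) {
          rate_slot(s$target$key)
        } else slot_of(s$target$key)
        lines <- c(lines, sprintf("%s <- %s", lhs, rhs))
      } else {
        blk_id <- blk_id + 1L
        lines <- c(lines, render_nla_block(s, blk_id, cls, slot_of,
                                           make_resolver, make_rate_resolver))
      }
    }
    lines
  }

  by_phase <- function(phase) {
    Filter(function(s) identical(s$phase, phase), plan$steps)
  }
  # rate evaluation executes algebraic/NLA steps too (in plan order), so
  # every quantity a rate needs is available
  rate_steps <- Filter(function(s) s$phase %in% c("algebraic", "rates"),
                       plan$steps)

  n_const_total <- length(const_keys) + length(ccons_keys)
  init_lines <- c(
    sprintf("constants <- numeric(%d)", n_const_total),
    sprintf("states <- numeric(%d)", length(state_keys))
  )
  for (k in const_keys) {
    iv <- cls$groups[[k]]$initial_value
    if (is.na(iv)) {
      stop_cellsim("missing-initial-condition",
                   sprintf("constant %s has no literal initial value",
                           cls$groups[[k]]$canonical))
    }
    init_lines <- c(init_lines,
                    sprintf("constants[%d] <- %s", idx_const[[k]], fmt_num(iv)))
  }
  for (k in state_keys) {
    init_lines <- c(init_lines,
                    sprintf("states[%d] <- %s", idx_state[[k]],
                            fmt_num(cls$groups[[k]]$initial_value)))
  }
  init_lines <- c(init_lines, "list(constants = constants, states = states)")

  ccons_lines <- c(render_steps(by_phase("computed_constants")), "constants")
  rates_lines <- c(
    sprintf("rates <- numeric(%d)", length(state_keys)),
    sprintf("algebraic <- numeric(%d)", length(alg_keys)),
    render_steps(rate_steps),
    "list(rates = rates, algebraic = algebraic)"
  )
  alg_lines <- c(
    sprintf("algebraic <- numeric(%d)", length(alg_keys)),
    render_steps(by_phase("algebraic")),
    "algebraic"
  )

  env <- new.env(parent = baseenv())
  env$.nla_solve <- nla_dispatch
  mk <- function(args, lines) {
    src <- sprintf("function(%s) {\n%s\n}", args,
                   paste(paste0("  ", lines), collapse = "\n"))
    eval(parse(text = src)[[1]], envir = env)
  }

  meta <- runtime_meta(cls, const_keys, ccons_keys, state_keys, alg_keys)
  counts <- cls$counts

  structure(list(
    counts = counts,
    meta = meta,
    voi = cls$groups[[cls$voi]],
    voi_label = cls$groups[[cls$voi]]$canonical,
    voi_units = cls$groups[[cls$voi]]$units,
    initialise = mk("", init_lines),
    compute_computed_constants = mk("constants", ccons_lines),
    compute_rates = mk("voi, states, constants, nla = NULL", rates_lines),
    compute_algebraic = mk("voi, states, rates, constants, nla = NULL",
                           alg_lines),
    new_nla_env = function() {
      e <- new.env(parent = emptyenv())
      e$warm <- list()
      e$tol <- 1e-12
      e$max_iterations <- 100L
      e
    },
    plan = plan,
    classification = cls,
    model = model
  ), class = "cellml_runtime")
}

runtime_meta <- function(cls, const_keys, ccons_keys, state_keys, alg_keys) {
  row <- function(key, category, index) {
    g <- cls$groups[[key]]
    parts <- strsplit(g$canonical, "/", fixed = TRUE)[[1]]
    data.frame(label = g$canonical, component = parts[1], name = parts[2],
               units = g$units, category = category, index = index,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_along(const_keys)) rows <- c(rows, list(row(const_keys[i], "constant", i)))
  for (i in seq_along(ccons_keys)) rows <- c(rows, list(row(ccons_keys[i], "computed_constant", length(const_keys) + i)))
  for (i in seq_along(state_keys)) rows <- c(rows, list(row(state_keys[i], "state", i)))
  for (i in seq_along(state_keys)) {
    r <- row(state_keys[i], "rate", i)
    r$label <- paste0(r$label, "'")
    r$name <- paste0(r$name, "'")
    rows <- c(rows, list(r))
  }
  for (i in seq_along(alg_keys)) rows <- c(rows, list(row(alg_keys[i], "algebraic", i)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# NLA block rendering: unknowns are loaded from the solution vector into
# their algebraic slots, residuals are lhs - rhs of the block equations.
render_nla_block <- function(step, blk_id, cls, slot_of, make_resolver,
                             make_rate_resolver) {
  unknowns <- step$unknowns
  load_lines <- vapply(seq_along(unknowns), function(k)
    sprintf("  %s <- .u[%d]", slot_of(unknowns[[k]]), k), character(1))
  res_exprs <- vapply(step$equations, function(e) {
    resolve <- make_resolver(e$component)
    resolve_rate <- make_rate_resolver(e$component)
    sprintf("(%s) - (%s)",
            math_to_r(e$expr$lhs, resolve, resolve_rate),
            math_to_r(e$expr$rhs, resolve, resolve_rate))
  }, character(1))
  c(
    sprintf(".res_%d <- function(.u) {", blk_id),
    load_lines,
    sprintf("  c(%s)", paste(res_exprs, collapse = ", ")),
    "}",
    sprintf(".u <- .nla_solve(nla, %dL, .res_%d, %dL)", blk_id, blk_id,
            length(unknowns)),
    vapply(seq_along(unknowns), function(k)
      sprintf("%s <- .u[%d]", slot_of(unknowns[[k]]), k), character(1))
  )
}

# Warm-started dispatch into the registered NLA solver: previous solution
# per block, zeros on first call.
nla_dispatch <- function(nla, block_id, residual, n) {
  if (is.null(nla)) nla <- new.env(parent = emptyenv())
  guess <- nla$warm[[as.character(block_id)]] %||% numeric(n)
  sol <- newton_solve(residual, guess,
                      tol = nla$tol %||% 1e-12,
                      max_iterations = nla$max_iterations %||% 100L)
  if (!is.null(nla$warm)) nla$warm[[as.character(block_id)]] <- sol
  sol
}

# ---- MathML AST -> R expression text ---------------------------------------

math_to_r <- function(node, resolve, resolve_rate) {
  rec <- function(n) math_to_r(n, resolve, resolve_rate)
  switch(node$kind,
    "ci" = resolve(node$name),
    "cn" = node$text,
    "pi" = "pi",
    "bool" = if (node$value) "TRUE" else "FALSE",
    "diff" = resolve_rate(node$var),
    "apply" = {
      a <- vapply(node$args, rec, character(1))
      op <- node$op
      if (op %in% c("plus")) sprintf("(%s)", paste(a, collapse = " + "))
      else if (identical(op, "minus")) {
        if (length(a) == 1) sprintf("(-%s)", a) else sprintf("(%s - %s)", a[1], a[2])
      }
      else if (identical(op, "times")) sprintf("(%s)", paste(a, collapse = " * "))
      else if (identical(op, "divide")) sprintf("(%s / %s)", a[1], a[2])
      else if (identical(op, "power")) sprintf("(%s)^(%s)", a[1], a[2])
      else if (identical(op, "root")) {
        if (is.null(node$degree)) sprintf("sqrt(%s)", a[1])
        else sprintf("(%s)^(1/(%s))", a[1], rec(node$degree))
      }
      else if (identical(op, "exp")) sprintf("exp(%s)", a[1])
      else if (identical(op, "ln")) sprintf("log(%s)", a[1])
      else if (identical(op, "log")) {
        if (is.null(node$logbase)) sprintf("log10(%s)", a[1])
        else sprintf("(log(%s)/log(%s))", a[1], rec(node$logbase))
      }
      else if (identical(op, "abs")) sprintf("abs(%s)", a[1])
      else if (identical(op, "floor")) sprintf("floor(%s)", a[1])
      else if (identical(op, "ceiling")) sprintf("ceiling(%s)", a[1])
      else if (op %in% c("sin", "cos", "tan")) sprintf("%s(%s)", op, a[1])
      else if (identical(op, "arcsin")) sprintf("asin(%s)", a[1])
      else if (identical(op, "arccos")) sprintf("acos(%s)", a[1])
      else if (identical(op, "arctan")) sprintf("atan(%s)", a[1])
      else if (identical(op, "and")) sprintf("(%s)", paste(a, collapse = " && "))
      else if (identical(op, "or")) sprintf("(%s)", paste(a, collapse = " || "))
      else if (identical(op, "not")) sprintf("(!%s)", a[1])
      else if (identical(op, "eq")) sprintf("(%s == %s)", a[1], a[2])
      else if (identical(op, "neq")) sprintf("(%s != %s)", a[1], a[2])
      else if (identical(op, "lt")) sprintf("(%s < %s)", a[1], a[2])
      else if (identical(op, "leq")) sprintf("(%s <= %s)", a[1], a[2])
      else if (identical(op, "gt")) sprintf("(%s > %s)", a[1], a[2])
      else if (identical(op, "geq")) sprintf("(%s >= %s)", a[1], a[2])
      else stop_cellsim("unsupported-operator",
                        sprintf("no R rendering for operator <%s>", op))
    },
    "piecewise" = {
      out <- "NaN"
      items <- rev(node$pieces)
      if (!is.null(node$otherwise)) out <- rec(node$otherwise)
      for (p in items) {
        out <- sprintf("(if (%s) %s else %s)", rec(p$cond), rec(p$value), out)
      }
      out
    },
    stop_cellsim("internal", sprintf("cannot render node kind %s", node$kind))
  )
}

#' @export
print.cellml_runtime <- function(x, ...) {
  cat("<cellml_runtime>\n")
  print(x$counts)
  invisible(x)
}
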