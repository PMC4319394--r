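# Source export in user-definable formats.
#
# A format description is a flat key = value text file: statement syntax
# (assignment, terminator, comment), identifier templates per category
# array with an {i} placeholder and an indexing base, one rendering per
# MathML operator (`infix`, `call` or `prefix` plus a token), a piecewise
# style, and a block style selecting the function-wrapper dialect. The
# four shipped formats (c, f77, matlab, python) are data files in exactly
# the syntax users supply -- the user-defined path is the only path.

#' Load a format description
#'
#' @param format a shipped format name (`"c"`, `"f77"`, `"matlab"`,
#'   `"python"`), a path to a format file, or an already-parsed
#'   `format_description` (returned unchanged).
#' @return a `format_description`.
#' @export
format_description <- function(format) {
  if (inherits(format, "format_description")) return(format)
  stopifnot(is.character(format), length(format) == 1)
  path <- if (format %in% c("c", "f77", "matlab", "python")) {
    system.file("formats", paste0(format, ".fmt"), package = "cellsim",
                mustWork = TRUE)
  } else format
  if (!file.exists(path)) {
    stop_cellsim("format-description",
                 sprintf("no format file at '%s'", path))
  }
  parse_format_text(readLines(path, warn = FALSE))
}

parse_format_text <- function(lines) {
  kv <- list()
  for (l in lines) {
    if (grepl("^\\s*(#.*)?$", l)) next
    eq <- regexpr("=", l, fixed = TRUE)
    if (eq < 0) {
      stop_cellsim("format-description",
                   sprintf("format line without '=': %s", l))
    }
    key <- trimws(substr(l, 1, eq - 1))
    val <- sub("^ ", "", substring(l, eq + 1))
    kv[[key]] <- val
  }
  ops <- list()
  for (k in names(kv)) {
    if (!startsWith(k, "op.")) next
    parts <- strsplit(kv[[k]], " ", fixed = TRUE)[[1]]
    style <- parts[1]
    if (!style %in% c("infix", "call", "prefix")) {
      stop_cellsim("format-description",
                   sprintf("operator rendering '%s' must be 'infix', 'call' or 'prefix'",
                           kv[[k]]))
    }
    ops[[substring(k, 4)]] <- list(style = style,
                                   token = paste(parts[-1], collapse = " "))
  }
  structure(list(
    name = kv$name %||% "custom",
    comment = kv$comment %||% "#",
    assign = trimws(kv$assign %||% "="),
    terminator = kv$terminator %||% "",
    index_base = as.integer(kv$index_base %||% "0"),
    block_style = kv$block_style %||% "python",
    piecewise = kv$piecewise %||% "ternary_python",
    max_line = if (!is.null(kv$max_line)) as.integer(kv$max_line) else NA_integer_,
    continuation = kv$continuation %||% "",
    bool_true = kv$bool.true %||% "True",
    bool_false = kv$bool.false %||% "False",
    pi = kv$pi %||% "pi",
    nan = kv$nan %||% "float('nan')",
    arrays = list(
      constants = kv$array.constants %||% "constants[{i}]",
      states = kv$array.states %||% "states[{i}]",
      rates = kv$array.rates %||% "rates[{i}]",
      algebraic = kv$array.algebraic %||% "algebraic[{i}]"
    ),
    voi_name = kv$scalar.voi %||% "voi",
    ops = ops
  ), class = "format_description")
}

fmt_array_ref <- function(fmt, array, index1) {
  gsub("{i}", as.character(index1 - 1L + fmt$index_base),
       fmt$arrays[[array]], fixed = TRUE)
}

fmt_op <- function(fmt, op) {
  r <- fmt$ops[[op]]
  if (is.null(r)) {
    stop_cellsim("format-description",
                 sprintf("format '%s' has no rendering for operator '%s'",
                         fmt$name, op))
  }
  r
}

render_op <- function(fmt, op, args) {
  r <- fmt_op(fmt, op)
  switch(r$style,
    infix = sprintf("(%s)", paste(args, collapse = sprintf(" %s ", r$token))),
    call = sprintf("%s(%s)", r$token, paste(args, collapse = ", ")),
    prefix = sprintf("(%s%s)", r$token, args[1])
  )
}

render_expr <- function(node, fmt, resolve, resolve_rate) {
  rec <- function(n) render_expr(n, fmt, resolve, resolve_rate)
  switch(node$kind,
    "ci" = resolve(node$name),
    "cn" = node$text,
    "pi" = fmt$pi,
    "bool" = if (node$value) fmt$bool_true else fmt$bool_false,
    "diff" = resolve_rate(node$var),
    "apply" = {
      op <- node$op
      if (identical(op, "minus") && length(node$args) == 1) {
        r <- fmt_op(fmt, "minus")
        return(sprintf("(%s%s)", r$token, rec(node$args[[1]])))
      }
      if (identical(op, "root")) {
        if (is.null(node$degree)) {
          return(render_op(fmt, "root", rec(node$args[[1]])))
        }
        return(render_op(fmt, "power",
                         c(rec(node$args[[1]]),
                           sprintf("(1.0 / (%s))", rec(node$degree)))))
      }
      if (identical(op, "log") && !is.null(node$logbase)) {
        return(sprintf("(%s / %s)",
                       render_op(fmt, "ln", rec(node$args[[1]])),
                       render_op(fmt, "ln", rec(node$logbase))))
      }
      render_op(fmt, op, vapply(node$args, rec, character(1)))
    },
    "piecewise" = {
      vals <- vapply(node$pieces, function(p) rec(p$value), character(1))
      conds <- vapply(node$pieces, function(p) rec(p$cond), character(1))
      tail <- if (!is.null(node$otherwise)) rec(node$otherwise) else fmt$nan
      switch(fmt$piecewise,
        ternary_python = {
          out <- tail
          for (k in rev(seq_along(vals))) {
            out <- sprintf("(%s if %s else %s)", vals[k], conds[k], out)
          }
          out
        },
        ternary_c = {
          out <- tail
          for (k in rev(seq_along(vals))) {
            out <- sprintf("(%s ? %s : %s)", conds[k], vals[k], out)
          }
          out
        },
        # fallback: a PIECEWISE(cond1, val1, ..., otherwise) call the target
        # environment must provide
        sprintf("PIECEWISE(%s)",
                paste(c(rbind(conds, vals), tail), collapse = ", "))
      )
    },
    stop_cellsim("internal", sprintf("cannot render node kind %s", node$kind))
  )
}

#' Export a model's runtime as source in a target format
#'
#' Emits a header comment with the category counts, declarations, and one
#' function per phase of the equation plan (initialisation, computed
#' constants, rates, algebraic), with identifiers mangled per the format.
#' Output is deterministic. Nonlinear-algebraic blocks are emitted as a
#' clearly marked stub (the shipped executable target is the explicit
#' evaluator set); see the vignette for this limitation.
#'
#' @param model a flattened `cellml_model` (or a `cellml_runtime`).
#' @param format shipped format name, format-file path, or
#'   `format_description`.
#' @return character scalar of generated source.
#' @export
export_source <- function(model, format = "python") {
  fmt <- format_description(format)
  rt <- if (inherits(model, "cellml_runtime")) model else build_runtime(model)
  cls <- rt$classification
  plan <- rt$plan
  meta <- rt$meta

  n_states <- rt$counts[["state"]]
  n_const <- rt$counts[["constant"]] + rt$counts[["computed_constant"]]
  n_alg <- rt$counts[["algebraic"]]

  slot_of <- function(key) {
    cat0 <- cls$category[[key]]
    if (identical(cat0, "variable_of_integration")) return(fmt$voi_name)
    sel <- which(sub("'$", "", meta$label) == cls$groups[[key]]$canonical &
                   meta$category != "rate")
    i <- meta$index[sel[1]]
    switch(cat0,
      constant = , computed_constant = fmt_array_ref(fmt, "constants", i),
      state = fmt_array_ref(fmt, "states", i),
      algebraic = fmt_array_ref(fmt, "algebraic", i))
  }
  rate_of <- function(key) {
    sel <- which(sub("'$", "", meta$label) == cls$groups[[key]]$canonical &
                   meta$category == "rate")
    fmt_array_ref(fmt, "rates", meta$index[sel[1]])
  }
  mk_resolver <- function(component) function(name) slot_of(cls$canon(component, name))
  mk_rate_resolver <- function(component) function(name) rate_of(cls$canon(component, name))

  stmt <- function(lhs, rhs) {
    sprintf("%s %s %s%s", lhs, fmt$assign, rhs, fmt$terminator)
  }

  steps_lines <- function(steps) {
    out <- character(0)
    for (s in steps) {
      if (identical(s$kind, "assign")) {
        rhs <- render_expr(s$expr, fmt, mk_resolver(s$component),
                           mk_rate_resolver(s$component))
        lhs <- if (identical(s$target$type, "rate")) rate_of(s$target$key)
               else slot_of(s$target$key)
        out <- c(out, stmt(lhs, rhs))
      } else {
        out <- c(out,
                 paste0(fmt$comment,
                        " nonlinear-algebraic block over {",
                        paste(s$unknowns, collapse = ", "),
                        "}: solve the residual system with an external NLA solver"),
                 nla_stub_line(fmt))
      }
    }
    out
  }

  by_phase <- function(phase) Filter(function(s) identical(s$phase, phase),
                                     plan$steps)
  rate_steps <- Filter(function(s) s$phase %in% c("algebraic", "rates"),
                       plan$steps)

  init_lines <- character(0)
  for (j in which(meta$category == "constant")) {
    k <- var_key(meta$component[j], meta$name[j])
    key <- cls$canon(meta$component[j], meta$name[j])
    init_lines <- c(init_lines,
                    stmt(fmt_array_ref(fmt, "constants", meta$index[j]),
                         fmt_num(cls$groups[[key]]$initial_value)))
  }
  for (j in which(meta$category == "state")) {
    key <- cls$canon(meta$component[j], meta$name[j])
    init_lines <- c(init_lines,
                    stmt(fmt_array_ref(fmt, "states", meta$index[j]),
                         fmt_num(cls$groups[[key]]$initial_value)))
  }

  sections <- list(
    header = c(
      paste0(fmt$comment, sprintf(" model '%s' exported by cellsim (%s format)",
                                  rt$model$name, fmt$name)),
      paste0(fmt$comment, sprintf(
        " categories: %d variable(s) of integration, %d state(s), %d rate(s), %d constant(s), %d computed constant(s), %d algebraic",
        rt$counts[["voi"]], rt$counts[["state"]], rt$counts[["rate"]],
        rt$counts[["constant"]], rt$counts[["computed_constant"]],
        rt$counts[["algebraic"]]))
    ),
    init = init_lines,
    ccons = steps_lines(by_phase("computed_constants")),
    rates = steps_lines(rate_steps),
    algebraic = steps_lines(by_phase("algebraic"))
  )

  emitter <- switch(fmt$block_style,
    python = emit_python, c = emit_c, matlab = emit_matlab, f77 = emit_f77,
    stop_cellsim("format-description",
                 sprintf("unknown block style '%s'", fmt$block_style)))
  text <- emitter(fmt, sections, n_const, n_states, n_alg)
  paste0(paste(text, collapse = "\n"), "\n")
}

nla_stub_line <- function(fmt) {
  if (identical(fmt$block_style, "python")) {
    "raise NotImplementedError('nonlinear-algebraic block')"
  } else {
    paste0(fmt$comment, " (no explicit assignment form exists)")
  }
}

emit_python <- function(fmt, s, n_const, n_states, n_alg) {
  ind <- function(x) paste0("    ", x)
  c(s$header,
    "from math import *",
    "",
    "def initialise():",
    ind(sprintf("constants = [0.0] * %d", n_const)),
    ind(sprintf("states = [0.0] * %d", n_states)),
    ind(s$init),
    ind("return constants, states"),
    "",
    "def compute_computed_constants(constants):",
    ind(s$ccons),
    ind("return constants"),
    "",
    "def compute_rates(voi, states, constants):",
    ind(sprintf("rates = [0.0] * %d", n_states)),
    ind(sprintf("algebraic = [0.0] * %d", n_alg)),
    ind(s$rates),
    ind("return rates, algebraic"),
    "",
    "def compute_algebraic(voi, states, rates, constants):",
    ind(sprintf("algebraic = [0.0] * %d", n_alg)),
    ind(s$algebraic),
    ind("return algebraic"))
}

emit_c <- function(fmt, s, n_const, n_states, n_alg) {
  ind <- function(x) paste0("    ", x)
  c(s$header,
    "#include <math.h>",
    "",
    "void initialise(double* constants, double* states)",
    "{", ind(s$init), "}",
    "",
    "void compute_computed_constants(double* constants)",
    "{", ind(s$ccons), "}",
    "",
    "void compute_rates(double voi, double* states, double* rates, double* constants, double* algebraic)",
    "{", ind(s$rates), "}",
    "",
    "void compute_algebraic(double voi, double* states, double* rates, double* constants, double* algebraic)",
    "{", ind(s$algebraic), "}")
}

emit_matlab <- function(fmt, s, n_const, n_states, n_alg) {
  ind <- function(x) paste0("    ", x)
  c(s$header,
    "function [constants, states] = initialise()",
    ind(sprintf("constants = zeros(%d, 1);", n_const)),
    ind(sprintf("states = zeros(%d, 1);", n_states)),
    ind(s$init), "end",
    "",
    "function constants = compute_computed_constants(constants)",
    ind(s$ccons), "end",
    "",
    "function [rates, algebraic] = compute_rates(voi, states, constants)",
    ind(sprintf("rates = zeros(%d, 1);", n_states)),
    ind(sprintf("algebraic = zeros(%d, 1);", n_alg)),
    ind(s$rates), "end",
    "",
    "function algebraic = compute_algebraic(voi, states, rates, constants)",
    ind(sprintf("algebraic = zeros(%d, 1);", n_alg)),
    ind(s$algebraic), "end")
}

emit_f77 <- function(fmt, s, n_const, n_states, n_alg) {
  body <- function(x) f77_wrap(paste0("      ", toupper(x)), fmt)
  decl <- "      DOUBLE PRECISION CONSTS(*), STATES(*), RATES(*), ALGBRC(*)"
  header <- unlist(lapply(toupper(s$header), function(l) {
    out <- character(0)
    while (nchar(l) > 72) {
      out <- c(out, substr(l, 1, 72))
      l <- paste0("C ", substring(l, 73))
    }
    c(out, l)
  }))
  c(header,
    "      SUBROUTINE INITIALISE(CONSTS, STATES)",
    "      DOUBLE PRECISION CONSTS(*), STATES(*)",
    body(s$init),
    "      RETURN", "      END",
    "      SUBROUTINE COMPCC(CONSTS)",
    "      DOUBLE PRECISION CONSTS(*)",
    body(s$ccons),
    "      RETURN", "      END",
    "      SUBROUTINE COMPRAT(VOI, STATES, RATES, CONSTS, ALGBRC)",
    "      DOUBLE PRECISION VOI", decl,
    body(s$rates),
    "      RETURN", "      END",
    "      SUBROUTINE COMPALG(VOI, STATES, RATES, CONSTS, ALGBRC)",
    "      DOUBLE PRECISION VOI", decl,
    body(s$algebraic),
    "      RETURN", "      END")
}

# FORTRAN 77 fixed form: wrap to the 72-column limit with continuation
# lines (non-blank column 6).
f77_wrap <- function(lines, fmt) {
  limit <- if (is.na(fmt$max_line)) 72L else fmt$max_line
  cont <- if (nzchar(fmt$continuation)) fmt$continuation else "     &"
  out <- character(0)
  for (l in lines) {
    while (nchar(l) > limit) {
      cut <- limit
      out <- c(out, substr(l, 1, cut))
      l <- paste0(cont, substring(l, cut + 1))
    }
    out <- c(out, l)
  }
  out
}
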