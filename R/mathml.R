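# Content-MathML subset.
#
# The supported operator set is exactly what ODE/DAE cell models need:
# arithmetic, powers/roots, exp/log, abs/floor/ceiling, trigonometry and
# inverses, boolean connectives, relations, piecewise, and first-order
# derivatives with a single bound variable. Anything else is a hard,
# located error -- never silently dropped.

MATHML_UNARY  <- c("exp", "ln", "abs", "floor", "ceiling",
                   "sin", "cos", "tan", "arcsin", "arccos", "arctan", "not")
MATHML_NARY   <- c("plus", "times", "and", "or")
MATHML_BINARY <- c("divide", "power", "neq", "lt", "leq", "gt", "geq")
# minus: unary or binary; eq: equation root or relation; log/root take
# qualifiers. diff is handled separately.
MATHML_OPS <- c(MATHML_UNARY, MATHML_NARY, MATHML_BINARY,
                "minus", "eq", "log", "root", "diff")

math_issue <- function(collector, code, message, location) {
  if (is.null(collector)) stop_cellsim(code, message, location)
  collector$issues <- c(collector$issues,
                        list(new_issue("error", code, message, location)))
  NULL
}

#' Parse a content-MathML fragment
#'
#' Each top-level child of the `math` element must be an equality-rooted
#' `apply`; the result is a list of typed expression trees.
#'
#' @param fragment an `xml2` node for a `math` element, or a character string
#'   containing one.
#' @param loc_idx,collector internal: source-location index and issue
#'   collector used by [parse_cellml()]. When `collector` is `NULL`
#'   (the default), problems raise classed errors instead of being recorded.
#' @return list of expression trees (see the package vignette for the node
#'   kinds).
#' @export
parse_mathml <- function(fragment, loc_idx = NULL, collector = NULL) {
  if (is.character(fragment)) fragment <- xml2::read_xml(fragment)
  if (!identical(node_local_name(fragment), "math")) {
    stop_cellsim("not-mathml", "expected a content-MathML <math> element")
  }
  kids <- xml2::xml_children(fragment)
  out <- list()
  for (k in seq_along(kids)) {
    loc <- next_location(loc_idx, "apply")
    expr <- parse_math_expr(kids[[k]], loc_idx, collector, loc_taken = loc)
    if (is.null(expr)) next
    if (!identical(expr$kind, "eq")) {
      math_issue(collector, "not-an-equation",
                 "top-level mathematics must be an equality", expr$location)
      next
    }
    out <- c(out, list(expr))
  }
  out
}

parse_math_expr <- function(node, loc_idx, collector, loc_taken = NULL) {
  tag <- node_local_name(node)
  loc <- loc_taken %||% next_location(loc_idx, tag)
  switch(tag,
    "apply" = parse_math_apply(node, loc_idx, collector,
                               if (is.null(loc_taken)) loc else loc),
    "ci" = list(kind = "ci", name = trimws(xml2::xml_text(node)),
                location = loc),
    "cn" = parse_math_cn(node, collector, loc),
    "piecewise" = parse_math_piecewise(node, loc_idx, collector, loc),
    "pi" = list(kind = "pi", location = loc),
    "true" = list(kind = "bool", value = TRUE, location = loc),
    "false" = list(kind = "bool", value = FALSE, location = loc),
    math_issue(collector, "unsupported-operator",
               sprintf("unsupported MathML element <%s>", tag), loc)
  )
}

parse_math_cn <- function(node, collector, loc) {
  units <- xml2::xml_attr(node, "units")
  text <- trimws(xml2::xml_text(node))
  if (is.na(units)) {
    math_issue(collector, "cn-without-units",
               sprintf("number %s carries no units attribute", text), loc)
    units <- NA_character_
  }
  list(kind = "cn", value = as.numeric(text), text = text,
       units = units, location = loc)
}

parse_math_piecewise <- function(node, loc_idx, collector, loc) {
  pieces <- list()
  otherwise <- NULL
  for (kid in xml2::xml_children(node)) {
    ktag <- node_local_name(kid)
    if (identical(ktag, "piece")) {
      parts <- xml2::xml_children(kid)
      if (length(parts) != 2) {
        return(math_issue(collector, "unsupported-operator",
                          "<piece> must hold exactly a value and a condition",
                          loc))
      }
      value <- parse_math_expr(parts[[1]], loc_idx, collector)
      cond <- parse_math_expr(parts[[2]], loc_idx, collector)
      if (is.null(value) || is.null(cond)) return(NULL)
      pieces <- c(pieces, list(list(value = value, cond = cond)))
    } else if (identical(ktag, "otherwise")) {
      parts <- xml2::xml_children(kid)
      otherwise <- parse_math_expr(parts[[1]], loc_idx, collector)
      if (is.null(otherwise)) return(NULL)
    } else {
      return(math_issue(collector, "unsupported-operator",
                        sprintf("unsupported element <%s> in piecewise", ktag),
                        loc))
    }
  }
  list(kind = "piecewise", pieces = pieces, otherwise = otherwise,
       location = loc)
}

parse_math_apply <- function(node, loc_idx, collector, loc) {
  kids <- xml2::xml_children(node)
  if (length(kids) == 0) {
    return(math_issue(collector, "unsupported-operator",
                      "empty <apply>", loc))
  }
  op <- node_local_name(kids[[1]])
  rest <- kids[-1]

  if (identical(op, "diff")) {
    # <apply><diff/><bvar><ci>t</ci></bvar><ci>y</ci></apply>
    bvar <- NULL; var <- NULL
    for (kid in rest) {
      ktag <- node_local_name(kid)
      if (identical(ktag, "bvar")) {
        bkids <- xml2::xml_children(kid)
        for (bk in bkids) {
          btag <- node_local_name(bk)
          if (identical(btag, "ci")) {
            next_location(loc_idx, "ci")
            bvar <- trimws(xml2::xml_text(bk))
          } else {
            return(math_issue(collector, "unsupported-operator",
                              sprintf("unsupported <%s> under <bvar> (only first derivatives are supported)",
                                      btag), loc))
          }
        }
      } else if (identical(ktag, "ci")) {
        next_location(loc_idx, "ci")
        var <- trimws(xml2::xml_text(kid))
      } else {
        return(math_issue(collector, "unsupported-operator",
                          sprintf("unsupported <%s> under <diff>", ktag), loc))
      }
    }
    if (is.null(bvar) || is.null(var)) {
      return(math_issue(collector, "unsupported-operator",
                        "derivative must name one bound variable and one dependent variable",
                        loc))
    }
    return(list(kind = "diff", var = var, bvar = bvar, location = loc))
  }

  if (!op %in% MATHML_OPS) {
    return(math_issue(collector, "unsupported-operator",
                      sprintf("unsupported MathML operator <%s>", op), loc))
  }

  degree <- NULL; logbase <- NULL
  args <- list()
  for (kid in rest) {
    ktag <- node_local_name(kid)
    if (identical(ktag, "degree") && identical(op, "root")) {
      degree <- parse_math_expr(xml2::xml_children(kid)[[1]], loc_idx, collector)
      if (is.null(degree)) return(NULL)
    } else if (identical(ktag, "logbase") && identical(op, "log")) {
      logbase <- parse_math_expr(xml2::xml_children(kid)[[1]], loc_idx, collector)
      if (is.null(logbase)) return(NULL)
    } else {
      a <- parse_math_expr(kid, loc_idx, collector)
      if (is.null(a)) return(NULL)
      args <- c(args, list(a))
    }
  }

  n <- length(args)
  bad_arity <- (op %in% MATHML_UNARY && n != 1) ||
    (op %in% MATHML_BINARY && n != 2) ||
    (op %in% MATHML_NARY && n < 2) ||
    (identical(op, "minus") && !n %in% c(1, 2)) ||
    (op %in% c("log", "root") && n != 1) ||
    (identical(op, "eq") && n != 2)
  if (bad_arity) {
    return(math_issue(collector, "unsupported-operator",
                      sprintf("operator <%s> applied to %d argument(s)", op, n),
                      loc))
  }

  if (identical(op, "eq")) {
    return(list(kind = "eq", lhs = args[[1]], rhs = args[[2]],
                location = loc))
  }
  node <- list(kind = "apply", op = op, args = args, location = loc)
  if (!is.null(degree)) node$degree <- degree
  if (!is.null(logbase)) node$logbase <- logbase
  node
}

# ---- AST utilities ----------------------------------------------------------

# All variable names referenced by ci nodes (not bound-variable positions).
math_ci_names <- function(node) {
  if (is.null(node) || !is.list(node)) return(character(0))
  switch(node$kind %||% "",
    "ci" = node$name,
    "cn" = , "pi" = , "bool" = character(0),
    "diff" = character(0),
    "eq" = c(math_ci_names(node$lhs), math_ci_names(node$rhs)),
    "apply" = unique(unlist(c(lapply(node$args, math_ci_names),
                              list(math_ci_names(node$degree)),
                              list(math_ci_names(node$logbase))))),
    "piecewise" = unique(unlist(c(
      lapply(node$pieces, function(p) c(math_ci_names(p$value),
                                        math_ci_names(p$cond))),
      list(math_ci_names(node$otherwise))))),
    character(0)
  )
}

# All derivative references (list of list(var, bvar)).
math_diff_refs <- function(node) {
  if (is.null(node) || !is.list(node)) return(list())
  switch(node$kind %||% "",
    "diff" = list(list(var = node$var, bvar = node$bvar)),
    "eq" = c(math_diff_refs(node$lhs), math_diff_refs(node$rhs)),
    "apply" = do.call(c, c(lapply(node$args, math_diff_refs), list(list()))),
    "piecewise" = do.call(c, c(
      lapply(node$pieces, function(p) c(math_diff_refs(p$value),
                                        math_diff_refs(p$cond))),
      list(math_diff_refs(node$otherwise) %||% list()), list(list()))),
    list()
  )
}

# All cn units names used in an expression.
math_cn_units <- function(node) {
  if (is.null(node) || !is.list(node)) return(character(0))
  switch(node$kind %||% "",
    "cn" = if (is.na(node$units)) character(0) else node$units,
    "eq" = c(math_cn_units(node$lhs), math_cn_units(node$rhs)),
    "apply" = unique(unlist(c(lapply(node$args, math_cn_units),
                              list(math_cn_units(node$degree)),
                              list(math_cn_units(node$logbase))))),
    "piecewise" = unique(unlist(c(
      lapply(node$pieces, function(p) c(math_cn_units(p$value),
                                        math_cn_units(p$cond))),
      list(math_cn_units(node$otherwise))))),
    character(0)
  )
}

# Rewrite cn units names (used when flattening remaps imported units).
math_rewrite_cn_units <- function(node, map) {
  if (is.null(node) || !is.list(node)) return(node)
  k <- node$kind %||% ""
  if (identical(k, "cn")) {
    if (!is.na(node$units) && !is.null(map[[node$units]])) {
      node$units <- map[[node$units]]
    }
    return(node)
  }
  if (identical(k, "eq")) {
    node$lhs <- math_rewrite_cn_units(node$lhs, map)
    node$rhs <- math_rewrite_cn_units(node$rhs, map)
  } else if (identical(k, "apply")) {
    node$args <- lapply(node$args, math_rewrite_cn_units, map = map)
    if (!is.null(node$degree)) node$degree <- math_rewrite_cn_units(node$degree, map)
    if (!is.null(node$logbase)) node$logbase <- math_rewrite_cn_units(node$logbase, map)
  } else if (identical(k, "piecewise")) {
    node$pieces <- lapply(node$pieces, function(p) {
      list(value = math_rewrite_cn_units(p$value, map),
           cond = math_rewrite_cn_units(p$cond, map))
    })
    if (!is.null(node$otherwise)) node$otherwise <- math_rewrite_cn_units(node$otherwise, map)
  }
  node
}

# ---- serialization ----------------------------------------------------------

serialize_math_block <- function(equations, indent) {
  pad <- strrep(" ", indent)
  out <- sprintf("%s<math xmlns=\"%s\">", pad, NS_MATHML)
  for (eq in equations) {
    out <- c(out, serialize_math_expr(eq, indent + 2L))
  }
  c(out, sprintf("%s</math>", pad))
}

serialize_math_expr <- function(node, indent) {
  pad <- strrep(" ", indent)
  k <- node$kind
  if (identical(k, "ci")) {
    return(sprintf("%s<ci>%s</ci>", pad, xml_escape_text(node$name)))
  }
  if (identical(k, "cn")) {
    if (is.na(node$units)) {
      return(sprintf("%s<cn>%s</cn>", pad, xml_escape_text(node$text)))
    }
    return(sprintf("%s<cn cellml:units=\"%s\">%s</cn>", pad,
                   xml_escape_attr(node$units), xml_escape_text(node$text)))
  }
  if (identical(k, "pi")) return(sprintf("%s<pi/>", pad))
  if (identical(k, "bool")) {
    return(sprintf("%s<%s/>", pad, if (node$value) "true" else "false"))
  }
  if (identical(k, "diff")) {
    return(c(sprintf("%s<apply><diff/>", pad),
             sprintf("%s  <bvar><ci>%s</ci></bvar>", pad,
                     xml_escape_text(node$bvar)),
             sprintf("%s  <ci>%s</ci>", pad, xml_escape_text(node$var)),
             sprintf("%s</apply>", pad)))
  }
  if (identical(k, "eq")) {
    return(c(sprintf("%s<apply><eq/>", pad),
             serialize_math_expr(node$lhs, indent + 2L),
             serialize_math_expr(node$rhs, indent + 2L),
             sprintf("%s</apply>", pad)))
  }
  if (identical(k, "piecewise")) {
    out <- sprintf("%s<piecewise>", pad)
    for (p in node$pieces) {
      out <- c(out, sprintf("%s  <piece>", pad),
               serialize_math_expr(p$value, indent + 4L),
               serialize_math_expr(p$cond, indent + 4L),
               sprintf("%s  </piece>", pad))
    }
    if (!is.null(node$otherwise)) {
      out <- c(out, sprintf("%s  <otherwise>", pad),
               serialize_math_expr(node$otherwise, indent + 4L),
               sprintf("%s  </otherwise>", pad))
    }
    c(out, sprintf("%s</piecewise>", pad))
  } else if (identical(k, "apply")) {
    out <- sprintf("%s<apply><%s/>", pad, node$op)
    if (!is.null(node$degree)) {
      out <- c(out, sprintf("%s  <degree>", pad),
               serialize_math_expr(node$degree, indent + 4L),
               sprintf("%s  </degree>", pad))
    }
    if (!is.null(node$logbase)) {
      out <- c(out, sprintf("%s  <logbase>", pad),
               serialize_math_expr(node$logbase, indent + 4L),
               sprintf("%s  </logbase>", pad))
    }
    for (a in node$args) out <- c(out, serialize_math_expr(a, indent + 2L))
    c(out, sprintf("%s</apply>", pad))
  } else {
    stop_cellsim("internal", sprintf("cannot serialize node kind %s", k))
  }
}
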