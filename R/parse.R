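# CellML document parsing.
#
# The model container mirrors the CellML document structure: named units
# definitions, components (variables + equations), connections, imports
# (1.1 only), plus two verbatim blocks -- the embedded RDF/XML annotation
# element and any foreign-namespace children -- kept byte-for-byte for
# round-tripping. Reaction, group and scripting elements of the wider
# CellML specification are preserved opaquely in the same way; they are
# not interpreted.

#' Parse a CellML 1.0/1.1 document
#'
#' @param text character scalar holding the document, or a file path when
#'   `is_path = TRUE` (see [read_cellml()] for the usual file entry point).
#' @param base_locator locator string recorded on the model; import hrefs are
#'   resolved relative to it.
#' @return a `cellml_model` object.
#' @seealso [serialize_cellml()], [validate_cellml()]
#' @export
parse_cellml <- function(text, base_locator = "") {
  stopifnot(is.character(text), length(text) == 1)
  doc <- tryCatch(
    xml2::read_xml(text),
    error = function(e) {
      msg <- conditionMessage(e)
      ln <- regmatches(msg, regexpr("line [0-9]+", msg))
      ln <- if (length(ln)) as.integer(sub("line ", "", ln)) else 1L
      stop_cellsim("xml-parse", sprintf("malformed XML: %s", msg),
                   new_location(ln, 1L))
    }
  )
  root <- xml2::xml_root(doc)
  nsmap <- xml2::xml_ns(doc)
  root_ns <- node_ns_uri(root, nsmap)
  version <- version_for_cellml_ns(root_ns)
  if (!identical(node_local_name(root), "model") || is.null(version)) {
    stop_cellsim("not-cellml",
                 sprintf("root element <%s> in namespace '%s' is not a CellML model",
                         node_local_name(root), root_ns))
  }

  idx <- index_source_locations(text)
  math_collector <- new.env(parent = emptyenv())
  math_collector$issues <- list()

  model <- structure(list(
    name = xml2::xml_attr(root, "name"),
    version = version,
    cmeta_id = cmeta_id_of(root),
    units = list(),
    components = list(),
    connections = list(),
    imports = list(),
    rdf = character(0),
    rdf_locations = list(),
    foreign = character(0),
    math_issues = list(),
    base_locator = base_locator,
    location = next_location(idx, "model")
  ), class = "cellml_model")

  for (node in as.list(xml2::xml_children(root))) {
    ns <- node_ns_uri(node, nsmap)
    tag <- node_local_name(node)
    if (identical(ns, root_ns)) {
      switch(tag,
        "units" = {
          u <- parse_units_def(node, idx)
          model$units <- c(model$units, list(u))
        },
        "component" = {
          cp <- parse_component(node, nsmap, root_ns, idx, math_collector)
          model$components <- c(model$components, list(cp))
        },
        "connection" = {
          model$connections <- c(model$connections,
                                 list(parse_connection(node, idx)))
        },
        "import" = {
          model$imports <- c(model$imports, list(parse_import(node, idx)))
        },
        # Preserved opaquely: exercised by no supported semantics.
        model$foreign <- c(model$foreign, as.character(node))
      )
    } else if (identical(ns, NS_RDF) && identical(tag, "RDF")) {
      model$rdf <- c(model$rdf, as.character(node))
      model$rdf_locations <- c(model$rdf_locations,
                               list(next_location(idx, "RDF")))
    } else {
      model$foreign <- c(model$foreign, as.character(node))
    }
  }

  if (identical(version, "1.0") && length(model$imports) > 0) {
    stop_cellsim("not-cellml",
                 "CellML 1.0 documents must not contain import elements",
                 model$imports[[1]]$location)
  }
  names(model$units) <- vapply(model$units, `[[`, character(1), "name")
  names(model$components) <- vapply(model$components, `[[`, character(1), "name")
  model$math_issues <- math_collector$issues
  model
}

#' Read and parse a CellML file
#'
#' @param path file path.
#' @return a `cellml_model`; the file path becomes the model's base locator.
#' @export
read_cellml <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parse_cellml(text, base_locator = path)
}

cmeta_id_of <- function(node) {
  a <- xml2::xml_attrs(node)
  # cmeta:id arrives as "id" with its namespace stripped by xml2; CellML
  # elements carry no other id-named attribute.
  if ("id" %in% names(a)) unname(a[["id"]]) else NA_character_
}

parse_units_def <- function(node, idx) {
  loc <- next_location(idx, "units")
  base <- identical(xml2::xml_attr(node, "base_units"), "yes")
  parts <- list()
  for (kid in as.list(xml2::xml_children(node))) {
    if (!identical(node_local_name(kid), "unit")) next
    parts <- c(parts, list(parse_unit_ref(kid, idx)))
  }
  list(name = xml2::xml_attr(node, "name"), base = base, parts = parts,
       location = loc)
}

parse_unit_ref <- function(node, idx) {
  loc <- next_location(idx, "unit")
  prefix <- xml2::xml_attr(node, "prefix")
  prefix <- if (is.na(prefix)) 0L else prefix_power(prefix, loc)
  num_attr <- function(name, default) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else as.numeric(v)
  }
  list(units = xml2::xml_attr(node, "units"),
       prefix = prefix,
       exponent = num_attr("exponent", 1),
       multiplier = num_attr("multiplier", 1),
       offset = num_attr("offset", 0),
       location = loc)
}

parse_component <- function(node, nsmap, root_ns, idx, collector) {
  loc <- next_location(idx, "component")
  comp <- list(name = xml2::xml_attr(node, "name"),
               cmeta_id = cmeta_id_of(node),
               variables = list(), equations = list(), location = loc)
  for (kid in as.list(xml2::xml_children(node))) {
    ns <- node_ns_uri(kid, nsmap)
    tag <- node_local_name(kid)
    if (identical(ns, root_ns) && identical(tag, "variable")) {
      comp$variables <- c(comp$variables, list(parse_variable(kid, idx)))
    } else if (identical(ns, NS_MATHML) && identical(tag, "math")) {
      next_location(idx, "math")
      eqs <- parse_mathml(kid, loc_idx = idx, collector = collector)
      comp$equations <- c(comp$equations, eqs)
    }
  }
  names(comp$variables) <- vapply(comp$variables, `[[`, character(1), "name")
  comp
}

parse_variable <- function(node, idx) {
  loc <- next_location(idx, "variable")
  iface <- function(name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) "none" else v
  }
  list(name = xml2::xml_attr(node, "name"),
       units = xml2::xml_attr(node, "units"),
       initial_value = xml2::xml_attr(node, "initial_value"),
       public_interface = iface("public_interface"),
       private_interface = iface("private_interface"),
       cmeta_id = cmeta_id_of(node),
       location = loc)
}

parse_connection <- function(node, idx) {
  loc <- next_location(idx, "connection")
  conn <- list(component_1 = NA_character_, component_2 = NA_character_,
               variable_pairs = list(), location = loc)
  for (kid in as.list(xml2::xml_children(node))) {
    tag <- node_local_name(kid)
    if (identical(tag, "map_components")) {
      next_location(idx, "map_components")
      conn$component_1 <- xml2::xml_attr(kid, "component_1")
      conn$component_2 <- xml2::xml_attr(kid, "component_2")
    } else if (identical(tag, "map_variables")) {
      next_location(idx, "map_variables")
      conn$variable_pairs <- c(conn$variable_pairs, list(
        c(xml2::xml_attr(kid, "variable_1"), xml2::xml_attr(kid, "variable_2"))))
    }
  }
  conn
}

parse_import <- function(node, idx) {
  loc <- next_location(idx, "import")
  imp <- list(href = xml2::xml_attr(node, "href"),
              units = list(), components = list(), location = loc)
  for (kid in as.list(xml2::xml_children(node))) {
    tag <- node_local_name(kid)
    if (identical(tag, "units")) {
      next_location(idx, "units")
      imp$units <- c(imp$units, list(
        list(name = xml2::xml_attr(kid, "name"),
             units_ref = xml2::xml_attr(kid, "units_ref"))))
    } else if (identical(tag, "component")) {
      next_location(idx, "component")
      imp$components <- c(imp$components, list(
        list(name = xml2::xml_attr(kid, "name"),
             component_ref = xml2::xml_attr(kid, "component_ref"))))
    }
  }
  imp
}

#' Detect the CellML version of a model or raw text
#'
#' The version is determined strictly from the document namespace; feature
#' usage is never sniffed.
#'
#' @param x a `cellml_model` or a character scalar of raw XML.
#' @return `"1.0"` or `"1.1"`.
#' @export
detect_version <- function(x) {
  if (inherits(x, "cellml_model")) return(x$version)
  stopifnot(is.character(x), length(x) == 1)
  doc <- tryCatch(xml2::read_xml(x), error = function(e) {
    stop_cellsim("xml-parse", sprintf("malformed XML: %s", conditionMessage(e)))
  })
  root <- xml2::xml_root(doc)
  v <- version_for_cellml_ns(node_ns_uri(root, xml2::xml_ns(doc)))
  if (is.null(v)) {
    stop_cellsim("not-cellml",
                 sprintf("unknown document namespace '%s'",
                         node_ns_uri(root, xml2::xml_ns(doc))))
  }
  v
}

#' @export
print.cellml_model <- function(x, ...) {
  cat(sprintf("<cellml_model> '%s' (CellML %s)\n", x$name, x$version))
  cat(sprintf("  components: %d, connections: %d, units: %d, imports: %d\n",
              length(x$components), length(x$connections),
              length(x$units), length(x$imports)))
  invisible(x)
}
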