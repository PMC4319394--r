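# Canonical CellML serialization.
#
# Output is deterministic: fixed indentation, fixed attribute order, elements
# emitted in stored (document) order. The round-trip guarantee is structural,
# not byte-level, except for the embedded RDF and foreign-namespace blocks,
# which reappear verbatim.

#' Serialize a CellML model
#'
#' @param model a `cellml_model`.
#' @return character scalar: the document text (UTF-8, `\n` line endings,
#'   trailing newline).
#' @export
serialize_cellml <- function(model) {
  stopifnot(inherits(model, "cellml_model"))
  ns <- cellml_ns_for_version(model$version)
  head_attrs <- sprintf(" name=\"%s\"", xml_escape_attr(model$name))
  if (!is.na(model$cmeta_id)) {
    head_attrs <- paste0(head_attrs,
                         sprintf(" cmeta:id=\"%s\"", xml_escape_attr(model$cmeta_id)))
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<model%s xmlns=\"%s\" xmlns:cellml=\"%s\"",
                   " xmlns:cmeta=\"%s\" xmlns:xlink=\"%s\">"),
            head_attrs, ns, ns, NS_CMETA, NS_XLINK)
  )
  for (imp in model$imports) out <- c(out, serialize_import(imp))
  for (u in model$units) out <- c(out, serialize_units_def(u))
  for (cp in model$components) out <- c(out, serialize_component(cp))
  for (cn in model$connections) out <- c(out, serialize_connection(cn))
  for (block in model$rdf) out <- c(out, indent_block(block, 2L))
  for (block in model$foreign) out <- c(out, indent_block(block, 2L))
  out <- c(out, "</model>")
  paste0(paste(out, collapse = "\n"), "\n")
}

# Verbatim blocks are re-emitted with their own internal layout untouched.
indent_block <- function(text, indent) {
  strsplit(text, "\n", fixed = TRUE)[[1]]
}

serialize_units_def <- function(u) {
  if (u$base) {
    return(sprintf("  <units name=\"%s\" base_units=\"yes\"/>",
                   xml_escape_attr(u$name)))
  }
  out <- sprintf("  <units name=\"%s\">", xml_escape_attr(u$name))
  for (p in u$parts) {
    attrs <- sprintf(" units=\"%s\"", xml_escape_attr(p$units))
    if (p$prefix != 0) attrs <- paste0(attrs, sprintf(" prefix=\"%s\"", fmt_num(p$prefix)))
    if (p$exponent != 1) attrs <- paste0(attrs, sprintf(" exponent=\"%s\"", fmt_num(p$exponent)))
    if (p$multiplier != 1) attrs <- paste0(attrs, sprintf(" multiplier=\"%s\"", fmt_num(p$multiplier)))
    if (p$offset != 0) attrs <- paste0(attrs, sprintf(" offset=\"%s\"", fmt_num(p$offset)))
    out <- c(out, sprintf("    <unit%s/>", attrs))
  }
  c(out, "  </units>")
}

serialize_component <- function(cp) {
  attrs <- sprintf(" name=\"%s\"", xml_escape_attr(cp$name))
  if (!is.na(cp$cmeta_id)) {
    attrs <- paste0(attrs, sprintf(" cmeta:id=\"%s\"", xml_escape_attr(cp$cmeta_id)))
  }
  out <- sprintf("  <component%s>", attrs)
  for (v in cp$variables) {
    vat <- sprintf(" name=\"%s\" units=\"%s\"",
                   xml_escape_attr(v$name), xml_escape_attr(v$units))
    if (!is.na(v$initial_value)) {
      vat <- paste0(vat, sprintf(" initial_value=\"%s\"",
                                 xml_escape_attr(v$initial_value)))
    }
    if (!identical(v$public_interface, "none")) {
      vat <- paste0(vat, sprintf(" public_interface=\"%s\"", v$public_interface))
    }
    if (!identical(v$private_interface, "none")) {
      vat <- paste0(vat, sprintf(" private_interface=\"%s\"", v$private_interface))
    }
    if (!is.na(v$cmeta_id)) {
      vat <- paste0(vat, sprintf(" cmeta:id=\"%s\"", xml_escape_attr(v$cmeta_id)))
    }
    out <- c(out, sprintf("    <variable%s/>", vat))
  }
  if (length(cp$equations) > 0) {
    out <- c(out, serialize_math_block(cp$equations, 4L))
  }
  c(out, "  </component>")
}

serialize_connection <- function(cn) {
  out <- c("  <connection>",
           sprintf("    <map_components component_1=\"%s\" component_2=\"%s\"/>",
                   xml_escape_attr(cn$component_1), xml_escape_attr(cn$component_2)))
  for (p in cn$variable_pairs) {
    out <- c(out, sprintf("    <map_variables variable_1=\"%s\" variable_2=\"%s\"/>",
                          xml_escape_attr(p[[1]]), xml_escape_attr(p[[2]])))
  }
  c(out, "  </connection>")
}

serialize_import <- function(imp) {
  out <- sprintf("  <import xlink:href=\"%s\">", xml_escape_attr(imp$href))
  for (u in imp$units) {
    out <- c(out, sprintf("    <units name=\"%s\" units_ref=\"%s\"/>",
                          xml_escape_attr(u$name), xml_escape_attr(u$units_ref)))
  }
  for (cp in imp$components) {
    out <- c(out, sprintf("    <component name=\"%s\" component_ref=\"%s\"/>",
                          xml_escape_attr(cp$name), xml_escape_attr(cp$component_ref)))
  }
  c(out, "  </import>")
}
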