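# Namespace URIs that identify the document dialects handled here.
NS_CELLML_10 <- "http://www.cellml.org/cellml/1.0#"
NS_CELLML_11 <- "http://www.cellml.org/cellml/1.1#"
NS_MATHML    <- "http://www.w3.org/1998/Math/MathML"
NS_CMETA     <- "http://www.cellml.org/metadata/1.0#"
NS_RDF       <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_XLINK     <- "http://www.w3.org/1999/xlink"
NS_BQBIOL    <- "http://biomodels.net/biology-qualifiers/"
NS_BQMODEL   <- "http://biomodels.net/model-qualifiers/"

cellml_ns_for_version <- function(version) {
  if (identical(version, "1.1")) NS_CELLML_11 else NS_CELLML_10
}

version_for_cellml_ns <- function(uri) {
  if (identical(uri, NS_CELLML_10)) return("1.0")
  if (identical(uri, NS_CELLML_11)) return("1.1")
  NULL
}

# Namespace URI of an xml2 node, resolved through the document prefix map.
node_ns_uri <- function(node, nsmap) {
  full <- xml2::xml_name(node, nsmap)
  if (!grepl(":", full, fixed = TRUE)) return("")
  prefix <- sub(":.*$", "", full)
  unname(nsmap[[prefix]]) %||% ""
}

node_local_name <- function(node) {
  sub("^.*:", "", xml2::xml_name(node))
}

xml_escape_attr <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Attribute serializer for numerics: enough digits to round-trip the values
# used in unit definitions without switching to scientific notation for
# common magnitudes.
fmt_num <- function(x) {
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  s
}
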