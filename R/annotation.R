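# Element-level semantic annotation.
#
# Annotations are RDF triples embedded in the document: the subject is the
# document locator plus an element's cmeta:id fragment, the predicate a
# biomodels.net qualifier URI, the object an identifiers.org URI. Deprecated
# MIRIAM URNs in pre-existing documents are recognized on read and converted
# (never written back). The embedded block is a constrained RDF/XML form:
# rdf:RDF > rdf:Description/@rdf:about > qualifier elements carrying
# @rdf:resource.

BIOLOGY_QUALIFIERS <- c("encodes", "hasPart", "hasProperty", "hasVersion",
                        "is", "isDescribedBy", "isEncodedBy", "isHomologTo",
                        "isPartOf", "isPropertyOf", "isVersionOf", "occursIn",
                        "hasTaxon")
MODEL_QUALIFIERS <- c("is", "isDerivedFrom", "isDescribedBy", "isInstanceOf",
                      "hasInstance")

#' biomodels.net qualifier vocabularies
#'
#' @return character vector of valid terms.
#' @export
biology_qualifiers <- function() BIOLOGY_QUALIFIERS

#' @rdname biology_qualifiers
#' @export
model_qualifiers <- function() MODEL_QUALIFIERS

# Accepts "bio:isVersionOf", "biology:isVersionOf", "model:is", or
# c(vocabulary, term); returns list(vocabulary, term, uri).
parse_qualifier <- function(qualifier) {
  if (length(qualifier) == 2) {
    vocab <- qualifier[[1]]; term <- qualifier[[2]]
  } else {
    parts <- strsplit(qualifier, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop_cellsim("vocabulary",
                   sprintf("qualifier '%s' must be '<vocabulary>:<term>'",
                           qualifier))
    }
    vocab <- parts[1]; term <- parts[2]
  }
  vocab <- switch(vocab, bio = , biology = "biology", model = "model",
                  stop_cellsim("vocabulary",
                               sprintf("unknown qualifier vocabulary '%s' (use 'biology' or 'model')",
                                       vocab)))
  valid <- if (identical(vocab, "biology")) BIOLOGY_QUALIFIERS else MODEL_QUALIFIERS
  if (!term %in% valid) {
    stop_cellsim("vocabulary",
                 sprintf("unknown %s qualifier '%s'; valid terms: %s",
                         vocab, term, paste(valid, collapse = ", ")))
  }
  base <- if (identical(vocab, "biology")) NS_BQBIOL else NS_BQMODEL
  list(vocabulary = vocab, term = term, uri = paste0(base, term))
}

# "collection:id" (first colon splits) -> identifiers.org URI.
parse_resource <- function(resource) {
  if (grepl("^https?://identifiers\\.org/", resource)) return(resource)
  if (grepl("^urn:miriam:", resource)) return(urn_to_identifiers_uri(resource))
  colon <- regexpr(":", resource, fixed = TRUE)
  if (colon < 0) {
    stop_cellsim("resource",
                 sprintf("resource '%s' must be '<collection>:<id>', an identifiers.org URI, or a MIRIAM URN",
                         resource))
  }
  collection <- substr(resource, 1, colon - 1)
  id <- substring(resource, colon + 1)
  if (!grepl("^[a-z0-9._]+$", collection) || !nzchar(id)) {
    stop_cellsim("resource",
                 sprintf("'%s' is not a valid compact identifier (lowercase collection, nonempty id)",
                         resource))
  }
  paste0("http://identifiers.org/", collection, "/", id)
}

#' Convert a MIRIAM URN to an identifiers.org URI
#'
#' `urn:miriam:<collection>:<encoded-id>` becomes
#' `http://identifiers.org/<collection>/<id>` with the id percent-decoded.
#'
#' @param urn a MIRIAM URN string.
#' @return identifiers.org URI string.
#' @seealso [identifiers_uri_to_urn()] for the inverse.
#' @export
urn_to_identifiers_uri <- function(urn) {
  m <- regmatches(urn, regexec("^urn:miriam:([^:]+):(.+)$", urn))[[1]]
  if (length(m) != 3) {
    stop_cellsim("urn-format",
                 sprintf("'%s' is not a MIRIAM URN (urn:miriam:<collection>:<id>)",
                         urn))
  }
  paste0("http://identifiers.org/", m[2], "/", utils::URLdecode(m[3]))
}

#' Convert an identifiers.org URI to a MIRIAM URN
#'
#' Inverse of [urn_to_identifiers_uri()]; the id is percent-encoded.
#'
#' @param uri an identifiers.org URI.
#' @return MIRIAM URN string.
#' @export
identifiers_uri_to_urn <- function(uri) {
  m <- regmatches(uri,
                  regexec("^https?://identifiers\\.org/([^/]+)/(.+)$", uri))[[1]]
  if (length(m) != 3) {
    stop_cellsim("urn-format",
                 sprintf("'%s' is not an identifiers.org URI", uri))
  }
  paste0("urn:miriam:", m[2], ":",
         utils::URLencode(m[3], reserved = TRUE))
}

new_triple <- function(subject, predicate, object, deprecated = FALSE) {
  list(subject = subject, predicate = predicate, object = object,
       deprecated = deprecated)
}

#' Extract the annotation triples embedded in a model
#'
#' @param model a `cellml_model`.
#' @return list of triples `list(subject, predicate, object, deprecated)`;
#'   `deprecated` flags objects that were stored as MIRIAM URNs (returned
#'   converted to identifiers.org form). Raises a `corrupted-rdf` error when
#'   the block cannot be read (the model itself remains usable).
#' @export
extract_rdf <- function(model) {
  triples <- list()
  for (block in model$rdf) {
    doc <- tryCatch(xml2::read_xml(block), error = function(e) {
      stop_cellsim("corrupted-rdf",
                   sprintf("embedded RDF block cannot be parsed: %s",
                           conditionMessage(e)))
    })
    root <- xml2::xml_root(doc)
    nsmap <- xml2::xml_ns(doc)
    if (!identical(node_local_name(root), "RDF") ||
        !identical(node_ns_uri(root, nsmap), NS_RDF)) {
      stop_cellsim("corrupted-rdf", "embedded RDF block root is not rdf:RDF")
    }
    for (desc in as.list(xml2::xml_children(root))) {
      if (!identical(node_local_name(desc), "Description")) {
        stop_cellsim("corrupted-rdf",
                     sprintf("unexpected element <%s> under rdf:RDF",
                             node_local_name(desc)))
      }
      about <- xml2::xml_attr(desc, "about")
      if (is.na(about)) {
        stop_cellsim("corrupted-rdf",
                     "rdf:Description without an rdf:about subject")
      }
      subject <- sub("^[^#]*#", "", about)
      for (prop in as.list(xml2::xml_children(desc))) {
        pred_ns <- node_ns_uri(prop, nsmap)
        predicate <- paste0(pred_ns, node_local_name(prop))
        object <- xml2::xml_attr(prop, "resource")
        if (is.na(object)) {
          stop_cellsim("corrupted-rdf",
                       sprintf("property <%s> without an rdf:resource object",
                               node_local_name(prop)))
        }
        deprecated <- grepl("^urn:miriam:", object)
        if (deprecated) object <- urn_to_identifiers_uri(object)
        triples <- c(triples,
                     list(new_triple(subject, predicate, object, deprecated)))
      }
    }
  }
  sort_triples(triples)
}

sort_triples <- function(triples) {
  if (length(triples) == 0) return(triples)
  key <- vapply(triples, function(tr)
    paste(tr$subject, tr$predicate, tr$object, sep = "\r"), character(1))
  triples <- triples[order(key)]
  triples[!duplicated(key[order(key)])]
}

#' Embed a set of annotation triples in a model
#'
#' Regenerates the RDF block deterministically from the triple set (sorted
#' by subject, predicate, object; grouped by subject). With an empty set the
#' model carries no RDF block at all.
#'
#' @param model a `cellml_model`.
#' @param triples list of triples (see [extract_rdf()]).
#' @return the updated model.
#' @export
embed_rdf <- function(model, triples) {
  triples <- sort_triples(triples)
  if (length(triples) == 0) {
    model$rdf <- character(0)
    return(model)
  }
  lines <- c(sprintf("<rdf:RDF xmlns:rdf=\"%s\" xmlns:bqbiol=\"%s\" xmlns:bqmodel=\"%s\">",
                     NS_RDF, NS_BQBIOL, NS_BQMODEL))
  subjects <- unique(vapply(triples, `[[`, character(1), "subject"))
  for (s in subjects) {
    lines <- c(lines, sprintf("  <rdf:Description rdf:about=\"#%s\">",
                              xml_escape_attr(s)))
    for (tr in triples) {
      if (!identical(tr$subject, s)) next
      pred <- tr$predicate
      tag <- if (startsWith(pred, NS_BQBIOL)) {
        paste0("bqbiol:", substring(pred, nchar(NS_BQBIOL) + 1))
      } else if (startsWith(pred, NS_BQMODEL)) {
        paste0("bqmodel:", substring(pred, nchar(NS_BQMODEL) + 1))
      } else {
        stop_cellsim("vocabulary",
                     sprintf("predicate '%s' is not a biomodels.net qualifier",
                             pred))
      }
      lines <- c(lines, sprintf("    <%s rdf:resource=\"%s\"/>", tag,
                                xml_escape_attr(tr$object)))
    }
    lines <- c(lines, "  </rdf:Description>")
  }
  lines <- c(lines, "</rdf:RDF>")
  model$rdf <- paste(lines, collapse = "\n")
  model
}

# All cmeta ids present in a document, in document order.
model_cmeta_ids <- function(model) {
  ids <- c(model$cmeta_id)
  for (comp in model$components) {
    ids <- c(ids, comp$cmeta_id,
             vapply(comp$variables, `[[`, character(1), "cmeta_id"))
  }
  ids[!is.na(ids)]
}

#' Ensure an element carries a metadata id
#'
#' Mints `id_<zero-padded counter>` (skipping collisions, deterministic in
#' document order) when the addressed element has no `cmeta:id` yet.
#'
#' @param model a `cellml_model`.
#' @param component component name.
#' @param variable optional variable name within the component; when
#'   omitted the component itself is addressed.
#' @return list with the updated `model` and the element's `id`.
#' @export
ensure_cmeta_id <- function(model, component, variable = NULL) {
  comp <- model$components[[component]]
  if (is.null(comp)) {
    stop_cellsim("missing-subject",
                 sprintf("no component named '%s'", component))
  }
  current <- if (is.null(variable)) comp$cmeta_id else {
    v <- comp$variables[[variable]]
    if (is.null(v)) {
      stop_cellsim("missing-subject",
                   sprintf("no variable '%s' in component '%s'", variable,
                           component))
    }
    v$cmeta_id
  }
  if (!is.na(current)) return(list(model = model, id = current))
  taken <- model_cmeta_ids(model)
  k <- 1L
  repeat {
    id <- sprintf("id_%05d", k)
    if (!id %in% taken) break
    k <- k + 1L
  }
  if (is.null(variable)) {
    model$components[[component]]$cmeta_id <- id
  } else {
    model$components[[component]]$variables[[variable]]$cmeta_id <- id
  }
  list(model = model, id = id)
}

#' Add an annotation triple to a model
#'
#' @param model a `cellml_model`.
#' @param cmeta_id metadata id of the element being annotated; it must exist
#'   in the document (mint one first with [ensure_cmeta_id()] if needed).
#' @param qualifier a biomodels.net qualifier, as `"bio:isVersionOf"` /
#'   `"model:is"` or `c(vocabulary, term)`. Unknown terms are vocabulary
#'   errors listing the valid terms.
#' @param resource the ontology reference, as `"<collection>:<id>"`
#'   (e.g. `"chebi:CHEBI:29108"`), an identifiers.org URI, or a MIRIAM URN.
#' @return the updated model. Adding an existing triple is idempotent.
#' @export
add_annotation <- function(model, cmeta_id, qualifier, resource) {
  if (!cmeta_id %in% model_cmeta_ids(model)) {
    stop_cellsim("missing-subject",
                 sprintf("no element carries cmeta:id '%s'", cmeta_id))
  }
  q <- parse_qualifier(qualifier)
  obj <- parse_resource(resource)
  triples <- extract_rdf(model)
  triples <- c(triples, list(new_triple(cmeta_id, q$uri, obj)))
  embed_rdf(model, triples)
}

#' List annotation triples
#'
#' @param model a `cellml_model`.
#' @param cmeta_id optional subject filter.
#' @return data.frame with columns `subject`, `predicate`, `object`,
#'   `deprecated`, sorted by (subject, predicate, object).
#' @export
list_annotations <- function(model, cmeta_id = NULL) {
  triples <- extract_rdf(model)
  if (!is.null(cmeta_id)) {
    triples <- Filter(function(tr) identical(tr$subject, cmeta_id), triples)
  }
  data.frame(
    subject = vapply(triples, `[[`, character(1), "subject"),
    predicate = vapply(triples, `[[`, character(1), "predicate"),
    object = vapply(triples, `[[`, character(1), "object"),
    deprecated = vapply(triples, `[[`, logical(1), "deprecated"),
    stringsAsFactors = FALSE
  )
}
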