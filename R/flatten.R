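# CellML 1.1 import resolution: emit an equivalent standalone CellML 1.0
# model. Imported units and components are instantiated under their local
# names; transitive dependencies (units used by an imported component,
# components connected to it in the source document) are pulled in, with a
# deterministic numeric-suffix rename on collision. Annotations attached to
# imported elements travel with them, their subjects renamed consistently.

#' In-memory model locator
#'
#' Maps locator strings to document text so flattening runs with no
#' filesystem access. Resolution is deterministic within a run.
#'
#' @param texts named character vector/list: locator string -> document text.
#' @return a locator object usable with [resolve_imports()].
#' @export
memory_locator <- function(texts) {
  texts <- as.list(texts)
  list(
    key = function(href, base) href,
    resolve = function(href, base) {
      if (is.null(texts[[href]])) {
        stop_cellsim("unresolvable-href",
                     sprintf("cannot resolve import href '%s'", href))
      }
      texts[[href]]
    }
  )
}

#' Filesystem model locator
#'
#' Resolves import hrefs relative to the importing file. Remote (http/https)
#' hrefs are refused unless `allow_remote = TRUE`; even then they are not
#' fetched here -- reproducible runs use local documents.
#'
#' @param allow_remote permit http(s) hrefs (they still fail to resolve; the
#'   flag only changes the error from a policy refusal to a lookup failure).
#' @return a locator object.
#' @export
file_locator <- function(allow_remote = FALSE) {
  list(
    key = function(href, base) {
      if (grepl("^https?://", href)) {
        if (!allow_remote) {
          stop_cellsim("remote-refused",
                       sprintf("remote href '%s' refused; pass a local copy or enable remote resolution",
                               href))
        }
        return(href)
      }
      normalizePath(file.path(dirname(base), href), mustWork = FALSE)
    },
    resolve = function(href, base) {
      path <- if (grepl("^https?://", href)) {
        stop_cellsim("unresolvable-href",
                     sprintf("remote href '%s' cannot be fetched", href))
      } else {
        normalizePath(file.path(dirname(base), href), mustWork = FALSE)
      }
      if (!file.exists(path)) {
        stop_cellsim("unresolvable-href",
                     sprintf("cannot resolve import href '%s' (no file at %s)",
                             href, path))
      }
      paste(readLines(path, warn = FALSE), collapse = "\n")
    }
  )
}

#' Resolve CellML 1.1 imports into a standalone CellML 1.0 model
#'
#' @param model a `cellml_model` (1.1 with imports, or any model without).
#' @param locator a locator from [memory_locator()] or [file_locator()];
#'   may be `NULL` when the model has no imports.
#' @return a version-1.0 `cellml_model` with no imports. The rename log (old
#'   name -> new name, per document) is attached as attribute `renames`.
#' @export
resolve_imports <- function(model, locator = NULL) {
  if (length(model$imports) == 0) {
    model$version <- "1.0"
    model <- rewrite_initial_refs(model)
    return(model)
  }
  if (is.null(locator)) {
    stop_cellsim("unresolvable-href",
                 "model has imports but no locator was supplied")
  }
  flat <- flatten_doc(model, locator, stack = model$base_locator,
                      memo = new.env(parent = emptyenv()))
  flat <- rewrite_initial_refs(flat)
  flat
}

flatten_doc <- function(model, locator, stack, memo) {
  out <- model
  out$imports <- list()
  out$version <- "1.0"
  renames <- list()
  pulled_triples <- list()

  # memo of already-instantiated remote elements: key -> local name
  inst <- new.env(parent = emptyenv())

  existing_units <- function() names(out$units) %||% character(0)
  existing_comps <- function() names(out$components) %||% character(0)

  fresh_name <- function(want, existing) {
    if (!want %in% existing) return(want)
    k <- 1L
    while (sprintf("%s_%d", want, k) %in% existing) k <- k + 1L
    sprintf("%s_%d", want, k)
  }

  load_child <- function(href) {
    key <- locator$key(href, model$base_locator)
    if (key %in% stack) {
      stop_cellsim("circular-import",
                   sprintf("circular import chain: %s",
                           paste(c(stack, key), collapse = " -> ")))
    }
    cached <- memo[[key]]
    if (!is.null(cached)) return(cached)
    text <- locator$resolve(href, model$base_locator)
    child <- parse_cellml(text, base_locator = key)
    childflat <- if (length(child$imports) > 0) {
      flatten_doc(child, locator, stack = c(stack, key), memo = memo)
    } else child
    memo[[key]] <- childflat
    childflat
  }

  # Instantiate a units definition from a child document (transitively).
  inst_units <- function(childflat, href, remote, local_want = NULL) {
    key <- paste0("u|", href, "|", remote)
    if (!is.null(inst[[key]])) return(inst[[key]])
    def <- childflat$units[[remote]]
    if (is.null(def)) {
      if (remote %in% names(builtin_units_table())) return(remote)
      stop_cellsim("import-reference",
                   sprintf("imported units '%s' not found in '%s'", remote, href))
    }
    local <- fresh_name(local_want %||% remote, existing_units())
    inst[[key]] <- local # pre-register to tolerate units cycles upstream
    def2 <- def
    def2$name <- local
    def2$parts <- lapply(def$parts, function(p) {
      if (p$units %in% names(childflat$units)) {
        p$units <- inst_units(childflat, href, p$units)
      }
      p
    })
    out$units[[local]] <<- def2
    if (!identical(local, remote)) {
      renames[[length(renames) + 1]] <<- list(document = href, kind = "units",
                                              from = remote, to = local)
    }
    local
  }

  # Instantiate a component (transitively pulling its units, its connected
  # neighbours in the source document, and their connections).
  inst_component <- function(childflat, href, remote, local_want = NULL) {
    key <- paste0("c|", href, "|", remote)
    if (!is.null(inst[[key]])) return(inst[[key]])
    comp <- childflat$components[[remote]]
    if (is.null(comp)) {
      stop_cellsim("import-reference",
                   sprintf("imported component '%s' not found in '%s'",
                           remote, href))
    }
    local <- fresh_name(local_want %||% remote, existing_comps())
    inst[[key]] <- local
    comp2 <- comp
    comp2$name <- local
    umap <- list()
    comp2$variables <- lapply(comp$variables, function(v) {
      if (v$units %in% names(childflat$units)) {
        nm <- inst_units(childflat, href, v$units)
        umap[[v$units]] <<- nm
        v$units <- nm
      }
      v
    })
    names(comp2$variables) <- vapply(comp2$variables, `[[`, character(1), "name")
    comp2$equations <- lapply(comp$equations, function(eq) {
      for (u in math_cn_units(eq)) {
        if (u %in% names(childflat$units) && is.null(umap[[u]])) {
          umap[[u]] <<- inst_units(childflat, href, u)
        }
      }
      math_rewrite_cn_units(eq, umap)
    })
    out$components[[local]] <<- comp2
    if (!identical(local, remote)) {
      renames[[length(renames) + 1]] <<- list(document = href, kind = "component",
                                              from = remote, to = local)
    }
    # Annotations on the component or its variables travel with it.
    pulled_triples <<- c(pulled_triples,
                         component_triples(childflat, comp, rename_to = local))
    # Pull neighbours connected to this component in the source document.
    for (cn in childflat$connections) {
      if (!remote %in% c(cn$component_1, cn$component_2)) next
      other <- setdiff(c(cn$component_1, cn$component_2), remote)
      if (length(other) == 0) other <- remote # self-connection
      other_local <- inst_component(childflat, href, other[[1]])
      cn2 <- cn
      cn2$component_1 <- if (identical(cn$component_1, remote)) local else other_local
      cn2$component_2 <- if (identical(cn$component_2, remote)) local else other_local
      sig <- paste(cn2$component_1, cn2$component_2,
                   paste(unlist(cn2$variable_pairs), collapse = ","), sep = "|")
      have <- vapply(out$connections, function(x)
        paste(x$component_1, x$component_2,
              paste(unlist(x$variable_pairs), collapse = ","), sep = "|"),
        character(1))
      if (!sig %in% have) out$connections[[length(out$connections) + 1]] <<- cn2
    }
    local
  }

  for (imp in model$imports) {
    childflat <- load_child(imp$href)
    for (u in imp$units) {
      inst_units(childflat, imp$href, u$units_ref, local_want = u$name)
    }
    for (cp in imp$components) {
      inst_component(childflat, imp$href, cp$component_ref, local_want = cp$name)
    }
  }

  if (length(pulled_triples) > 0) {
    own <- tryCatch(extract_rdf(out), cellsim_error = function(e) NULL)
    all_triples <- unique(c(if (is.null(own)) list() else own, pulled_triples))
    out <- embed_rdf(out, all_triples)
  }
  attr(out, "renames") <- renames
  out
}

# Triples from a child document whose subject is the component or one of its
# variables (subjects follow the component rename).
component_triples <- function(childflat, comp, rename_to) {
  ids <- c(comp$cmeta_id,
           vapply(comp$variables, `[[`, character(1), "cmeta_id"))
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0) return(list())
  triples <- tryCatch(extract_rdf(childflat), cellsim_error = function(e) list())
  keep <- Filter(function(tr) tr$subject %in% ids, triples)
  # cmeta ids are unique per document and kept on the instantiated elements,
  # so subjects are stable even when the component is renamed.
  keep
}

# CellML 1.1 allows initial_value to name another variable in the same
# component; the flattened 1.0 document needs the literal.
rewrite_initial_refs <- function(model) {
  for (ci in seq_along(model$components)) {
    comp <- model$components[[ci]]
    for (vi in seq_along(comp$variables)) {
      v <- comp$variables[[vi]]
      if (is.na(v$initial_value)) next
      if (grepl("^[+-]?[0-9.]", v$initial_value)) next
      ref <- comp$variables[[v$initial_value]]
      if (is.null(ref) || is.na(ref$initial_value)) {
        stop_cellsim("import-reference",
                     sprintf("initial value of '%s' references '%s', which has no literal initial value",
                             v$name, v$initial_value), v$location)
      }
      model$components[[ci]]$variables[[vi]]$initial_value <- ref$initial_value
    }
  }
  model
}

#' Export a model as standalone CellML 1.0 text
#'
#' `serialize_cellml(resolve_imports(model, locator))`; the output parses as
#' valid CellML 1.0 and flattening is byte-idempotent.
#'
#' @inheritParams resolve_imports
#' @return character scalar of CellML 1.0 text.
#' @export
export_cellml10 <- function(model, locator = NULL) {
  serialize_cellml(resolve_imports(model, locator))
}
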