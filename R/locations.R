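# Source locations.
#
# libxml2 line information is not exposed by xml2, so locations are recovered
# from the raw text: every textual occurrence of "<tag" is indexed up front,
# and the k-th parsed element with local name "tag" (document order equals
# preorder traversal order) is assigned the k-th occurrence. The guarantee is
# that the recorded line's text contains the element's tag, which is what the
# jump-to-line diagnostics need.

index_source_locations <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  tab <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    m <- gregexpr("<([A-Za-z_][A-Za-z0-9_.:-]*)", lines[[i]])[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      tag <- substr(lines[[i]], m[k] + 1L, m[k] + lens[k] - 1L)
      tag <- sub("^.*:", "", tag)
      tab[[tag]] <- c(tab[[tag]], list(new_location(i, m[k])))
    }
  }
  idx <- new.env(parent = emptyenv())
  idx$tab <- tab
  idx$count <- new.env(parent = emptyenv())
  idx
}

next_location <- function(idx, tag) {
  if (is.null(idx)) return(new_location())
  n <- (idx$count[[tag]] %||% 0L) + 1L
  idx$count[[tag]] <- n
  occ <- idx$tab[[tag]]
  if (is.null(occ) || n > length(occ)) return(new_location())
  occ[[n]]
}

#' Remove source locations from a parsed structure
#'
#' Structural model equality (e.g. the parse/serialize round trip) is defined
#' up to source locations; this strips every `location` field recursively.
#'
#' @param x a model, expression, or any nested list.
#' @return `x` without `location` fields.
#' @export
strip_locations <- function(x) {
  if (!is.list(x)) return(x)
  x[["location"]] <- NULL
  x[["rdf_locations"]] <- NULL
  lapply(x, strip_locations)
}
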