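#' @keywords internal
"_PACKAGE"

# Classed conditions: every failure mode carries a short machine code and,
# where available, a source location, so the CLI and the validator can map
# errors back to the offending line/column.

`%||%` <- function(a, b) if (is.null(a)) b else a

cellsim_error <- function(code, message, location = NULL, data = list()) {
  structure(
    class = c(paste0("cellsim_", gsub("-", "_", code)),
              "cellsim_error", "error", "condition"),
    list(message = message, call = NULL, code = code,
         location = location, data = data)
  )
}

stop_cellsim <- function(code, message, location = NULL, data = list()) {
  stop(cellsim_error(code, message, location, data))
}

is_cellsim_error <- function(e, code = NULL) {
  inherits(e, "cellsim_error") && (is.null(code) || identical(e$code, code))
}

new_location <- function(line = 1L, column = 1L) {
  list(line = as.integer(line), column = as.integer(column))
}

# A ValidationIssue: severity in {error, warning}, short machine code,
# human-readable message, and a source location.
new_issue <- function(severity, code, message, location = NULL) {
  list(severity = severity, code = code, message = message,
       location = location %||% new_location())
}

sort_issues <- function(issues) {
  if (length(issues) == 0) return(issues)
  ln <- vapply(issues, function(i) i$location$line, integer(1))
  cl <- vapply(issues, function(i) i$location$column, integer(1))
  issues[order(ln, cl)]
}

#' Format validation issues as diagnostic text
#'
#' One issue per line, in the stable form
#' `<severity>:<line>:<column>: [<code>] <message>`.
#'
#' @param issues list of issues as returned by [validate_cellml()].
#' @return character vector, one element per issue.
#' @export
format_issues <- function(issues) {
  vapply(issues, function(i) {
    sprintf("%s:%d:%d: [%s] %s", i$severity, i$location$line,
            i$location$column, i$code, i$message)
  }, character(1))
}

issue_codes <- function(issues) {
  vapply(issues, function(i) i$code, character(1))
}
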