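# Data store: uniform VOI grid plus one tracked series per model parameter
# (constants, computed constants, states, rates, algebraic), with naming,
# units, and category metadata. Exporters are pluggable; CSV ships.

new_datastore <- function(voi, data, meta, voi_label, voi_units) {
  stopifnot(nrow(data) == length(voi), ncol(data) == nrow(meta))
  structure(list(voi = voi, data = data, meta = meta,
                 voi_label = voi_label, voi_units = voi_units),
            class = "cellsim_datastore")
}

#' Labels of tracked parameters in a data store
#'
#' @param store a `cellsim_datastore`.
#' @return character vector of canonical `component/name` labels, in the
#'   stored (category-then-name) column order.
#' @export
ds_labels <- function(store) store$meta$label

#' Extract a tracked series by label
#'
#' Any parameter can be plotted against any other; this is the extraction
#' primitive behind that.
#'
#' @param store a `cellsim_datastore`.
#' @param label canonical `component/name` label (the VOI label is allowed).
#' @return numeric vector over the grid.
#' @export
ds_series <- function(store, label) {
  if (identical(label, store$voi_label)) return(store$voi)
  j <- match(label, store$meta$label)
  if (is.na(j)) {
    stop_cellsim("unknown-parameter",
                 sprintf("no tracked parameter '%s'; known: %s", label,
                         paste(store$meta$label, collapse = ", ")))
  }
  store$data[, j]
}

#' @export
print.cellsim_datastore <- function(x, ...) {
  cat(sprintf("<cellsim_datastore> %d point(s) x %d parameter(s) (+VOI '%s')\n",
              length(x$voi), ncol(x$data), x$voi_label))
  invisible(x)
}

ds_column_label <- function(label, units) sprintf("%s (%s)", label, units)

# Full round-trip precision: 17 significant digits, always scientific.
fmt_series_num <- function(x) sprintf("%.16e", x)

csv_writer <- function(store, path) {
  header <- c(ds_column_label(store$voi_label, store$voi_units),
              mapply(ds_column_label, store$meta$label, store$meta$units,
                     USE.NAMES = FALSE))
  body <- cbind(fmt_series_num(store$voi),
                matrix(fmt_series_num(store$data), nrow = length(store$voi)))
  lines <- c(paste(header, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  write_atomically(path, paste0(paste(lines, collapse = "\n"), "\n"))
  invisible(NULL)
}

write_atomically <- function(path, text) {
  dir <- dirname(path)
  tmp <- tempfile(tmpdir = if (nzchar(dir)) dir else ".", fileext = ".tmp")
  con <- file(tmp, open = "wb")
  writeBin(charToRaw(text), con)
  close(con)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' The default data-store exporter registry
#'
#' Ships exactly one exporter, `"csv"`: header row; first column the VOI as
#' `component/name (units)`; remaining columns every tracked parameter in
#' category-then-name order with the same labeling; one data row per grid
#' point; numbers in full round-trip precision scientific notation; `\n`
#' line endings.
#'
#' @return an `exporter_registry`.
#' @export
default_exporter_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$writers <- list(csv = csv_writer)
  structure(list(env = reg), class = "exporter_registry")
}

#' Register a data-store exporter
#'
#' @param registry an `exporter_registry`.
#' @param name new exporter name (must not be taken).
#' @param writer function `(store, path)` writing the store to `path`.
#' @return the registry, invisibly (registration mutates it).
#' @export
register_exporter <- function(registry, name, writer) {
  stopifnot(inherits(registry, "exporter_registry"), is.function(writer))
  if (name %in% names(registry$env$writers)) {
    stop_cellsim("duplicate-exporter",
                 sprintf("an exporter named '%s' is already registered", name))
  }
  registry$env$writers[[name]] <- writer
  registry$env$writers <- registry$env$writers[order(names(registry$env$writers))]
  invisible(registry)
}

#' Names of registered exporters
#'
#' @param registry an `exporter_registry`.
#' @return sorted character vector.
#' @export
exporter_names <- function(registry = default_exporter_registry()) {
  sort(names(registry$env$writers))
}

#' Export a data store
#'
#' @param store a `cellsim_datastore`.
#' @param exporter registered exporter name (`"csv"` ships).
#' @param destination output file path (written atomically).
#' @param registry an `exporter_registry`.
#' @return `NULL`, invisibly.
#' @export
export_datastore <- function(store, exporter = "csv", destination,
                             registry = default_exporter_registry()) {
  w <- registry$env$writers[[exporter]]
  if (is.null(w)) {
    stop_cellsim("unknown-exporter",
                 sprintf("no exporter named '%s'; registered: %s", exporter,
                         paste(exporter_names(registry), collapse = ", ")))
  }
  w(store, destination)
  invisible(NULL)
}

#' Read a CSV data store back
#'
#' Inverse of the shipped CSV exporter (used for round-trip checks).
#'
#' @param path CSV file written by [export_datastore()].
#' @return list with `voi`, `data` (matrix), and `labels` (header fields).
#' @export
read_datastore_csv <- function(path) {
  lines <- readLines(path)
  labels <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  vals <- lapply(lines[-1], function(l)
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1]]))
  m <- do.call(rbind, vals)
  list(voi = m[, 1], data = m[, -1, drop = FALSE], labels = labels)
}
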