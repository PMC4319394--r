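# Plugin registry: the modularity backbone. Features register as in-package
# descriptors with a category, selectability, CLI capability, and
# dependencies; "loading" means activating a registration. Non-selectable
# plugins load only when a selected plugin (transitively) needs them.

#' Create a plugin descriptor
#'
#' @param name unique plugin name.
#' @param category one of `api`, `editing`, `simulation`, `solver`,
#'   `data-store`, `miscellaneous`, `organisation`.
#' @param selectable can the user select it directly?
#' @param cli_capable does it contribute CLI commands?
#' @param dependencies names of plugins it needs.
#' @return a `plugin_descriptor`.
#' @export
plugin_descriptor <- function(name, category = "miscellaneous",
                              selectable = TRUE, cli_capable = FALSE,
                              dependencies = character(0)) {
  category <- match.arg(category, c("api", "editing", "simulation", "solver",
                                    "data-store", "miscellaneous",
                                    "organisation"))
  structure(list(name = name, category = category, selectable = selectable,
                 cli_capable = cli_capable,
                 dependencies = as.character(dependencies)),
            class = "plugin_descriptor")
}

#' The shipped plugin descriptors
#'
#' Mirrors the package's feature set: a core, the CellML support layer, the
#' CellML tools (the only CLI-capable plugin, providing the exports), the
#' editing/annotation views, the simulation view, solver plugins, and the
#' data-store layer with its CSV exporter.
#'
#' @return named list of `plugin_descriptor`s.
#' @export
shipped_plugin_descriptors <- function() {
  ds <- list(
    plugin_descriptor("core", "miscellaneous", selectable = FALSE),
    plugin_descriptor("cellml_support", "api", selectable = FALSE,
                      dependencies = "core"),
    plugin_descriptor("cellml_tools", "miscellaneous", selectable = TRUE,
                      cli_capable = TRUE, dependencies = "cellml_support"),
    plugin_descriptor("annotation_view", "editing", selectable = TRUE,
                      dependencies = "cellml_support"),
    plugin_descriptor("raw_cellml_view", "editing", selectable = TRUE,
                      dependencies = "cellml_support"),
    plugin_descriptor("solvers_core", "solver", selectable = FALSE,
                      dependencies = "core"),
    plugin_descriptor("ode_solvers", "solver", selectable = TRUE,
                      dependencies = "solvers_core"),
    plugin_descriptor("dae_solver", "solver", selectable = TRUE,
                      dependencies = c("solvers_core", "nla_solver")),
    plugin_descriptor("nla_solver", "solver", selectable = TRUE,
                      dependencies = "solvers_core"),
    plugin_descriptor("data_store_core", "data-store", selectable = FALSE,
                      dependencies = "core"),
    plugin_descriptor("csv_data_store", "data-store", selectable = TRUE,
                      dependencies = "data_store_core"),
    plugin_descriptor("single_cell_view", "simulation", selectable = TRUE,
                      dependencies = c("cellml_support", "solvers_core",
                                       "data_store_core"))
  )
  names(ds) <- vapply(ds, `[[`, character(1), "name")
  ds
}

#' Resolve plugin selection into a load order and statuses
#'
#' Selected plugins and their transitive dependencies load in topological
#' order (dependencies first); the always-on `core` loads regardless.
#' Disabled plugins are `unloadable`; plugins whose (transitive)
#' dependencies are missing or unloadable are `missing-dependency`;
#' resolvable plugins that are not needed stay `not-loaded`.
#'
#' @param descriptors named list of `plugin_descriptor`s.
#' @param selected names of selected plugins.
#' @param disabled names of plugins withheld from loading.
#' @return list with `load_order` (character vector) and `status` (named
#'   character vector over all descriptors).
#' @export
resolve_plugins <- function(descriptors = shipped_plugin_descriptors(),
                            selected = character(0),
                            disabled = character(0)) {
  for (s in c(selected, disabled)) {
    if (!s %in% names(descriptors)) {
      stop_cellsim("unknown-plugin", sprintf("no plugin named '%s'", s))
    }
  }
  edges <- character(0)
  for (d in descriptors) {
    for (dep in d$dependencies) {
      if (!dep %in% names(descriptors)) {
        stop_cellsim("unknown-plugin",
                     sprintf("plugin '%s' depends on unknown plugin '%s'",
                             d$name, dep))
      }
      edges <- c(edges, dep, d$name)
    }
  }
  g <- igraph::make_graph(edges,
                          isolates = setdiff(names(descriptors), edges),
                          directed = TRUE)
  scc <- igraph::components(g, mode = "strong")
  if (any(scc$csize > 1)) {
    cyc <- names(scc$membership)[scc$membership == which(scc$csize > 1)[1]]
    stop_cellsim("dependency-cycle",
                 sprintf("plugin dependency cycle: %s",
                         paste(sort(cyc), collapse = " -> ")))
  }

  status <- stats::setNames(rep("not-loaded", length(descriptors)),
                            names(descriptors))
  status[disabled] <- "unloadable"

  # transitive closure of requested plugins
  want <- unique(c("core", selected))
  repeat {
    more <- unique(unlist(lapply(want, function(n)
      descriptors[[n]]$dependencies)))
    new <- setdiff(more, want)
    if (length(new) == 0) break
    want <- c(want, new)
  }

  # propagate unloadable dependencies
  loadable <- function(n, seen = character(0)) {
    if (identical(status[[n]], "unloadable")) return(FALSE)
    deps <- descriptors[[n]]$dependencies
    all(vapply(deps, function(d) loadable(d, c(seen, n)), logical(1)))
  }
  order_all <- names(igraph::topo_sort(g, mode = "out"))
  load_order <- character(0)
  for (n in order_all) {
    if (!n %in% want) next
    if (identical(status[[n]], "unloadable")) next
    if (loadable(n)) {
      status[[n]] <- "loaded"
      load_order <- c(load_order, n)
    } else {
      status[[n]] <- "missing-dependency"
    }
  }
  list(load_order = load_order, status = status)
}

#' CLI-capable plugin listing
#'
#' @param descriptors named list of `plugin_descriptor`s.
#' @return character vector of lines, name-sorted: `name (category)`.
#' @export
cli_plugins <- function(descriptors = shipped_plugin_descriptors()) {
  caps <- Filter(function(d) isTRUE(d$cli_capable), descriptors)
  caps <- caps[order(names(caps))]
  vapply(caps, function(d) sprintf("%s (%s)", d$name, d$category),
         character(1), USE.NAMES = FALSE)
}

#' Status lines for all plugins
#'
#' @param descriptors named list of `plugin_descriptor`s.
#' @param selected,disabled forwarded to [resolve_plugins()].
#' @return character vector, one name-sorted line per descriptor:
#'   `name: status`.
#' @export
cli_status <- function(descriptors = shipped_plugin_descriptors(),
                       selected = names(Filter(function(d) d$selectable,
                                               descriptors)),
                       disabled = character(0)) {
  res <- resolve_plugins(descriptors, selected, disabled)
  nm <- sort(names(res$status))
  vapply(nm, function(n) sprintf("%s: %s", n, res$status[[n]]),
         character(1), USE.NAMES = FALSE)
}
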