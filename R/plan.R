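# Equation ordering.
#
# Each equation is rewritten into assignment form when one side is a bare
# variable or derivative; a dependency graph over the resulting steps is
# built; strongly connected components of size > 1, and equations that are
# not rewritable to assignment form, become nonlinear-algebraic (NLA)
# blocks; the topological order of the condensation gives the plan.

#' Order a model's equations into an executable plan
#'
#' @param model a flattened `cellml_model`.
#' @param classification result of [classify_variables()]; computed when
#'   omitted.
#' @return a `cellml_plan`: a list of steps, each either
#'   `list(kind = "assign", target, expr, component, phase)` or
#'   `list(kind = "nla", equations, unknowns, phase)`, in evaluation order.
#'   Phases are `computed_constants`, `rates` or `algebraic`.
#' @export
order_equations <- function(model, classification = classify_variables(model)) {
  cls <- classification
  eqs <- cls$equations
  n <- length(eqs)
  canon <- cls$canon

  # assignment targets; redefinition check
  targets <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    t <- cls$target_of[[i]]
    if (is.null(t)) next
    targets[i] <- if (identical(t$type, "rate")) paste0("rate:", t$key) else t$key
  }
  tt <- targets[!is.na(targets)]
  if (anyDuplicated(tt)) {
    stop_cellsim("redefinition",
                 sprintf("variable %s is defined by more than one equation",
                         sub("^rate:", "d/dt of ", tt[duplicated(tt)][[1]])))
  }

  # references per equation (canonical keys; a derivative reference counts
  # as a reference to "rate:<state>")
  refs <- vector("list", n)
  for (i in seq_len(n)) {
    e <- eqs[[i]]
    r <- vapply(math_ci_names(e$expr), function(nm) canon(e$component, nm),
                character(1))
    dr <- vapply(math_diff_refs(e$expr),
                 function(d) paste0("rate:", canon(e$component, d$var)),
                 character(1))
    refs[[i]] <- setdiff(unique(c(r, dr)), c(targets[i], cls$voi))
  }

  defined_by_assign <- tt
  is_known <- function(key) {
    if (startsWith(key, "rate:")) return(key %in% defined_by_assign)
    key %in% defined_by_assign ||
      cls$category[[key]] %in% c("constant", "state", "variable_of_integration")
  }

  # seed NLA blocks from non-assignment equations grouped by shared unknowns
  nla_idx <- which(is.na(targets))
  nla_unknowns <- lapply(nla_idx, function(i) Filter(Negate(is_known), refs[[i]]))
  blocks <- list()
  if (length(nla_idx) > 0) {
    bid <- seq_along(nla_idx)
    repeat {
      changed <- FALSE
      for (a in seq_along(nla_idx)) for (b in seq_along(nla_idx)) {
        if (bid[a] != bid[b] &&
            length(intersect(nla_unknowns[[a]], nla_unknowns[[b]])) > 0) {
          bid[bid == max(bid[a], bid[b])] <- min(bid[a], bid[b])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (gix in unique(bid)) {
      sel <- which(bid == gix)
      unknowns <- sort(unique(unlist(nla_unknowns[sel])))
      if (length(sel) != length(unknowns)) {
        stop_cellsim("structural-singularity",
                     sprintf("nonlinear-algebraic block has %d equation(s) but %d unknown(s): %s",
                             length(sel), length(unknowns),
                             paste(unknowns, collapse = ", ")))
      }
      blocks <- c(blocks, list(list(eq_idx = nla_idx[sel], unknowns = unknowns)))
    }
  }

  assign_idx <- which(!is.na(targets))

  # Build the condensation graph; fold assignment-only cycles into NLA
  # blocks until the graph is acyclic.
  repeat {
    node_ids <- c(if (length(assign_idx)) paste0("eq", assign_idx),
                  if (length(blocks)) paste0("blk", seq_along(blocks)))
    defines <- c(as.list(targets[assign_idx]),
                 lapply(blocks, function(b) b$unknowns))
    needs <- c(
      lapply(assign_idx, function(i) refs[[i]]),
      lapply(blocks, function(b)
        unique(setdiff(unlist(refs[b$eq_idx]), b$unknowns)))
    )
    def_of <- list()
    for (j in seq_along(node_ids)) {
      for (d in defines[[j]]) def_of[[d]] <- node_ids[[j]]
    }
    edges <- character(0)
    for (j in seq_along(node_ids)) {
      for (r in needs[[j]]) {
        src <- def_of[[r]]
        if (!is.null(src) && !identical(src, node_ids[[j]])) {
          edges <- c(edges, src, node_ids[[j]])
        }
      }
    }
    g <- igraph::make_graph(edges, isolates = setdiff(node_ids, edges),
                            directed = TRUE)
    scc <- igraph::components(g, mode = "strong")
    if (all(scc$csize == 1)) break
    ci <- which(scc$csize > 1)[1]
    members <- names(scc$membership)[scc$membership == ci]
    if (any(startsWith(members, "blk"))) {
      stop_cellsim("structural-singularity",
                   "cyclic coupling between an algebraic block and assignments")
    }
    eq_is <- as.integer(sub("^eq", "", members))
    unknowns <- sort(unique(targets[eq_is]))
    if (any(startsWith(unknowns, "rate:"))) {
      stop_cellsim("structural-singularity",
                   "differential equations form an algebraic cycle")
    }
    blocks <- c(blocks, list(list(eq_idx = eq_is, unknowns = unknowns)))
    assign_idx <- setdiff(assign_idx, eq_is)
  }

  order_ids <- names(igraph::topo_sort(g, mode = "out"))

  steps <- list()
  for (id in order_ids) {
    if (startsWith(id, "eq")) {
      i <- as.integer(sub("^eq", "", id))
      e <- eqs[[i]]
      tgt <- cls$target_of[[i]]
      expr <- if (isTRUE(side_matches_target(e$expr$lhs, tgt))) e$expr$rhs
              else e$expr$lhs
      phase <- if (identical(tgt$type, "rate")) "rates"
        else switch(cls$category[[tgt$key]],
                    computed_constant = "computed_constants",
                    "algebraic")
      steps <- c(steps, list(list(kind = "assign", target = tgt, expr = expr,
                                  component = e$component, phase = phase,
                                  eq_index = i)))
    } else {
      b <- blocks[[as.integer(sub("^blk", "", id))]]
      steps <- c(steps, list(list(
        kind = "nla",
        equations = lapply(b$eq_idx, function(i) eqs[[i]]),
        unknowns = b$unknowns, phase = "algebraic")))
    }
  }
  structure(list(steps = steps, classification = cls), class = "cellml_plan")
}

side_matches_target <- function(side, tgt) {
  if (identical(tgt$type, "var")) {
    return(identical(side$kind, "ci") && identical(side$name, tgt$name))
  }
  identical(side$kind, "diff") && identical(side$var, tgt$name)
}

#' @export
print.cellml_plan <- function(x, ...) {
  n_nla <- sum(vapply(x$steps, function(s) identical(s$kind, "nla"), logical(1)))
  cat(sprintf("<cellml_plan> %d step(s), %d NLA block(s)\n",
              length(x$steps), n_nla))
  invisible(x)
}
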