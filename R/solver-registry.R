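# Solver registry: pluggable descriptors with per-solver customizable
# properties. Solvers are made available by type (ODE, DAE, NLA) to the
# simulation layer.

#' Create a solver descriptor
#'
#' @param name unique solver name.
#' @param solver_type `"ODE"`, `"DAE"` or `"NLA"`.
#' @param properties named list; each entry
#'   `list(type =, default =, range = c(lo, hi))`.
#' @return a `solver_descriptor`.
#' @export
solver_descriptor <- function(name, solver_type, properties = list()) {
  solver_type <- match.arg(solver_type, c("ODE", "DAE", "NLA"))
  for (p in properties) stopifnot(!is.null(p$default))
  structure(list(name = name, solver_type = solver_type,
                 properties = properties),
            class = "solver_descriptor")
}

prop_num <- function(default, lo = 0, hi = Inf) {
  list(type = "numeric", default = default, range = c(lo, hi))
}

#' The default solver registry
#'
#' ODE: `euler`, `heun`, `rk2` (midpoint), `rk4` (classic) and `adaptive`
#' (variable-step stiff-capable, tolerance-controlled). DAE: `backward_euler`
#' (implicit, paired with the NLA solver). NLA: `newton` (damped, with
#' finite-difference Jacobian).
#'
#' @return a `solver_registry`.
#' @export
default_solver_registry <- function() {
  step_props <- list(step = prop_num(NA_real_, 0, Inf))
  reg <- list(
    solver_descriptor("euler", "ODE", step_props),
    solver_descriptor("heun", "ODE", step_props),
    solver_descriptor("rk2", "ODE", step_props),
    solver_descriptor("rk4", "ODE", step_props),
    solver_descriptor("adaptive", "ODE", list(
      reltol = prop_num(1e-7, 0, 1),
      abstol = prop_num(1e-9, 0, Inf),
      max_step = prop_num(Inf, 0, Inf),
      max_steps = prop_num(50000, 1, Inf)
    )),
    solver_descriptor("backward_euler", "DAE", c(step_props, list(
      tol = prop_num(1e-12, 0, 1)
    ))),
    solver_descriptor("newton", "NLA", list(
      tol = prop_num(1e-12, 0, 1),
      max_iterations = prop_num(100, 1, 1e6)
    ))
  )
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  structure(list(solvers = reg), class = "solver_registry")
}

#' List registered solvers
#'
#' @param registry a `solver_registry`.
#' @param solver_type optional filter (`"ODE"`, `"DAE"`, `"NLA"`).
#' @return name-sorted list of `solver_descriptor`s.
#' @export
list_solvers <- function(registry = default_solver_registry(),
                         solver_type = NULL) {
  out <- registry$solvers
  if (!is.null(solver_type)) {
    out <- Filter(function(d) identical(d$solver_type, solver_type), out)
  }
  if (length(out) == 0) return(list())
  out[order(names(out))]
}

get_solver <- function(registry, name) {
  d <- registry$solvers[[name]]
  if (is.null(d)) {
    stop_cellsim("unknown-solver",
                 sprintf("no solver named '%s'; available: %s", name,
                         paste(sort(names(registry$solvers)), collapse = ", ")))
  }
  d
}

# Merge user properties into descriptor defaults; unknown keys are errors
# listing the valid keys.
solver_properties <- function(descriptor, props = list()) {
  out <- lapply(descriptor$properties, `[[`, "default")
  for (k in names(props)) {
    if (!k %in% names(out)) {
      stop_cellsim("unknown-solver-property",
                   sprintf("solver '%s' has no property '%s'; valid keys: %s",
                           descriptor$name, k,
                           paste(sort(names(out)), collapse = ", ")))
    }
    v <- as.numeric(props[[k]])
    rg <- descriptor$properties[[k]]$range
    if (is.finite(v) && (v < rg[1] || v > rg[2])) {
      stop_cellsim("bad-solver-property",
                   sprintf("property '%s' = %g outside valid range [%g, %g]",
                           k, v, rg[1], rg[2]))
    }
    out[[k]] <- v
  }
  out
}
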