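# Simulation orchestration: grid construction from start/end/point interval,
# solver dispatch, pause-modify-resume, and all-parameter capture into a
# data store.
#
# Grid points are computed as start + i*interval (index multiplication, no
# accumulation drift); the final point is `end` whenever (end-start)/interval
# is integral within 1e-9 relative tolerance, else the last grid point below
# `end`. Every model parameter is always tracked; a memory cap (counts x
# points x 8 bytes) raises a capacity error before the run starts.

#' Define a simulation setup
#'
#' @param start,end simulation window in VOI units (`end > start`).
#' @param point_interval recording interval (> 0, at most `end - start`).
#' @param ode_solver registered ODE/DAE solver name.
#' @param ode_props named list of solver properties (e.g. `step` for the
#'   fixed-step methods, `reltol`/`abstol` for the adaptive one).
#' @param nla_solver registered NLA solver name.
#' @param nla_props properties for the NLA solver.
#' @param memory_cap data-store capacity bound in bytes (default 1 GiB).
#' @return a `simulation_setup`.
#' @export
simulation_setup <- function(start, end, point_interval,
                             ode_solver = "rk4", ode_props = list(),
                             nla_solver = "newton", nla_props = list(),
                             memory_cap = 2^30) {
  if (!(end > start)) stop_cellsim("bad-setup", "end must exceed start")
  if (!(point_interval > 0)) {
    stop_cellsim("bad-setup", "point interval must be positive")
  }
  if (point_interval > (end - start) + 1e-12 * abs(end - start)) {
    stop_cellsim("bad-setup",
                 "point interval must not exceed the simulation window")
  }
  structure(list(start = start, end = end, point_interval = point_interval,
                 ode_solver = ode_solver, ode_props = ode_props,
                 nla_solver = nla_solver, nla_props = nla_props,
                 memory_cap = memory_cap),
            class = "simulation_setup")
}

# start + i*interval; last index chosen so the end point is hit when the
# ratio is integral within 1e-9 relative tolerance.
sim_grid <- function(setup) {
  r <- (setup$end - setup$start) / setup$point_interval
  n <- floor(r + 1e-9 * max(1, abs(r)))
  setup$start + (0:n) * setup$point_interval
}

#' Create a simulation session
#'
#' A session owns its state (solver position, warm starts, data store);
#' several sessions over the same runtime can be advanced in any
#' interleaving and share nothing mutable.
#'
#' @param runtime a `cellml_runtime`.
#' @param setup a `simulation_setup`.
#' @param registry a `solver_registry`.
#' @return a `simulation_session` (advance with [advance_session()], read
#'   with [session_store()]).
#' @export
simulation_session <- function(runtime, setup,
                               registry = default_solver_registry()) {
  stopifnot(inherits(runtime, "cellml_runtime"),
            inherits(setup, "simulation_setup"))
  ode_desc <- get_solver(registry, setup$ode_solver)
  if (identical(ode_desc$solver_type, "NLA")) {
    stop_cellsim("unknown-solver",
                 sprintf("'%s' is an NLA solver; an ODE or DAE solver is required",
                         setup$ode_solver))
  }
  ode_props <- solver_properties(ode_desc, setup$ode_props)
  nla_desc <- get_solver(registry, setup$nla_solver)
  nla_props <- solver_properties(nla_desc, setup$nla_props)

  grid <- sim_grid(setup)
  n_par <- nrow(runtime$meta)
  need <- (n_par + 1) * length(grid) * 8
  if (need > setup$memory_cap) {
    stop_cellsim("capacity",
                 sprintf("simulation needs %d bytes of data-store capacity but the cap is %d",
                         need, setup$memory_cap))
  }

  s <- new.env(parent = emptyenv())
  s$runtime <- runtime
  s$setup <- setup
  s$grid <- grid
  s$state <- "ready"
  s$pos <- 0L                        # grid points recorded so far
  s$data <- matrix(NA_real_, nrow = length(grid), ncol = n_par)
  s$nla <- runtime$new_nla_env()
  s$nla$tol <- nla_props$tol
  s$nla$max_iterations <- as.integer(nla_props$max_iterations)
  s$ode_name <- ode_desc$name
  s$ode_props <- ode_props
  s$pending <- list()                # grid index -> named modifications
  init <- runtime$initialise()
  s$constants <- runtime$compute_computed_constants(init$constants)
  s$states <- init$states
  class(s) <- "simulation_session"
  s
}

# Apply pause-time modifications: constants and states only. Changing a
# constant re-derives the computed constants so stored data stay
# self-consistent.
apply_modifications <- function(s, mods) {
  meta <- s$runtime$meta
  touched_const <- FALSE
  for (label in names(mods)) {
    j <- match(label, meta$label)
    if (is.na(j)) {
      stop_cellsim("unknown-parameter",
                   sprintf("no model parameter '%s'", label))
    }
    cat0 <- meta$category[j]
    if (identical(cat0, "constant")) {
      s$constants[meta$index[j]] <- as.numeric(mods[[label]])
      touched_const <- TRUE
    } else if (identical(cat0, "state")) {
      s$states[meta$index[j]] <- as.numeric(mods[[label]])
    } else {
      stop_cellsim("category",
                   sprintf("parameter '%s' is a %s and cannot be modified mid-run",
                           label, gsub("_", " ", cat0)))
    }
  }
  if (touched_const) {
    s$constants <- s$runtime$compute_computed_constants(s$constants)
  }
  invisible(s)
}

record_point <- function(s, i) {
  rt <- s$runtime
  voi <- s$grid[i]
  ra <- rt$compute_rates(voi, s$states, s$constants, s$nla)
  alg <- rt$compute_algebraic(voi, s$states, ra$rates, s$constants, s$nla)
  meta <- rt$meta
  row <- numeric(nrow(meta))
  for (j in seq_len(nrow(meta))) {
    row[j] <- switch(meta$category[j],
      constant = , computed_constant = s$constants[meta$index[j]],
      state = s$states[meta$index[j]],
      rate = ra$rates[meta$index[j]],
      algebraic = alg[meta$index[j]]
    )
  }
  s$data[i, ] <- row
  invisible(s)
}

rate_fn <- function(s) {
  rt <- s$runtime
  constants <- s$constants
  nla <- s$nla
  function(t, y) rt$compute_rates(t, y, constants, nla)$rates
}

dae_residual_fn <- function(s) {
  f <- rate_fn(s)
  function(t, y, yp) yp - f(t, y)
}

step_interval <- function(s, i) {
  # advance states across [grid[i], grid[i+1]]
  t0 <- s$grid[i]; t1 <- s$grid[i + 1]
  interval <- t1 - t0
  h_prop <- s$ode_props$step
  nsub <- if (!is.na(h_prop) && h_prop > 0 && h_prop < interval) {
    as.integer(ceiling(interval / h_prop - 1e-9))
  } else 1L
  h <- interval / nsub
  if (identical(s$ode_name, "backward_euler")) {
    Fres <- dae_residual_fn(s)
    for (k in seq_len(nsub)) {
      s$states <- implicit_step(Fres, t0 + (k - 1) * h, s$states, h,
                                tol = s$ode_props$tol)
    }
  } else {
    f <- rate_fn(s)
    for (k in seq_len(nsub)) {
      s$states <- fixed_step(s$ode_name, f, t0 + (k - 1) * h, s$states, h)
    }
  }
  invisible(s)
}

#' Advance a session
#'
#' Records grid points (applying any pending pause-point modifications
#' before a point is recorded) and integrates the intervals between them.
#'
#' @param session a `simulation_session`.
#' @param to_index grid index (1-based) to advance through; defaults to the
#'   full grid.
#' @return the session, invisibly.
#' @export
advance_session <- function(session, to_index = length(session$grid)) {
  s <- session
  to_index <- min(to_index, length(s$grid))
  if (s$pos >= to_index) return(invisible(s))
  s$state <- "running"
  if (identical(s$ode_name, "adaptive")) {
    advance_adaptive(s, to_index)
  } else {
    while (s$pos < to_index) {
      i <- s$pos + 1L
      mods <- s$pending[[as.character(i)]]
      if (!is.null(mods)) apply_modifications(s, mods)
      record_point(s, i)
      s$pos <- i
      # step eagerly so a later resume finds the states at the next grid
      # point; the final grid point is never stepped past
      if (i < length(s$grid)) step_interval(s, i)
    }
  }
  s$state <- if (s$pos >= length(s$grid)) "done" else "paused"
  invisible(s)
}

# The adaptive path integrates in stretches between modification points and
# queries the trajectory at grid points. An interval leading into a pause
# point is integrated with the pre-modification values, matching the
# fixed-step semantics (modifications apply before the paused point is
# recorded).
advance_adaptive <- function(s, to_index) {
  while (s$pos < to_index) {
    i <- s$pos + 1L
    if (i == 1L) {
      mods <- s$pending[["1"]]
      if (!is.null(mods)) apply_modifications(s, mods)
      record_point(s, 1L)
      s$pos <- 1L
      next
    }
    # next stretch: from the point the states sit at (grid[i-1]) up to the
    # nearest pending-modification index, or to_index
    pend_idx <- suppressWarnings(as.integer(names(s$pending)))
    pend_idx <- pend_idx[!is.na(pend_idx) & pend_idx >= i & pend_idx <= to_index]
    bound <- if (length(pend_idx) > 0) min(pend_idx) else to_index
    traj <- adaptive_integrate(
      rate_fn(s), t0 = s$grid[i - 1L], y0 = s$states, t_end = s$grid[bound],
      reltol = s$ode_props$reltol, abstol = s$ode_props$abstol,
      max_step = s$ode_props$max_step,
      max_steps = as.integer(s$ode_props$max_steps))
    ys <- traj$at(s$grid[i:bound])
    for (k in seq_len(bound - i + 1L)) {
      idx <- i + k - 1L
      s$states <- ys[k, ]
      mods <- s$pending[[as.character(idx)]]
      if (!is.null(mods)) apply_modifications(s, mods)
      record_point(s, idx)
    }
    s$pos <- bound
  }
  invisible(s)
}

#' Data store of a session
#'
#' @param session a `simulation_session` (advanced to completion or not;
#'   the store holds the recorded prefix).
#' @return a `cellsim_datastore`.
#' @export
session_store <- function(session) {
  s <- session
  upto <- seq_len(s$pos)
  new_datastore(s$grid[upto], s$data[upto, , drop = FALSE], s$runtime$meta,
                voi_label = s$runtime$voi_label,
                voi_units = s$runtime$voi_units)
}

#' Run a simulation
#'
#' Initialises constants and states, computes the computed constants once,
#' then records every tracked parameter at every grid point. Fixed-step
#' solvers take `ceil(point_interval / step)` internal substeps per interval
#' when a finer internal `step` property is configured, else one step per
#' interval; the adaptive solver is queried at the grid points.
#'
#' @param runtime a `cellml_runtime`.
#' @param setup a `simulation_setup`.
#' @param registry a `solver_registry`.
#' @return a `cellsim_datastore`.
#' @export
run_simulation <- function(runtime, setup,
                           registry = default_solver_registry()) {
  s <- simulation_session(runtime, setup, registry)
  advance_session(s)
  session_store(s)
}

#' Run a simulation with pause-modify-resume segments
#'
#' Integrates to each pause point (snapped to the nearest grid point at or
#' after the requested value), applies the modifications (constants and
#' states only; modifying a computed parameter is a category error), and
#' resumes. Modifications are applied before the paused point is recorded,
#' so stored data are always self-consistent.
#'
#' @param runtime a `cellml_runtime`.
#' @param setup a `simulation_setup`.
#' @param segments list of `list(pause_at =, modifications = named list)`,
#'   pause points strictly increasing inside `(start, end)`.
#' @param registry a `solver_registry`.
#' @return a `cellsim_datastore`.
#' @export
run_segments <- function(runtime, setup, segments = list(),
                         registry = default_solver_registry()) {
  s <- simulation_session(runtime, setup, registry)
  last <- -Inf
  for (seg in segments) {
    if (!(seg$pause_at > last)) {
      stop_cellsim("bad-setup", "pause points must be strictly increasing")
    }
    if (seg$pause_at <= setup$start || seg$pause_at >= setup$end) {
      stop_cellsim("bad-setup", "pause points must lie inside (start, end)")
    }
    last <- seg$pause_at
    idx <- match(TRUE, s$grid >= seg$pause_at - 1e-9 * max(1, abs(seg$pause_at)))
    # validate modification categories up front
    meta <- runtime$meta
    for (label in names(seg$modifications)) {
      j <- match(label, meta$label)
      if (!is.na(j) && !meta$category[j] %in% c("constant", "state")) {
        stop_cellsim("category",
                     sprintf("parameter '%s' is a %s and cannot be modified mid-run",
                             label, gsub("_", " ", meta$category[j])))
      }
    }
    s$pending[[as.character(idx)]] <- seg$modifications
  }
  advance_session(s)
  session_store(s)
}

#' @export
print.simulation_session <- function(x, ...) {
  cat(sprintf("<simulation_session> %s at %d/%d point(s)\n",
              x$state, x$pos, length(x$grid)))
  invisible(x)
}
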