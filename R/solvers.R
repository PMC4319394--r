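# Numerical solvers.
#
# Fixed-step one-step methods (forward Euler, Heun, midpoint RK2, classic
# RK4), an adaptive stiff-capable integrator delegating to deSolve (lsoda),
# a damped Newton solver with forward-difference Jacobian for
# nonlinear-algebraic systems, and a backward-Euler implicit step built on
# it for semi-explicit index-1 problems.

#' One fixed step of an explicit ODE method
#'
#' * `euler`: y + h f(t, y)
#' * `heun`: y + (h/2)\[f(t, y) + f(t + h, y + h f(t, y))\]
#' * `rk2` (midpoint): y + h f(t + h/2, y + (h/2) f(t, y))
#' * `rk4` (classic): y + (h/6)(k1 + 2 k2 + 2 k3 + k4)
#'
#' @param method one of `"euler"`, `"heun"`, `"rk2"`, `"rk4"`.
#' @param f rate evaluator `f(t, y)` returning a numeric vector.
#' @param t,y current time and state vector.
#' @param h step size (> 0).
#' @return the state vector after one step.
#' @export
fixed_step <- function(method, f, t, y, h) {
  stopifnot(h > 0)
  check <- function(v, at) {
    if (any(!is.finite(v))) {
      stop_cellsim("numeric",
                   sprintf("non-finite rate evaluation at t = %.17g", at),
                   data = list(t = at))
    }
    v
  }
  switch(match.arg(method, c("euler", "heun", "rk2", "rk4")),
    euler = {
      y + h * check(f(t, y), t)
    },
    heun = {
      k1 <- check(f(t, y), t)
      k2 <- check(f(t + h, y + h * k1), t + h)
      y + (h / 2) * (k1 + k2)
    },
    rk2 = {
      k1 <- check(f(t, y), t)
      y + h * check(f(t + h / 2, y + (h / 2) * k1), t + h / 2)
    },
    rk4 = {
      k1 <- check(f(t, y), t)
      k2 <- check(f(t + h / 2, y + h * k1 / 2), t + h / 2)
      k3 <- check(f(t + h / 2, y + h * k2 / 2), t + h / 2)
      k4 <- check(f(t + h, y + h * k3), t + h)
      y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  )
}

#' Adaptive stiff-capable integration
#'
#' Variable-step integration with dense output, delegating to
#' [deSolve::ode()] (lsoda, which switches between Adams and BDF). The
#' returned trajectory is queried at arbitrary points of `[t0, t_end]`
#' through interpolated output rather than forcing integrator steps onto
#' the grid.
#'
#' @param f rate evaluator `f(t, y)`.
#' @param t0,y0 initial time and state.
#' @param t_end final time (>= t0).
#' @param reltol,abstol relative/absolute tolerances (> 0).
#' @param max_step largest internal step (default unrestricted).
#' @param max_steps maximum number of internal steps per output interval.
#' @return a `cellsim_trajectory`: call `$at(times)` for a matrix of states
#'   (rows = times, in `[t0, t_end]`).
#' @export
adaptive_integrate <- function(f, t0, y0, t_end, reltol = 1e-7,
                               abstol = 1e-9, max_step = Inf,
                               max_steps = 50000L) {
  stopifnot(reltol > 0, abstol > 0, t_end >= t0)
  at <- function(times) {
    stopifnot(all(times >= t0 - 1e-12), all(times <= t_end + 1e-12))
    if (isTRUE(all.equal(t_end, t0)) || length(times) == 0 ||
        all(abs(times - t0) < 1e-300)) {
      out <- matrix(rep(y0, each = length(times)), nrow = length(times))
      return(out)
    }
    tt <- c(t0, times[times > t0])
    sol <- tryCatch(
      suppressWarnings(deSolve::ode(
        y = y0, times = tt,
        func = function(t, y, parms) list(f(t, y)),
        method = "lsoda", rtol = reltol, atol = abstol,
        hmax = if (is.finite(max_step)) max_step else NULL,
        maxsteps = max_steps
      )),
      error = function(e) {
        stop_cellsim("integration",
                     sprintf("adaptive integration failed: %s",
                             conditionMessage(e)))
      }
    )
    got <- as.matrix(sol)
    if (nrow(got) < length(tt) || any(!is.finite(got))) {
      bad <- if (nrow(got) > 0) max(got[, 1][is.finite(got[, 1])]) else t0
      stop_cellsim("integration",
                   sprintf("adaptive integration failed near t = %.17g (tolerance failure or step-size collapse)",
                           bad),
                   data = list(t = bad))
    }
    states <- got[, -1, drop = FALSE]
    out <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
    past <- times > t0
    out[!past, ] <- matrix(rep(y0, each = sum(!past)), nrow = sum(!past))
    if (any(past)) out[past, ] <- states[-1, , drop = FALSE]
    out
  }
  structure(list(at = at, t0 = t0, t_end = t_end, y0 = y0),
            class = "cellsim_trajectory")
}

#' Damped Newton solver for nonlinear-algebraic systems
#'
#' Forward-difference Jacobian (perturbation `sqrt(eps) * max(|x_i|, 1)`),
#' halving line search (at most 10 halvings), success when the residual's
#' max-norm drops below `tol`.
#'
#' @param residual vector residual function.
#' @param guess starting vector (same length as the residual).
#' @param tol max-norm convergence tolerance.
#' @param max_iterations Newton iteration cap.
#' @return the solution vector.
#' @export
newton_solve <- function(residual, guess, tol = 1e-10, max_iterations = 50L) {
  x <- as.numeric(guess)
  n <- length(x)
  r <- residual(x)
  if (length(r) != n) {
    stop_cellsim("dimension",
                 sprintf("residual has length %d but guess has length %d",
                         length(r), n))
  }
  if (any(!is.finite(r))) {
    stop_cellsim("numeric", "non-finite residual at the initial guess")
  }
  nrm <- function(v) max(abs(v))
  if (nrm(r) < tol) return(x)
  sqeps <- sqrt(.Machine$double.eps)
  for (iter in seq_len(max_iterations)) {
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      dx <- sqeps * max(abs(x[j]), 1)
      xp <- x; xp[j] <- xp[j] + dx
      J[, j] <- (residual(xp) - r) / dx
    }
    step <- tryCatch(solve(J, -r), error = function(e) {
      stop_cellsim("singular-jacobian",
                   sprintf("singular Jacobian in Newton iteration %d", iter))
    })
    lambda <- 1
    improved <- FALSE
    for (half in 0:10) {
      xn <- x + lambda * step
      rn <- residual(xn)
      if (all(is.finite(rn)) && nrm(rn) < nrm(r)) {
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      # accept the full step once; quadratic convergence near the root can
      # stall the norm test in the last ulps
      xn <- x + step
      rn <- residual(xn)
      if (any(!is.finite(rn))) {
        stop_cellsim("non-convergence",
                     sprintf("Newton line search failed; last residual max-norm %.3e",
                             nrm(r)))
      }
    }
    x <- xn; r <- rn
    if (nrm(r) < tol) return(x)
  }
  stop_cellsim("non-convergence",
               sprintf("Newton did not converge in %d iterations; last residual max-norm %.3e",
                       max_iterations, nrm(r)))
}

#' One backward-Euler step for a residual-form (DAE-style) system
#'
#' Solves `F(t + h, y_next, (y_next - y)/h) = 0` with [newton_solve()],
#' starting from the current state. Intended for semi-explicit index-1
#' systems (every implicit block's unknowns are algebraic).
#'
#' @param F residual over `(t, y, yprime)`.
#' @param t,y current time and state.
#' @param h step size (> 0).
#' @param nla the nonlinear solver (signature of [newton_solve()]).
#' @param tol,max_iterations passed to the solver.
#' @return the state vector at `t + h`.
#' @export
implicit_step <- function(F, t, y, h, nla = newton_solve, tol = 1e-12,
                          max_iterations = 50L) {
  stopifnot(h > 0)
  res <- function(z) F(t + h, z, (z - y) / h)
  nla(res, y, tol = tol, max_iterations = max_iterations)
}
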