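# Numerical solvers: steppers, adaptive integration, Newton, implicit step.

test_that("one step of each fixed method matches the hand computation on y' = -y", {
  f <- function(t, y) -y
  expect_equal(fixed_step("euler", f, 0, 1, 0.1), 0.9, tolerance = 1e-15)
  expect_equal(fixed_step("heun", f, 0, 1, 0.1), 0.905, tolerance = 1e-15)
  expect_equal(fixed_step("rk2", f, 0, 1, 0.1), 0.905, tolerance = 1e-15)
  # k1..k4 = -1, -0.95, -0.9525, -0.90475
  expect_equal(fixed_step("rk4", f, 0, 1, 0.1), 0.9048375, tolerance = 1e-15)
})

test_that("heun and rk2 coincide for linear rate functions", {
  f <- function(t, y) -2.5 * y + 0.3
  for (h in c(0.1, 0.01)) {
    expect_equal(fixed_step("heun", f, 0, 1.7, h),
                 fixed_step("rk2", f, 0, 1.7, h), tolerance = 1e-15)
  }
})

test_that("fixed-step methods and newton_solve are bitwise deterministic", {
  f <- function(t, y) sin(y) - 0.3 * y
  for (m in c("euler", "heun", "rk2", "rk4")) {
    expect_identical(fixed_step(m, f, 0.2, c(1.1, -0.4), 0.05),
                     fixed_step(m, f, 0.2, c(1.1, -0.4), 0.05))
  }
  r <- function(x) c(x[1]^2 - 2, x[1] * x[2] - 1)
  expect_identical(newton_solve(r, c(2, 2)), newton_solve(r, c(2, 2)))
})

test_that("observed convergence orders on the decay problem are as designed", {
  err_at1 <- function(method, h) {
    f <- function(t, y) -y
    y <- 10; t <- 0
    for (k in seq_len(round(1 / h))) {
      y <- fixed_step(method, f, t, y, h)
      t <- t + h
    }
    abs(y - 10 * exp(-1))
  }
  p <- function(method) log2(err_at1(method, 0.01) / err_at1(method, 0.005))
  expect_gt(p("euler"), 0.8); expect_lt(p("euler"), 1.2)
  expect_gt(p("heun"), 1.8); expect_lt(p("heun"), 2.2)
  expect_gt(p("rk2"), 1.8); expect_lt(p("rk2"), 2.2)
  expect_gt(p("rk4"), 3.7); expect_lt(p("rk4"), 4.3)
})

test_that("a non-finite rate evaluation is a numeric error carrying t", {
  f <- function(t, y) if (t > 0.5) NaN else -y
  err <- expect_cellsim_error(fixed_step("euler", f, 0.6, 1, 0.1), "numeric")
  expect_false(is.null(err$data$t))
})

test_that("adaptive integration matches the closed form on decay", {
  f <- function(t, y) -y
  traj <- adaptive_integrate(f, 0, 10, 1, reltol = 1e-8, abstol = 1e-10)
  y1 <- traj$at(1)[1, 1]
  expect_lt(abs(y1 - 10 * exp(-1)), 1e-6)
})

test_that("a zero-length adaptive window yields the single initial point", {
  traj <- adaptive_integrate(function(t, y) -y, 2, c(3, 4), 2)
  out <- traj$at(2)
  expect_equal(out[1, ], c(3, 4))
})

test_that("finite-time blow-up raises an integration error, not a silent NaN", {
  traj <- adaptive_integrate(function(t, y) y^2, 0, 1, 2, reltol = 1e-8,
                             abstol = 1e-10)
  expect_cellsim_error(traj$at(c(0.5, 1.5, 2)), "integration")
})

test_that("newton_solve converges quadratically on x^2 - 4 and in one step on linear systems", {
  calls <- 0
  r <- function(x) { calls <<- calls + 1; x^2 - 4 }
  x <- newton_solve(r, 3, tol = 1e-10, max_iterations = 8)
  expect_equal(x, 2, tolerance = 1e-10)

  iter_counting <- local({
    n <- 0
    function(x) { n <<- n + 1; x - 5 }
  })
  expect_equal(newton_solve(function(x) x - 5, 0), 5, tolerance = 1e-14)

  # the 2x2 linear NLA system (x + y - 3, x - y - 1) from the zero guess
  sol <- newton_solve(function(u) c(u[1] + u[2] - 3, u[1] - u[2] - 1),
                      c(0, 0))
  expect_equal(sol, c(2, 1), tolerance = 1e-12)
})

test_that("newton_solve reports singular Jacobians and non-convergence", {
  expect_cellsim_error(newton_solve(function(x) c(x[1] + x[2], x[1] + x[2]),
                                    c(1, 2)), "singular-jacobian")
  err <- expect_cellsim_error(
    newton_solve(function(x) x^2 + 1, 0.5, max_iterations = 5),
    "non-convergence")
  expect_match(conditionMessage(err), "residual")
})

test_that("backward-Euler implicit step solves decay exactly as y/(1+h) and is first order", {
  Fres <- function(t, y, yp) yp + y
  expect_equal(implicit_step(Fres, 0, 1, 0.1), 1 / 1.1, tolerance = 1e-12)
  be_err <- function(h) {
    y <- 1; t <- 0
    for (k in seq_len(round(1 / h))) {
      y <- implicit_step(Fres, t, y, h)
      t <- t + h
    }
    abs(y - exp(-1))
  }
  p <- log2(be_err(0.01) / be_err(0.005))
  expect_gt(p, 0.8); expect_lt(p, 1.2)
})

test_that("a non-finite residual at the guess is a numeric error", {
  expect_cellsim_error(
    implicit_step(function(t, y, yp) NaN * y, 0, 1, 0.1), "numeric")
})

test_that("the default registry lists its solvers by type, name-sorted", {
  reg <- default_solver_registry()
  ode <- list_solvers(reg, "ODE")
  expect_length(ode, 5)
  expect_identical(names(ode), sort(names(ode)))
  nla <- list_solvers(reg, "NLA")
  expect_length(nla, 1)
  expect_identical(nla[[1]]$name, "newton")
  expect_length(list_solvers(structure(list(solvers = list()),
                                       class = "solver_registry")), 0)
})

test_that("unknown solver properties are rejected listing the valid keys", {
  reg <- default_solver_registry()
  err <- expect_cellsim_error(
    cellsim:::solver_properties(reg$solvers$rk4, list(banana = 1)),
    "unknown-solver-property")
  expect_match(conditionMessage(err), "step")
})
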