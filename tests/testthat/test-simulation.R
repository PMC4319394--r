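# Simulation orchestration: grids, data stores, sessions, exporters.

test_that("start=0, end=10, interval=0.1 gives 101 points and an exact index grid", {
  rt <- decay_runtime()
  setup <- simulation_setup(0, 10, 0.1)
  store <- run_simulation(rt, setup)
  expect_length(store$voi, 101)
  expect_lte(abs(store$voi[length(store$voi)] - 10),
             4 * .Machine$double.eps * 10)
  expect_equal(store$voi, 0 + (0:100) * 0.1)
})

test_that("end = start + interval yields the minimal 2-point grid", {
  rt <- decay_runtime()
  store <- run_simulation(rt, simulation_setup(0, 0.1, 0.1))
  expect_length(store$voi, 2)
})

test_that("rk4 with substeps matches the closed form 10*exp(-10) at t = 10", {
  rt <- decay_runtime()
  store <- run_simulation(rt, simulation_setup(0, 10, 0.1, ode_solver = "rk4",
                                               ode_props = list(step = 0.01)))
  y <- ds_series(store, "main/y")
  expect_lt(abs(y[length(y)] - 10 * exp(-10)), 1e-6)
  # the rate series is the recomputed derivative
  a <- ds_series(store, "main/a")
  expect_equal(ds_series(store, "main/y'"), -a * y, tolerance = 1e-14)
})

test_that("adaptive and finely-stepped rk4 agree on the FHN voltage to 1e-4", {
  rt <- build_runtime(parse_cellml(make_fhn()))
  s_ad <- run_simulation(rt, simulation_setup(0, 2, 0.1, ode_solver = "adaptive",
                                              ode_props = list(reltol = 1e-8,
                                                               abstol = 1e-10)))
  s_rk <- run_simulation(rt, simulation_setup(0, 2, 0.1, ode_solver = "rk4",
                                              ode_props = list(step = 1e-4)))
  dv <- max(abs(ds_series(s_ad, "main/v") - ds_series(s_rk, "main/v")))
  expect_lt(dv, 1e-4)
})

test_that("the backward-Euler DAE path integrates the NLA fixture: x=2, y=1, z=z0+2t", {
  rt <- build_runtime(parse_cellml(make_nla()))
  store <- run_simulation(rt, simulation_setup(0, 2, 0.1,
                                               ode_solver = "backward_euler"))
  expect_lt(max(abs(ds_series(store, "main/x") - 2)), 1e-10)
  expect_lt(max(abs(ds_series(store, "main/y") - 1)), 1e-10)
  expect_lt(max(abs(ds_series(store, "main/z") - (1 + 2 * store$voi))), 1e-8)
})

test_that("the conservation probe stays within solver-order bounds of its initial sum", {
  rt <- build_runtime(parse_cellml(make_conservation_model()))
  store <- run_simulation(rt, simulation_setup(0, 10, 0.1, ode_solver = "rk4"))
  total <- ds_series(store, "main/y1") + ds_series(store, "main/y2")
  expect_lt(max(abs(total - total[1])), 1e-10)
})

test_that("pausing to zero the decay rate freezes the state thereafter", {
  rt <- decay_runtime()
  setup <- simulation_setup(0, 10, 0.1)
  store <- run_segments(rt, setup, segments = list(
    list(pause_at = 5, modifications = list("main/a" = 0))))
  y <- ds_series(store, "main/y")
  after <- store$voi >= 5 - 1e-12
  expect_lt(max(abs(y[after] - y[which(after)[1]])), 1e-12)
  expect_lt(max(abs(ds_series(store, "main/a")[after])), 1e-15)
  # before the pause the run is untouched
  plain <- run_simulation(rt, setup)
  expect_identical(y[store$voi < 5], ds_series(plain, "main/y")[plain$voi < 5])
})

test_that("an empty segments list reproduces run_simulation exactly", {
  rt <- decay_runtime()
  setup <- simulation_setup(0, 3, 0.1)
  expect_identical(run_segments(rt, setup, list())$data,
                   run_simulation(rt, setup)$data)
})

test_that("modifying a computed parameter is a category error naming its category", {
  rt <- decay_runtime()
  setup <- simulation_setup(0, 3, 0.1)
  err <- expect_cellsim_error(
    run_segments(rt, setup, list(list(pause_at = 1,
                                      modifications = list("main/y'" = 0)))),
    "category")
  expect_match(conditionMessage(err), "rate")
})

test_that("the CSV export matches its contract and round-trips exactly", {
  rt <- decay_runtime()
  store <- run_simulation(rt, simulation_setup(0, 10, 0.1))
  path <- tempfile(fileext = ".csv")
  export_datastore(store, "csv", path)
  lines <- readLines(path)
  expect_length(lines, 102)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  # 1 VOI + 1 constant + 1 state + 1 rate; no computed/algebraic in decay
  expect_length(header, 4)
  expect_identical(header[1], "main/time (second)")
  expect_true("main/y (dimensionless)" %in% header)
  expect_true("main/a (per_second)" %in% header)
  back <- read_datastore_csv(path)
  expect_identical(back$voi, store$voi)
  expect_identical(unname(back$data), unname(store$data))
})

test_that("exporter registry: shipped csv, registration, duplicates, unknown names", {
  reg <- default_exporter_registry()
  expect_identical(exporter_names(reg), "csv")
  register_exporter(reg, "tsv", function(store, path) {
    writeLines("tsv", path)
  })
  expect_identical(exporter_names(reg), c("csv", "tsv"))
  expect_cellsim_error(register_exporter(reg, "csv", function(s, p) NULL),
                       "duplicate-exporter")
  err <- expect_cellsim_error(
    export_datastore(run_simulation(decay_runtime(),
                                    simulation_setup(0, 0.2, 0.1)),
                     "bogus", tempfile()),
    "unknown-exporter")
  expect_match(conditionMessage(err), "csv")
})

test_that("interleaved sessions equal sequential runs bitwise (shared-nothing sessions)", {
  rt <- decay_runtime()
  setup <- simulation_setup(0, 5, 0.1)
  a <- simulation_session(rt, setup)
  b <- simulation_session(rt, setup)
  n <- length(a$grid)
  cut <- c(10, 25, 33, n)
  for (k in cut) {
    advance_session(a, k)
    advance_session(b, k)
  }
  seq_store <- run_simulation(rt, setup)
  expect_identical(session_store(a)$data, seq_store$data)
  expect_identical(session_store(b)$data, seq_store$data)
})

test_that("the capacity cap raises before the run starts", {
  rt <- decay_runtime()
  expect_cellsim_error(
    run_simulation(rt, simulation_setup(0, 10, 0.1, memory_cap = 100)),
    "capacity")
})

test_that("setup invariants are enforced", {
  expect_cellsim_error(simulation_setup(1, 1, 0.1), "bad-setup")
  expect_cellsim_error(simulation_setup(0, 1, 0), "bad-setup")
  expect_cellsim_error(simulation_setup(0, 1, 2), "bad-setup")
})
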