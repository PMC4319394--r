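# Helpers for executing emitted python source against the host interpreter.

run_python_module <- function(src, driver_lines) {
  dir <- tempfile("pygen"); dir.create(dir)
  writeLines(src, file.path(dir, "genmod.py"))
  writeLines(driver_lines, file.path(dir, "driver.py"))
  out <- system2("python", file.path(dir, "driver.py"), stdout = TRUE)
  unlink(dir, recursive = TRUE)
  out
}

# Evaluate the emitted python evaluators at given points; returns one
# numeric vector c(rates, algebraic) per point.
python_eval_points <- function(src, points, n_states, n_const) {
  fmt_vec <- function(v) paste0("[", paste(sprintf("%.17g", v), collapse = ","), "]")
  driver <- c("import genmod as g")
  for (p in points) {
    driver <- c(driver, sprintf(
      "r, alg = g.compute_rates(%.17g, %s, %s)", p$voi, fmt_vec(p$states),
      fmt_vec(p$constants)))
    driver <- c(driver, sprintf(
      "a2 = g.compute_algebraic(%.17g, %s, r, %s)", p$voi, fmt_vec(p$states),
      fmt_vec(p$constants)))
    driver <- c(driver,
                "print(' '.join('%.17g' % v for v in list(r) + list(a2)))")
  }
  out <- run_python_module(src, driver)
  lapply(out, function(l) as.numeric(strsplit(l, " ", fixed = TRUE)[[1]]))
}
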