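test_that("packaged constants carry the measured values and censoring", {
  ps <- default_parameter_set()
  expect_equal(get_constant(ps, "C:M")$kd, 4.6)
  expect_equal(get_constant(ps, "R:H")$kd, 30)
  expect_equal(get_constant(ps, "M:H")$kd, 4)
  expect_equal(get_constant(ps, "PHD3:H")$kd, 51)
  expect_equal(get_constant(ps, "CM:H")$kd, 70)
  expect_equal(get_constant(ps, "CMda:H")$kd, 24)
  expect_equal(get_constant(ps, "C:R")$kd, 300)
  expect_equal(get_constant(ps, "C_WLF:R")$kd, 70)
  expect_equal(get_constant(ps, "C_K83A:R")$kd, 1800)
  expect_equal(get_constant(ps, "C_RK:R")$kd, 2000)
  krk <- get_constant(ps, "C_KRK:R")
  expect_true(krk$censored)
  expect_equal(krk$kd, 10000)
  expect_equal(ps$kon_default, 10)
})

test_that("rate pairs realise the dissociation constant and refuse censoring", {
  bc <- binding_constant(c("C", "M"), 4.6)
  r <- rates_for(bc, 10)
  expect_equal(r$koff, 46)
  expect_equal(rates_for(binding_constant(c("C", "R"), 300), 10)$koff, 3000)
  # koff/kon reproduces kd to machine precision for every usable constant
  ps <- default_parameter_set()
  for (bc in ps$constants) {
    if (bc$censored) next
    r <- rates_for(bc, ps$kon_default)
    expect_identical(r$koff / r$kon, bc$kd)
  }
  expect_error(rates_for(get_constant(ps, "C_KRK:R"), 10), "censored")
  expect_error(binding_constant(c("A", "B"), 0), "positive")
})

test_that("cycle closure fixes the ternary assembly edge by detailed balance", {
  expect_equal(close_cycle(4.6, 70, 4), 80.5)
  expect_equal(close_cycle(7, 42, 42), 7)
  expect_equal(close_cycle(4.6, 70, 70), 4.6)
  expect_error(close_cycle(-1, 70, 4), "positive")

  ps <- default_parameter_set()
  derived <- get_constant(ps, "C:MH")
  expect_true(derived$derived)
  expect_equal(derived$kd, 80.5)
  # product of equilibrium constants around the M/MH/CM/CMH cycle is 1
  prod_K <- (1 / 4) * (1 / 80.5) * 70 * 4.6
  expect_equal(prod_K, 1, tolerance = 1e-9)
  expect_error(set_constant(ps, "C:MH", 50), "detailed balance")
})

test_that("parameter sets round-trip losslessly through YAML", {
  ps <- default_parameter_set()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_set(ps, path)
  expect_equal(read_parameter_set(path), ps)
  # the packaged default file matches the in-code defaults
  packaged <- system.file("extdata", "binding_constants.yaml",
                          package = "cyp33switch")
  expect_equal(read_parameter_set(packaged), ps)
})

test_that("set_constant re-derives the cycle and validates the pair", {
  ps <- set_constant(default_parameter_set(), "CM:H", 24)
  expect_equal(get_constant(ps, "C:MH")$kd, close_cycle(4.6, 24, 4))
  expect_error(set_constant(default_parameter_set(), "X:Y", 1), "missing")
  expect_error(parameter_set(list(binding_constant(c("A", "B"), 1),
                                  binding_constant(c("A", "B"), 2))),
               "duplicate")
})
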