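test_that("the default network has the expected reactions and bookkeeping", {
  net <- default_net
  expect_length(net$reactions, 6)
  expect_length(net$species, 9)
  expect_setequal(net$monomers, c("M", "H", "C", "R"))
  # conservation group for H: one copy in each of H, MH, CMH, RH
  h <- net$conservation[["H"]]
  expect_equal(sort(names(h[h > 0])), c("CMH", "H", "MH", "RH"))
  expect_true(all(h[h > 0] == 1))
  # stoichiometry orthogonal to every conservation vector
  for (m in net$monomers)
    expect_equal(max(abs(net$conservation[[m]] %*% net$stoich)), 0)

  ps <- default_parameter_set()
  ps$constants[["R:H"]] <- NULL
  expect_error(build_network(parameter_set(unname(ps$constants))),
               "missing constant R:H")
})

test_that("mass-action derivatives behave at limits and conserve monomers", {
  net <- default_net
  zero <- setNames(rep(0, 9), net$species)
  expect_equal(ode_rhs(net, zero), zero)

  st <- zero; st[c("M", "H")] <- 1
  dx <- ode_rhs(net, st)
  expect_equal(dx[["MH"]], 10)  # kon * [M][H] = 10 * 1 * 1
  expect_equal(dx[["M"]], -10)

  set.seed(11)
  for (i in 1:10) {
    st <- setNames(runif(9, 0, 50), net$species)
    dx <- ode_rhs(net, st)
    for (m in net$monomers)
      expect_equal(sum(net$conservation[[m]] * dx), 0, tolerance = 1e-10)
  }
  st <- zero; st[["M"]] <- -1
  expect_error(ode_rhs(net, st), "negative")
})

test_that("closed-form bound fraction matches its quadratic and kinetics", {
  expect_equal(bound_fraction_1to1(100, 0, 4), 0)
  expect_equal(bound_fraction_1to1(10, 20, 1e-6), 1, tolerance = 1e-6)
  # frozen value: quadratic at P = L = 100 uM, Kd = 4 uM
  expect_equal(bound_fraction_1to1(100, 100, 4), 0.8190025, tolerance = 1e-6)
  expect_equal(100 * bound_fraction_1to1(100, 100, 4),
               oracle_complex_1to1(100, 100, 4), tolerance = 1e-9)
  # independent brute-force relaxation of the two-species ODE
  expect_equal(100 * bound_fraction_1to1(100, 100, 4),
               oracle_relax_1to1(100, 100, 4), tolerance = 1e-6)
})

test_that("equilibrate solves the competitive equilibrium algebraically", {
  net <- default_net
  eq <- equilibrate(net, c(M = 100, H = 100))
  expect_equal(eq[["MH"]], 100 * bound_fraction_1to1(100, 100, 4),
               tolerance = 1e-9)
  expect_equal(max(abs(equilibrate(net, c(M = 0, H = 0, C = 0, R = 0)))), 0)

  eq <- equilibrate(net, c(M = 100, H = 100, C = 100, R = 100))
  # conservation honoured
  for (m in net$monomers)
    expect_equal(sum(net$conservation[[m]] * eq), 100, tolerance = 1e-6 * 100)
  # detailed balance: net flux of every reaction vanishes
  flux <- sapply(net$reactions, function(rx)
    rx$kon * prod(eq[rx$reactants]) - rx$koff * eq[[rx$product]])
  expect_lt(max(abs(flux)), 1e-9)

  expect_error(equilibrate(net, c(M = -1)), "non-negative")
  expect_error(equilibrate(net, c(Z = 1)), "unknown")
})

test_that("equilibrate agrees with long-time ODE integration", {
  net <- default_net
  set.seed(42)
  for (i in 1:3) {
    totals <- setNames(runif(4, 10, 200), net$monomers)
    eq <- equilibrate(net, totals)
    y0 <- setNames(rep(0, 9), net$species)
    y0[net$monomers] <- totals
    out <- integrate_network(net, y0, times = c(0, 1e4))
    expect_lt(max(abs(out[2, net$species] - eq[net$species])), 1e-4)
  }
})

test_that("two-species subnetworks match the closed form for any pair", {
  net <- default_net
  set.seed(7)
  for (i in 1:8) {
    p <- runif(1, 1, 500); l <- runif(1, 1, 500)
    eq <- equilibrate(net, c(M = p, H = l))
    expect_equal(eq[["MH"]], p * bound_fraction_1to1(p, l, 4),
                 tolerance = 1e-9)
    eq <- equilibrate(net, c(C = p, R = l))
    expect_equal(eq[["CR"]], p * bound_fraction_1to1(p, l, 300),
                 tolerance = 1e-9)
  }
})

test_that("bound fractions are invariant under joint scaling of totals and Kd", {
  ps <- default_parameter_set()
  net <- build_network(ps)
  totals <- c(M = 100, H = 100, C = 100, R = 100)
  eq1 <- equilibrate(net, totals)

  lambda <- 3.7
  scaled <- ps
  for (id in names(scaled$constants))
    scaled <- set_constant(scaled, id, scaled$constants[[id]]$kd * lambda)
  eq2 <- equilibrate(build_network(scaled), totals * lambda)
  expect_equal(eq2[net$species] / lambda, eq1[net$species],
               tolerance = 1e-8)
})

test_that("integration never lets species dip below tolerance", {
  net <- default_net
  y0 <- setNames(rep(0, 9), net$species)
  y0[net$monomers] <- c(100, 100, 100, 100)
  out <- integrate_network(net, y0, times = seq(0, 100, by = 0.5))
  expect_gt(min(out[, net$species]), -1e-9)
})
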