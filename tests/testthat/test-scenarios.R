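# The pulse scenario is the expensive fixture; build it (and its trajectory)
# once per test run.
pulse_scen <- transcription_pulse_scenario(default_ps)
pulse_traj <- simulate_scenario(default_net, pulse_scen)

test_that("the transcription pulse has the documented timing and calibration", {
  expect_equal(sapply(pulse_scen$events, `[[`, "t_s"), c(336, 1320))
  expect_true(pulse_scen$pre_equilibrate)
  expect_equal(pulse_scen$initial_totals, c(M = 100, H = 100))

  # initial partition: the two-species quadratic at M = H = 100, Kd = 4
  p0 <- partition_at(pulse_traj, 0)
  expect_equal(p0$active, 81.90025, tolerance = 1e-4)

  # synthesis calibrated so each pulsed total peaks at 100 uM (within 5%)
  expect_equal(max(monomer_total(pulse_traj, "R")), 100, tolerance = 0.05)
  expect_equal(max(monomer_total(pulse_traj, "C")), 100, tolerance = 0.05)
  # M and H totals are untouched by the pulse machinery
  expect_equal(range(monomer_total(pulse_traj, "M")), c(100, 100),
               tolerance = 1e-5)
  expect_equal(range(monomer_total(pulse_traj, "H")), c(100, 100),
               tolerance = 1e-5)
})

test_that("the pulse tips the system repressive and then relaxes back", {
  plateau <- partition_at(pulse_traj, 1320)
  expect_gt(plateau$repressive, plateau$active)

  # long after switch-off the system returns to the pre-trigger equilibrium
  base <- equilibrate(default_net, c(M = 100, H = 100))
  final <- state_at(pulse_traj, max(pulse_traj$time_s))
  expect_lt(max(abs(final - base[default_net$species])), 1)
})

test_that("classification partitions the H pool exactly", {
  net <- default_net
  st <- setNames(rep(0, 9), net$species)
  st[c("MH", "H")] <- c(81.9, 18.1)
  p <- classify_state(st, net)
  expect_equal(p$active, 81.9)
  expect_equal(p$repressive, 18.1)

  st <- setNames(rep(0, 9), net$species)
  p <- classify_state(st, net)
  expect_equal(unlist(p), c(active = 0, repressive = 0, other = 0))

  st[c("CMH", "RH", "H")] <- c(10, 5, 5)
  p <- classify_state(st, net)
  expect_equal(p$active, 10)
  expect_equal(p$repressive, 10)

  expect_error(classify_state(st, net, list(active = "MH",
                                            repressive = c("H", "RH"))),
               "not assigned")

  # along the whole trajectory: active + repressive + other = total H
  htot <- monomer_total(pulse_traj, "H")
  expect_equal(pulse_traj$active_uM + pulse_traj$repressive_uM +
                 pulse_traj$other_uM, htot, tolerance = 1e-6)
})

test_that("single-component pulses do not tip the balance; both do more than either", {
  ctl <- control_scenarios(default_ps)
  parts <- lapply(ctl, function(s)
    partition_at(simulate_scenario(default_net, s, dt = 5), 1320))
  expect_gte(parts$rna_only$active, parts$rna_only$repressive)
  expect_gte(parts$cyp33_only$active, parts$cyp33_only$repressive)
  expect_gt(parts$both$repressive, parts$rna_only$repressive)
  expect_gt(parts$both$repressive, parts$cyp33_only$repressive)
})

test_that("scenario validation rejects malformed event lists", {
  expect_error(scenario(c(M = 1), list(list(t_s = 10), list(t_s = 5))),
               "increasing")
  expect_error(scenario(c(M = 1), list(list(t_s = 5,
                                            synthesis = list(R = -1)))),
               "non-negative")
  expect_error(simulate_scenario(default_net,
                                 scenario(c(Z = 1), t_end = 10)),
               "not in network")
  empty <- simulate_scenario(default_net,
                             scenario(c(M = 0, H = 0), t_end = 10), dt = 5)
  expect_equal(max(abs(as.matrix(empty[, default_net$species]))), 0)
})

test_that("synthesis and decay modify totals exactly as prescribed", {
  # during the pulse: d(total R)/dt = ksyn - kdeg * [R_free]
  ksyn <- unlist(pulse_scen$events[[1]]$synthesis)
  i <- which(pulse_traj$time_s >= 400 & pulse_traj$time_s <= 1200)
  rtot <- monomer_total(pulse_traj, "R")
  drdt <- diff(rtot[i]) / diff(pulse_traj$time_s[i])
  mid <- (pulse_traj$R[i][-1] + pulse_traj$R[i][-length(i)]) / 2
  expect_equal(drdt, ksyn[["R"]] - 0.005 * mid, tolerance = 1e-3)
})

test_that("equilibrium scans rebuild the network and refuse the derived edge", {
  totals <- c(M = 100, H = 100, C = 100, R = 100)
  tab <- scan_kd(default_ps, "R:H", c(30, 100, 500, 1e9), totals)
  expect_equal(nrow(tab), 4)
  # repressive fraction decreases monotonically as the RNA-H affinity weakens
  expect_true(all(diff(tab$repressive_fraction) < 0))
  # in the no-binding limit RNA acts purely as a Cyp33 sink
  ps_sink <- set_constant(default_ps, "R:H", 1e9)
  expect_equal(tab$repressive_uM[4],
               classify_state(equilibrate(build_network(ps_sink), totals),
                              build_network(ps_sink))$repressive,
               tolerance = 1e-6)
  expect_error(scan_kd(default_ps, "C:MH", 50, totals), "detailed balance")
})
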