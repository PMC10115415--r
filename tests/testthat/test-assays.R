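test_that("fast-exchange shifts interpolate between the limiting states", {
  expect_equal(predict_shift(50, 0, 300, 3.15, 3.12), 3.15)
  # trace protein, ligand far above Kd: saturation at the bound shift
  expect_equal(predict_shift(1e-3, 1e5, 10, 3.15, 3.12), 3.12,
               tolerance = 1e-4)
  expect_equal(predict_shift(100, 100, 4, 0, 1), 0.8190025, tolerance = 1e-6)

  l <- seq(0, 800, by = 50)
  obs <- predict_shift(100, l, 300, 3.15, 3.12)
  expect_true(all(diff(obs) < 0))          # monotone towards the bound shift
  expect_true(all(obs <= 3.15 & obs >= 3.12))
})

test_that("combined chemical shift perturbation follows the weighted norm", {
  expect_equal(csp_combined(0, 0, 0.2), 0)
  expect_equal(csp_combined(0.1, 0.5, 0.2), sqrt(0.01 + 0.01))
  expect_equal(csp_combined(0.1, 0.5, 0.2), 0.14142, tolerance = 1e-4)
  expect_equal(csp_combined(-0.3, 0, 0.2), 0.3)
  expect_error(csp_combined(0.1, 0.1, 0), "weight")
})

test_that("titration fitting inverts the forward model and flags flat series", {
  for (kd in c(1, 10, 100, 1000)) {
    fit <- fit_titration(gen_titration(kd, sigma = 0))
    expect_true(fit$converged)
    expect_equal(fit$estimates[["kd_uM"]], kd, tolerance = 1e-3)
    expect_equal(fit$estimates[["delta_bound_ppm"]], 8.10, tolerance = 1e-3)
  }
  flat <- titration_series(100, c(0, 100, 200, 400, 800),
                           rep(8.30, 5) + c(0, 1e-6, -1e-6, 0, 1e-6))
  expect_true("non_binding" %in% fit_titration(flat)$flags)
})

test_that("ITC heats satisfy conservation and match a brute-force oracle", {
  expect_equal(itc_heats(1, 30, 0, 200, 50, 500, rep(2, 20)), rep(0, 20))

  # saturating design: total heat equals n * dH * cell moles within 1%
  heats <- itc_heats(1, 1e-4, -5, 200, 50, 1e4, rep(1, 30))
  expect_equal(sum(heats), -5 * 200 * 50 * 1e-3, tolerance = 0.01)

  heats <- itc_heats(1, 30, -5, 200, 50, 500, rep(2, 20))
  expect_equal(heats, oracle_itc_heats(1, 30, -5, 200, 50, 500, rep(2, 20)),
               tolerance = 1e-9)
})

test_that("ITC fitting inverts the forward model and flags weak designs", {
  for (kd in c(1, 10, 100, 1000)) {
    tg <- gen_itc(kd, design = itc_design(cell_uM = max(10, kd / 2),
                                          syringe_uM = max(100, kd * 5)),
                  sigma_rel = 0)
    fit <- fit_itc(tg)
    expect_true(fit$converged)
    expect_equal(fit$estimates[["kd_uM"]], kd, tolerance = 1e-3)
    expect_equal(fit$estimates[["n"]], 1, tolerance = 1e-3)
    expect_equal(fit$estimates[["dH_kcal_mol"]], -5, tolerance = 1e-3)
  }
  zero <- itc_thermogram(200, 50, 500, rep(2, 20), rep(0, 20))
  expect_true("non_binding" %in% fit_itc(zero)$flags)
  # c-value far outside the informative window: flagged low confidence
  weak <- gen_itc(5e4, design = itc_design(cell_uM = 20, syringe_uM = 200),
                  sigma_rel = 0)
  expect_true("low_confidence_kd" %in% fit_itc(weak)$flags)
  expect_error(fit_itc(itc_thermogram(200, 50, 500, rep(2, 5), rep(1, 5))),
               "10 usable")
})

test_that("coupled-assay rates are linear in enzyme concentration", {
  expect_equal(ppiase_kobs(0.02, 150.3, 0, 50), 0.02)
  expect_equal(ppiase_kobs(0.02, 150.3, 0.04, 50), 0.14024)
  k1 <- ppiase_kobs(0.02, 150.3, 0.01, 50)
  k2 <- ppiase_kobs(0.02, 150.3, 0.02, 50)
  expect_equal(k2 - 0.02, 2 * (k1 - 0.02))
})

test_that("PPIase fitting recovers turnover and is amplitude-invariant", {
  curves <- gen_ppiase(150.3, k0 = 0.02, sigma_rel = 0)
  fit <- suppressWarnings(fit_ppiase(curves))
  expect_equal(fit$estimates[["turnover_s1"]], 150.3, tolerance = 1e-3)
  expect_equal(fit$estimates[["k0_s1"]], 0.02, tolerance = 1e-3)

  # absorbance units are arbitrary: rescaling the signal changes nothing
  scaled <- lapply(curves, function(cv) {
    cv$signal <- 37.5 * cv$signal + 2
    cv
  })
  fit2 <- suppressWarnings(fit_ppiase(scaled))
  expect_equal(fit2$estimates[["turnover_s1"]],
               fit$estimates[["turnover_s1"]], tolerance = 1e-6)

  # all curves at the blank rate: no enzymatic activity, flagged
  blankish <- lapply(c(0.005, 0.01, 0.02, 0.04), function(E)
    progress_curve(E, 50, 0:150, 1 - exp(-0.02 * (0:150))))
  fit3 <- suppressWarnings(fit_ppiase(blankish))
  expect_equal(fit3$estimates[["turnover_s1"]], 0, tolerance = 1e-6)
  expect_true("no_activity" %in% fit3$flags)

  expect_error(fit_ppiase(blankish[1:2]), "3 enzyme concentrations")
})
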