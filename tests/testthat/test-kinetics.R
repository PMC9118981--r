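test_that("the MM rate law has the right limits", {
  p <- table1_cah_pr()
  expect_equal(mm_rate(p, 0.01, 0), 0)
  expect_equal(mm_rate(p, 0.01, p$Km), p$kcat * 0.01 / 2, tolerance = 1e-12)
  expect_equal(mm_rate(p, 0.01, 100 * p$Km), p$kcat * 0.01,
               tolerance = 0.01)
  # zero-order regime: within 5% of Vmax for S >= 20 Km
  expect_gt(mm_rate(p, 0.01, 20 * p$Km), 0.95 * p$kcat * 0.01)
})

test_that("noiseless rate data are recovered exactly and degenerate designs error", {
  p <- table1_cah_pr()
  E0 <- 0.012
  S <- c(10, 25, 50, 100, 200, 400, 700, 1000)
  d <- gen_rate_data(p, E0, S, cv = 0, seed = 1)
  fit <- fit_mm(d$S_uM, d$v_uM_s, E0)
  expect_equal(fit$kcat, p$kcat, tolerance = 1e-8)
  expect_equal(fit$Km, p$Km, tolerance = 1e-8)
  expect_error(fit_mm(c(100, 500), c(1, 2), E0), "degenerate_design")
})

test_that("fit is invariant to observation order and consistent unit rescaling", {
  p <- table1_cah_pr()
  E0 <- 0.012
  S <- c(10, 25, 50, 100, 200, 400, 700, 1000)
  d <- gen_rate_data(p, E0, S, cv = 0.01, seed = 9)
  f1 <- fit_mm(d$S_uM, d$v_uM_s, E0)
  ix <- sample(nrow(d))
  f2 <- fit_mm(d$S_uM[ix], d$v_uM_s[ix], E0)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)

  # concentrations in nM, E0 rescaled consistently: kcat unchanged, Km scales
  f3 <- fit_mm(d$S_uM * 1000, d$v_uM_s * 1000, E0 * 1000)
  expect_equal(f3$kcat, f1$kcat, tolerance = 1e-6)
  expect_equal(f3$Km, f1$Km * 1000, tolerance = 1e-3)
})

test_that("progress curves obey the implicit MM solution, mass balance and event semantics", {
  p <- table1_cah_pr()
  E0 <- 0.002   # partial depletion over the 8 hr window
  t <- seq(0, 8, by = 0.5)

  # no enzyme: constant
  none <- simulate_progress(p, 0, 200, t)
  expect_equal(none$cya_ppm, rep(200, length(t)))

  tc <- simulate_progress(p, E0, 200, t)
  # cross-check against the analytic implicit solution at every grid point
  S0 <- 200 / 129.07 * 1000
  for (k in seq_along(t)[-1]) {
    S_k <- tc$cya_ppm[k] / 129.07 * 1000
    t_implied <- mm_implicit_time(p, E0, S0, S_k) / 3600
    expect_equal(t_implied, t[k], tolerance = 1e-6)
  }
  # molar mass balance CYA -> biuret (1:1)
  expect_equal(tc$biuret_ppm / 103.08, (200 - tc$cya_ppm) / 129.07,
               tolerance = 1e-9)
  expect_true(all(diff(tc$cya_ppm) <= 1e-9))

  # inactivation event freezes the curve
  ev <- simulate_progress(p, E0, 200, t, inactivation_times_hr = 3)
  expect_equal(ev$cya_ppm[t <= 3], tc$cya_ppm[t <= 3], tolerance = 1e-8)
  after <- ev$cya_ppm[t >= 3]
  expect_true(all(abs(after - after[1]) < 1e-9))
  expect_false(any(ev$enzyme_active[t >= 3]))
  expect_error(simulate_progress(p, E0, 200, c(-1, 0, 1)), "non-negative")
})

test_that("depletion is linear in time while S stays far above Km", {
  p <- table1_cah_pr()
  E0 <- 0.07
  t <- seq(0, 6, by = 1)
  tc <- simulate_progress(p, E0, 6000, t)   # 6000 ppm >> Km (~14.8 ppm)
  drops <- -diff(tc$cya_ppm)
  expect_gt(min(tc$cya_ppm), 20 * p$Km * 129.07 / 1000)
  expect_lt(max(drops) / min(drops) - 1, 0.05)
})

test_that("the remediation plan composes the three stage calculators", {
  p <- table1_cah_pr()
  plan <- plan_remediation(volume_L = 1000, cya_ppm = 200, free_cl_ppm = 5.72,
                           params = p, enzyme_mgL = 0.45,
                           target_cya_ppm = 50)
  # stage 1 equals the standalone dose call with the sulfite preset
  solo <- reductant_dose(5.72, "hypochlorite", "sodium_sulfite", 2)
  expect_equal(plan$stage1_reduce$dose_ppm, solo$dose_ppm)
  # stage 2 equals the standalone implicit-time call
  E0 <- 0.45 / p$enzyme_molar_mass * 1000
  expect_equal(plan$stage2_hydrolyze$hours_to_target,
               mm_implicit_time(p, E0, 200 / 129.07 * 1000,
                                50 / 129.07 * 1000) / 3600,
               tolerance = 1e-12)
  # stage 3 equals the electron-balance equivalents applied to biuret formed
  expect_equal(plan$stage3_oxidize$equivalents_per_biuret, 4.5)
  expect_equal(plan$stage3_oxidize$biuret_mmol, 150 / 129.07 * 1000,
               tolerance = 1e-9)

  zero_cl <- plan_remediation(1000, 200, 0, p, 0.45, 50)
  expect_equal(zero_cl$stage1_reduce$dose_ppm, 0)
  at_target <- plan_remediation(1000, 40, 1, p, 0.45, 50)
  expect_equal(at_target$stage2_hydrolyze$hours_to_target, 0)
  expect_error(plan_remediation(1000, 200, 1, p, 0, 50), "unreachable_target")
})
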