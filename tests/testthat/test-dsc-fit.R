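test_that("two-state fit recovers exact model data to numerical
           precision", {
  tg <- simulate_dsc(T_d = 350, dH = 450, sigma_frac = 0)
  f <- fit_two_state(tg)
  expect_equal(f$T_d, 350, tolerance = 1e-6)
  expect_equal(f$dH_vH, 450, tolerance = 1e-4)
  expect_lt(f$rms_residual / f$peak_height, 1e-8)
  expect_identical(f$status, "OK")
  expect_equal(f$cooperativity_ratio, 1, tolerance = 0.005)
  expect_equal(f$dS_d, f$dH_cal / f$T_d, tolerance = 1e-12)
})

test_that("two-state fit recovers parameters under 1% peak noise", {
  f <- fit_two_state(simulate_dsc(T_d = 350, dH = 450,
                                  sigma_frac = 0.01, seed = 99))
  expect_lt(abs(f$T_d - 350), 0.1)
  expect_rel(f$dH_vH, 450, 0.02)
  expect_equal(f$cooperativity_ratio, 1, tolerance = 0.05)
  expect_identical(f$status, "OK")
})

test_that("a shouldered two-population mixture fails the two-state
           criterion", {
  mix <- simulate_dsc(sigma_frac = 0, populations = data.frame(
    weight = c(0.6, 0.4), T_d = c(350, 344), dH = c(450, 450)))
  f <- suppressWarnings(fit_two_state(mix))
  expect_identical(f$status, "FAILED")
  expect_gt(f$rms_residual / f$peak_height, 0.05)

  # the diagnostic has a floor: populations only 4 K apart are still
  # absorbed by a single two-state shape
  mix4 <- simulate_dsc(sigma_frac = 0, populations = data.frame(
    weight = c(0.6, 0.4), T_d = c(350, 346), dH = c(450, 450)))
  f4 <- suppressWarnings(fit_two_state(mix4))
  expect_identical(f4$status, "OK")
  expect_lt(f4$rms_residual / f4$peak_height, 0.05)
})

test_that("a simulated T_d downshift reads out as strictly negative
           delta T_d", {
  free <- fit_two_state(simulate_dsc(T_d = 350, dH = 450, sigma_frac = 0))
  bound <- fit_two_state(simulate_dsc(T_d = 345, dH = 450, sigma_frac = 0))
  expect_lt(bound$T_d - free$T_d, 0)
  # destabilization at constant dH is entropic: dS rises as T_d falls
  expect_gt(bound$dS_d, free$dS_d)
})

test_that("fitted T_d is the half-denatured temperature", {
  tg <- simulate_dsc(T_d = 352, dH = 500, sigma_frac = 0)
  f <- fit_two_state(tg)
  # f_D(T_d) = 1/2 within a grid step
  TK <- tg$T_K
  cp_at <- two_state_cp(f$T_d, f$dH_vH, f$T_d)
  expect_equal(cp_at, f$dH_vH^2 / (4 * 8.314462618e-3 * f$T_d^2),
               tolerance = 1e-9)
  expect_lt(abs(f$T_d - 352), diff(TK)[1])
})
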