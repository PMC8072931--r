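R_kJ <- 8.314462618e-3

test_that("two-state Cp closed forms at the midpoint", {
  # at T_d (dCp = 0): f_D = 1/2 and Cp = dH^2 / (4 R T_d^2)
  expect_equal(two_state_cp(350, 450, 350),
               450^2 / (4 * R_kJ * 350^2), tolerance = 1e-12)
  expect_equal(two_state_cp(350, 450, 350), 49.70439, tolerance = 1e-5)
  expect_error(two_state_cp(-1, 450, 350), "positive")
})

test_that("integral of the two-state curve conserves the enthalpy", {
  for (dH in c(200, 450, 700)) for (Td in c(330, 350, 360)) {
    TK <- seq(250, 450, by = 0.05)  # wide window captures the tails
    tg <- thermogram(TK, two_state_cp(TK, dH, Td))
    expect_rel(integrate_enthalpy(tg), dH, 1e-3)
  }
})

test_that("grid maximum of the two-state curve matches the closed form", {
  TK <- seq(293.15, 368.15, by = 0.01)
  peak <- max(two_state_cp(TK, 450, 350))
  expect_rel(peak, 450^2 / (4 * R_kJ * 350^2), 1e-3)
})

test_that("find_td locates the transition maximum", {
  # the Cp maximum sits a hair below T_d (~2RT_d^3/dH^2 scale), inside
  # 0.1 K for dH = 450 and 0.05 K for the sharper dH = 700 transition
  expect_lt(abs(find_td(simulate_dsc(T_d = 350, dH = 450,
                                     sigma_frac = 0)) - 350), 0.1)
  expect_lt(abs(find_td(simulate_dsc(T_d = 350, dH = 700,
                                     sigma_frac = 0)) - 350), 0.05)
  # symmetric gaussian: exact centre
  TK <- seq(300, 380, by = 0.1)
  g <- thermogram(TK, 10 * exp(-(TK - 340)^2 / 18))
  expect_equal(find_td(g), 340, tolerance = 1e-6)
  # shouldered mixture raises a warning
  mix <- simulate_dsc(sigma_frac = 0, populations = data.frame(
    weight = c(0.5, 0.5), T_d = c(352, 341), dH = c(600, 600)))
  expect_warning(td <- find_td(mix), "multimodal|maxima")
})

test_that("sigmoidal baseline: round trip, ramp removal, flat input", {
  # transition clear of both windows (precondition of the operation)
  tg <- simulate_dsc(T_d = 340, dH = 450, sigma_frac = 0)
  peak <- max(tg$cp_exc)
  rt <- subtract_baseline(tg)
  expect_lt(max(abs(rt$cp_exc - tg$cp_exc)) / peak, 0.005)

  ramp <- tg
  ramp$cp_exc <- tg$cp_exc + 2 + 0.05 * (tg$T_K - 320)
  fixed <- subtract_baseline(ramp)
  expect_rel(integrate_enthalpy(fixed), 450, 0.01)
  expect_lt(max(abs(fixed$cp_exc - tg$cp_exc)) / peak, 0.01)

  flat <- thermogram(seq(293.15, 368.15, 0.1),
                     rep(0, length(seq(293.15, 368.15, 0.1))))
  expect_equal(max(abs(subtract_baseline(flat)$cp_exc)), 0)

  # window overlapping the peak is rejected
  expect_error(subtract_baseline(tg, pre_window = c(330, 345)),
               "overlaps")
})

test_that("enthalpy integration is exact on the simulator and linear", {
  tg <- simulate_dsc(T_d = 350, dH = 450, sigma_frac = 0)
  expect_rel(integrate_enthalpy(tg), 450, 1e-3)
  z <- thermogram(seq(300, 360, 0.1), rep(0, 601))
  expect_identical(integrate_enthalpy(z), 0)
  scaled <- tg
  scaled$cp_exc <- tg$cp_exc / (1 - 0.12)
  expect_equal(integrate_enthalpy(scaled),
               integrate_enthalpy(tg) / 0.88, tolerance = 1e-12)
})

test_that("native-loss correction rescales by the surviving fraction", {
  tg <- simulate_dsc(T_d = 350, dH = 450, sigma_frac = 0)
  h0 <- integrate_enthalpy(tg)
  # 12% native loss after 24 h of incubation
  expect_equal(integrate_enthalpy(correct_native_loss(tg, 0.12)),
               h0 / 0.88, tolerance = 1e-12)
  # 48 h: a further 9% composes multiplicatively
  expect_equal(integrate_enthalpy(correct_native_loss(tg, c(0.12, 0.09))),
               h0 / (0.88 * 0.91), tolerance = 1e-12)
  expect_equal(correct_native_loss(tg, 0)$cp_exc, tg$cp_exc)
  expect_error(correct_native_loss(tg, 1), "loss_fraction")
})

test_that("entropy at the midpoint is dH / T_d", {
  expect_equal(entropy_at_td(450, 350), 450 / 350, tolerance = 1e-12)
  expect_equal(entropy_at_td(450, 350), 1.2857, tolerance = 1e-4)
  expect_identical(entropy_at_td(0, 350), 0)
  expect_equal(entropy_at_td(900, 175), 4 * entropy_at_td(450, 350))
})
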