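test_that("adduct mass prediction reproduces the printed peak roster", {
  frag <- pt_fragment(q = 2)
  # free RNase A deconvolved at 13682 Da; fragment adds ~502.4 Da
  expect_equal(round(predict_adduct_mass(13682, frag, 1)), 14184)
  expect_lt(abs(predict_adduct_mass(13682, frag, 2) - 14686), 1)
  # HEWL adduct printed at 14807 Da
  expect_lt(abs(predict_adduct_mass(14304, frag, 1) - 14807), 1)
  expect_identical(predict_adduct_mass(13682, frag, 0), 13682)
  # sulphate/phosphate adducts: +98 Da
  expect_equal(round(13682 + average_mass("H3PO4")), 13780)
  expect_equal(round(13682 + average_mass("H2SO4")), 13780)
})

test_that("adduct mass increments are M0-independent and additive in k", {
  frag <- pt_fragment(q = 2)
  d1 <- predict_adduct_mass(13682, frag, 1) - 13682
  d2 <- predict_adduct_mass(14304, frag, 1) - 14304
  expect_equal(d1, d2, tolerance = 1e-12)
  for (k in 0:3)
    expect_equal(predict_adduct_mass(13682, frag, k) - 13682, k * d1,
                 tolerance = 1e-9)
})

test_that("assignment engine reproduces the full RNase A roster with the
           isobaric acid flag", {
  peaks <- c(13682, 13780, 14184, 14283, 14686)
  asg <- assign_adducts(peaks, M0 = 13682, fragments = pt_fragment(2),
                        k_max = 2)
  expect_true(all(asg$matched))
  expect_equal(asg$k, c(0, 0, 1, 1, 2))
  expect_identical(asg$composition[1], "protein")
  # 13780 and 14283: sulphuric vs phosphoric acid are isobaric - flagged,
  # never silently resolved
  expect_true(asg$ambiguous[2])
  expect_true(asg$ambiguous[4])
  expect_match(asg$candidates[2], "H2SO4")
  expect_match(asg$candidates[2], "H3PO4")
  expect_false(asg$ambiguous[3])
  expect_true(all(abs(asg$error_da) <= 1.5))
  # printed-roster internal consistency the engine must reproduce
  expect_lt(abs((14184 - 13682) - (14283 - 13780)), 1 + 1e-9)
  expect_lt(abs((14686 - 13682) - 2 * (14184 - 13682)), 2 + 1e-9)
})

test_that("assignment handles free-protein-only and unmatched peaks", {
  asg <- assign_adducts(14304, M0 = 14304, fragments = pt_fragment(2))
  expect_identical(asg$composition, "protein")
  expect_false(asg$ambiguous)
  far <- assign_adducts(14304 + 250, M0 = 14304,
                        fragments = pt_fragment(2))
  expect_false(far$matched)
  expect_identical(far$composition, "unassigned")
})

test_that("m/z conversion follows the proton convention", {
  expect_equal(mz_from_mass(14304, 10), (14304 + 10 * 1.007276466) / 10,
               tolerance = 1e-12)
  expect_equal(mz_from_mass(14304, 10), 1431.41, tolerance = 0.01)
  expect_equal(mz_from_mass(14304, 1), 14305.01, tolerance = 0.01)
  expect_error(mz_from_mass(14304, 0), "z")
})

test_that("envelope deconvolution round-trips single and mixed species", {
  sp <- simulate_esi_spectrum(14304, z_range = 8:14, sigma_rel = 0)
  dc <- deconvolve_envelope(sp, z_range = 8:14)
  expect_equal(nrow(dc), 1)
  expect_lt(abs(dc$mass - 14304), 1)

  sp2 <- simulate_esi_spectrum(c(13682, 14184), c(3, 1), z_range = 8:14,
                               sigma_rel = 0)
  dc2 <- deconvolve_envelope(sp2, z_range = 8:14)
  expect_equal(nrow(dc2), 2)
  expect_lt(abs(dc2$mass[1] - 13682), 1)
  expect_lt(abs(dc2$mass[2] - 14184), 1)
  # 3:1 abundance preserved as intensity order
  expect_gt(dc2$intensity[1], dc2$intensity[2])

  expect_warning(dc0 <- deconvolve_envelope(
    data.frame(mz = numeric(0), intensity = numeric(0))), "empty")
  expect_equal(nrow(dc0), 0)
})

test_that("deconvolution tolerates 2% multiplicative noise within 2 Da", {
  errs <- vapply(1:50, function(i) {
    sp <- simulate_esi_spectrum(14304, z_range = 8:14, sigma_rel = 0.02,
                                seed = i)
    d <- deconvolve_envelope(sp, z_range = 8:14)
    if (nrow(d) == 0) return(NA_real_)
    min(abs(d$mass - 14304))
  }, numeric(1))
  expect_true(all(!is.na(errs)))
  expect_lt(max(errs), 2)
})

test_that("deconvolution round trip across the 10-20 kDa range", {
  set.seed(5)
  for (i in 1:6) {
    M <- runif(1, 10000, 20000)
    zr <- sort(sample(5:20, sample(4:8, 1)))
    sp <- simulate_esi_spectrum(M, z_range = zr,
                                envelope_center_z = round(mean(zr)),
                                sigma_rel = 0,
                                mz_window = c(400, 4100))
    dc <- deconvolve_envelope(sp, z_range = zr)
    expect_gte(nrow(dc), 1)
    expect_lt(min(abs(dc$mass - M)), 1)
  }
})
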